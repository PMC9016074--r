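#' Spatial-frequency grids
#'
#' Uniformly spaced spatial frequencies, endpoints inclusive. The standard
#' acquisition band for tissue work spans 0 to 0.8 1/mm in 81 points.
#'
#' @param f_max highest frequency (1/m).
#' @param n number of points.
#' @return strictly increasing numeric vector of frequencies (1/m),
#'   starting at 0.
#' @examples
#' f <- sfdiFrequencies()      # 81 points, 0 to 800 1/m (0.8 1/mm)
#' @export
sfdiFrequencies <- function(f_max = 0.8e3, n = 81L) {
  stopifnot(f_max > 0, n >= 2)
  seq(0, f_max, length.out = n)
}

#' Hankel transform of radially symmetric spatially resolved reflectance
#'
#' Transforms a radially symmetric reflectance profile into the spatial
#' frequency domain by the discrete zero-order Hankel transform
#' `R(f) = 2 pi sum_i R(r_i) J0(2 pi f r_i) r_i dr_i`, evaluated at the ring
#' area-centroid radii (which reduces quadrature error of steep near-source
#' profiles on logarithmically spaced rings). The result is unitless. The
#' profile must extend far enough that the tail contribution is negligible;
#' no extrapolation beyond the last bin edge is performed.
#'
#' @param srr data frame from [normalizeRadial()] (columns `r_lo`, `r_hi`,
#'   `value`; 1/m^2).
#' @param freqs frequency grid (1/m), e.g. [sfdiFrequencies()].
#' @return data frame with `f` (1/m) and `R` (unitless spectrum). The
#'   attribute `"band_warning"` is `TRUE` when the frequency grid exceeds
#'   the band resolvable by the binning (`f > 1 / (2 min dr)`).
#' @export
hankelSRR <- function(srr, freqs) {
  stopifnot(is.data.frame(srr), all(c("r_lo", "r_hi", "value") %in% names(srr)),
            is.numeric(freqs), all(freqs >= 0), all(diff(freqs) > 0))
  r <- sqrt((srr$r_lo^2 + srr$r_hi^2) / 2)   # ring area-centroid radius
  ring_area <- pi * (srr$r_hi^2 - srr$r_lo^2)
  wgt <- srr$value * ring_area               # exact per-ring weight
  spec <- vapply(freqs, function(f) sum(wgt * besselJ(2 * pi * f * r, 0)),
                 numeric(1))
  dr_min <- min(srr$r_hi - srr$r_lo)
  structure(data.frame(f = freqs, R = spec),
            band_warning = max(freqs) > 1 / (2 * dr_min))
}

#' Fourier transform of x-resolved, y-integrated reflectance
#'
#' For profiles symmetric across the x axis (e.g. acquired with a tilted
#' detector that integrates over y), the spatial-frequency-domain reflectance
#' is the one-dimensional cosine transform along x:
#' `R(f) = sum_i R(x_i) cos(2 pi f x_i) dx_i`. The symmetry makes the sine
#' part vanish, so any antisymmetric noise component contributes nothing by
#' construction.
#'
#' @param x bin-center coordinates (m).
#' @param value profile values (1/m, y-integrated reflectance per unit x).
#' @param dx bin widths (m), recycled.
#' @param freqs frequency grid (1/m).
#' @return data frame with `f` and `R` (unitless).
#' @export
fourierSRRx <- function(x, value, dx, freqs) {
  stopifnot(length(x) == length(value), all(freqs >= 0), all(diff(freqs) > 0))
  dx <- rep_len(dx, length(x))
  spec <- vapply(freqs, function(f) sum(value * cos(2 * pi * f * x) * dx),
                 numeric(1))
  structure(data.frame(f = freqs, R = spec),
            band_warning = max(freqs) > 1 / (2 * min(dx)))
}
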