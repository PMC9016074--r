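#' Surface detectors and volumetric accumulators
#'
#' Constructors for the accumulators a simulation can score into. All raw
#' accumulator contents are packet weights; normalized views (per area, per
#' volume, relative to the launch count N) are computed on demand by
#' [normalizeRadial()], [normalizeFluence()] and friends, never stored as the
#' only copy.
#'
#' `mcRadialDetector()` bins exiting packets into annular rings. Bins are
#' half-open `[lo, hi)` (the last upper edge inclusive). With `log = TRUE`
#' the first edge is at 0 and the remaining edges are logarithmically spaced
#' between `r_min` and `r_max` (the placement of the first interior edge is
#' an explicit parameter, not a convention).
#'
#' Acceptance: either a minimum exit-direction cosine `cos_min` w.r.t. the
#' surface normal, or a numerical aperture `na` together with the exterior
#' refractive index `n_exterior` (converted to
#' `cos_min = sqrt(1 - (na/n_exterior)^2)`). `na = 1` accepts all exit
#' angles.
#'
#' @param r_max outer radius (m).
#' @param n_bins number of annular bins.
#' @param log logical: logarithmically spaced bins.
#' @param r_min first interior edge for log-spaced bins (m).
#' @param cos_min minimum acceptance cosine (default 0: all angles).
#' @param na,n_exterior alternative acceptance: numerical aperture and
#'   exterior index.
#' @return detector spec objects consumed by [mcSimulate()].
#' @export
mcRadialDetector <- function(r_max, n_bins, log = FALSE, r_min = 10e-6,
                             cos_min = NULL, na = NULL, n_exterior = 1) {
  stopifnot(r_max > 0, n_bins >= 1)
  edges <- if (log) {
    stopifnot(r_min > 0, r_min < r_max, n_bins >= 2)
    c(0, exp(seq(base::log(r_min), base::log(r_max), length.out = n_bins)))
  } else {
    seq(0, r_max, length.out = n_bins + 1)
  }
  structure(list(edges = edges, cos_min = acceptCos(cos_min, na, n_exterior)),
            class = "mc_radial_detector")
}

#' @rdname mcRadialDetector
#' @param xlim,ylim length-2 extents (m).
#' @param nx,ny bin counts.
#' @param tilt acceptance-axis tilt about the y axis, radians (the axis lies
#'   in the x-z plane; 0 is the surface normal).
#' @export
mcCartesianDetector <- function(xlim, ylim, nx, ny, cos_min = NULL, na = NULL,
                                n_exterior = 1, tilt = 0) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, nx >= 1, ny >= 1,
            xlim[2] > xlim[1], ylim[2] > ylim[1])
  structure(list(
    x0 = xlim[1], dx = diff(xlim) / nx, nx = as.integer(nx),
    y0 = ylim[1], dy = diff(ylim) / ny, ny = as.integer(ny),
    cos_min = acceptCos(cos_min, na, n_exterior), tilt = tilt
  ), class = "mc_cartesian_detector")
}

#' @rdname mcRadialDetector
#' @param centers two-column matrix of fiber center coordinates (m).
#' @param core_diameter fiber core diameter (m).
#' @export
mcFiberArrayDetector <- function(centers, core_diameter, na) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, core_diameter > 0, na > 0, na <= 1)
  if (nrow(centers) > 1 &&
      min(stats::dist(centers)) < core_diameter - 1e-12)
    stop("detector fibers overlap")
  structure(list(cx = centers[, 1], cy = centers[, 2],
                 core_radius = core_diameter / 2, na = na),
            class = "mc_fiber_detector")
}

#' @rdname mcRadialDetector
#' @param zlim length-2 depth extent (m).
#' @param nz depth bin count.
#' @param mode `"energy_deposition"` (deposited weight per voxel) or
#'   `"fluence"` (deposition divided by the local absorption coefficient).
#' @export
mcFluenceGrid <- function(xlim, ylim, zlim, nx, ny, nz,
                          mode = c("energy_deposition", "fluence")) {
  mode <- match.arg(mode)
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(zlim) == 2,
            nx >= 1, ny >= 1, nz >= 1)
  structure(list(
    x0 = xlim[1], dx = diff(xlim) / nx, nx = as.integer(nx),
    y0 = ylim[1], dy = diff(ylim) / ny, ny = as.integer(ny),
    z0 = zlim[1], dz = diff(zlim) / nz, nz = as.integer(nz),
    mode = mode
  ), class = "mc_fluence_grid")
}

#' @rdname mcRadialDetector
#' @param capacity maximum recorded events per packet (default 1000; packets
#'   exceeding it are flagged as overflowed and dropped from sampling-volume
#'   computation).
#' @param filter optional recording-time filter: a list with `center`
#'   (length-2, m), `radius` (m), `na` and `n_exit`. Per-packet summaries
#'   (fate, terminal state) are always kept for every packet, but event
#'   lists are stored only for packets that escape through the top surface
#'   inside the given footprint and acceptance cone — the criteria of
#'   [filterTraces()]. This bounds trace memory at the launch counts a
#'   sampling volume needs.
#' @export
mcTrace <- function(capacity = 1000L, filter = NULL) {
  stopifnot(capacity >= 2)
  if (!is.null(filter)) {
    stopifnot(length(filter$center) == 2, filter$radius >= 0,
              filter$na > 0, filter$na <= 1)
    filter <- list(cx = filter$center[1], cy = filter$center[2],
                   radius = filter$radius, na = filter$na,
                   n_exit = filter$n_exit %||% 1)
  }
  structure(list(capacity = as.integer(capacity), filter = filter),
            class = "mc_trace_spec")
}

#' @rdname mcRadialDetector
#' @param radial_top,radial_bottom,cartesian_top,cartesian_bottom,fiber_top
#'   detector specs (or NULL).
#' @export
mcDetectors <- function(radial_top = NULL, radial_bottom = NULL,
                        cartesian_top = NULL, cartesian_bottom = NULL,
                        fiber_top = NULL) {
  structure(list(radial_top = radial_top, radial_bottom = radial_bottom,
                 cartesian_top = cartesian_top,
                 cartesian_bottom = cartesian_bottom, fiber_top = fiber_top),
            class = "mc_detectors")
}

acceptCos <- function(cos_min, na, n_exterior) {
  if (!is.null(cos_min) && !is.null(na))
    stop("give either cos_min or na, not both")
  if (!is.null(na)) {
    stopifnot(na > 0, na <= 1, n_exterior >= 1)
    s <- min(1, na / n_exterior)
    return(sqrt(max(0, 1 - s^2)))
  }
  if (is.null(cos_min)) return(0)
  stopifnot(cos_min >= 0, cos_min <= 1)
  cos_min
}

#' Normalize a radial accumulator to per-area reflectance
#'
#' Spatially resolved reflectance/transmittance relative to the launch count
#' N and per surface area of the annular ring (1/m^2):
#' `value_i = raw_i / (N * pi * (r_{i+1}^2 - r_i^2))`.
#'
#' @param result an `mc_result` from [mcSimulate()].
#' @param side `"top"` or `"bottom"`.
#' @return data frame with `r_lo`, `r_hi`, `r_mid`, `r_centroid` (ring
#'   area-centroid radius), `raw` and `value` (1/m^2).
#' @export
normalizeRadial <- function(result, side = c("top", "bottom")) {
  side <- match.arg(side)
  stopifnot(inherits(result, "mc_result"))
  acc <- result[[paste0("radial_", side)]]
  if (is.null(acc)) stop("no radial ", side, " detector in this result")
  N <- result$n_packets
  if (N <= 0) stop("launch count N is zero")
  det <- result$config$detectors[[paste0("radial_", side)]]
  e <- det$edges
  lo <- e[-length(e)]; hi <- e[-1]
  area <- pi * (hi^2 - lo^2)
  data.frame(
    r_lo = lo, r_hi = hi, r_mid = (lo + hi) / 2,
    r_centroid = sqrt((lo^2 + hi^2) / 2),
    raw = acc$raw, value = acc$raw / (N * area))
}

#' Normalize a Cartesian accumulator
#'
#' @param result an `mc_result`.
#' @param side `"top"` or `"bottom"`.
#' @return list with `x`, `y` (bin centers) and `value` matrix (1/m^2,
#'   relative to N).
#' @export
normalizeCartesian <- function(result, side = c("top", "bottom")) {
  side <- match.arg(side)
  stopifnot(inherits(result, "mc_result"))
  acc <- result[[paste0("cartesian_", side)]]
  if (is.null(acc)) stop("no cartesian ", side, " detector in this result")
  det <- result$config$detectors[[paste0("cartesian_", side)]]
  m <- matrix(acc$raw, det$nx, det$ny)
  list(x = det$x0 + (seq_len(det$nx) - 0.5) * det$dx,
       y = det$y0 + (seq_len(det$ny) - 0.5) * det$dy,
       value = m / (result$n_packets * det$dx * det$dy))
}

#' Normalize a fluence accumulator to a per-volume map
#'
#' Energy deposition relative to N and the voxel volume (1/m^3). In
#' `"fluence"` mode the deposition is additionally divided by the local
#' absorption coefficient, which converts deposited energy into fluence;
#' voxels with `mua = 0` are undefined in that mode and returned as `NA`.
#'
#' @param result an `mc_result`.
#' @return 3D array (1/m^3), dimensions `nx x ny x nz`.
#' @export
normalizeFluence <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  if (is.null(result$fluence)) stop("no fluence grid in this result")
  g <- result$config$fluence
  v <- array(result$fluence$raw, c(g$nx, g$ny, g$nz))
  out <- v / (result$n_packets * g$dx * g$dy * g$dz)
  if (g$mode == "fluence") {
    mua <- localMua(result$config$geometry, g)
    out <- out / ifelse(mua > 0, mua, NA_real_)
  }
  out
}

# absorption coefficient at the fluence-grid voxel centers
localMua <- function(geometry, g) {
  zc <- g$z0 + (seq_len(g$nz) - 0.5) * g$dz
  if (inherits(geometry, "mc_layer_stack")) {
    il <- locateLayer(geometry, zc)
    mua_z <- vapply(il, function(i) {
      if (i < 1 || i > length(geometry$layers)) 0
      else geometry$layers[[i]]$mua
    }, numeric(1))
    array(rep(mua_z, each = g$nx * g$ny), c(g$nx, g$ny, g$nz))
  } else {
    xc <- g$x0 + (seq_len(g$nx) - 0.5) * g$dx
    yc <- g$y0 + (seq_len(g$ny) - 0.5) * g$dy
    out <- array(0, c(g$nx, g$ny, g$nz))
    for (k in seq_len(g$nz)) for (j in seq_len(g$ny)) for (i in seq_len(g$nx)) {
      vx <- voxelAt(geometry, c(xc[i], yc[j], zc[k]))
      out[i, j, k] <- if (is.null(vx)) 0 else vx$material$mua
    }
    out
  }
}

#' Integrate spatially resolved reflectance over a detector-fiber footprint
#'
#' Estimates the reflectance collected by a fiber of the given core radius at
#' a source-detector separation `sds` from a radially symmetric reflectance
#' profile, using exact ring-disc overlap areas: the contribution of ring
#' `[r_i, r_{i+1})` is `value_i` times the area of its intersection with the
#' off-axis detector disc.
#'
#' @param srr data frame from [normalizeRadial()] (columns `r_lo`, `r_hi`,
#'   `value`).
#' @param sds source-detector separation (m).
#' @param core_radius detector-fiber core radius (m).
#' @return collected reflectance fraction (dimensionless, relative to N).
#' @export
integrateRadialToFiber <- function(srr, sds, core_radius) {
  stopifnot(is.data.frame(srr), all(c("r_lo", "r_hi", "value") %in% names(srr)),
            sds >= 0, core_radius > 0)
  if (sds + core_radius > max(srr$r_hi) + 1e-12)
    stop("detector footprint extends beyond the last radial bin edge")
  ov_hi <- vapply(srr$r_hi, circleOverlap, numeric(1),
                  d = sds, r2 = core_radius)
  ov_lo <- vapply(srr$r_lo, circleOverlap, numeric(1),
                  d = sds, r2 = core_radius)
  sum(srr$value * (ov_hi - ov_lo))
}

# area of intersection of a disc of radius r1 centered at the origin with a
# disc of radius r2 centered at distance d
circleOverlap <- function(r1, d, r2) {
  if (r1 <= 0) return(0)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos(pmin(1, pmax(-1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- r2^2 * acos(pmin(1, pmax(-1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  tri <- 0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) *
                          (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - tri
}

#' Per-run energy balance
#'
#' Sums the specular, reflected, transmitted, absorbed (including housing
#' absorption) and laterally escaped weights plus the net roulette drift and
#' compares the total against the launch count N. With roulette disabled the
#' residual is at floating-point rounding level; with roulette enabled the
#' drift term restores the identity exactly while the physical sum matches N
#' only in expectation.
#'
#' @param result an `mc_result`.
#' @return list with `total` (physical weight sum / N), `residual`
#'   (`|total + roulette_net - 1|`), and the individual fractions.
#' @export
energyBalance <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  N <- result$n_packets
  phys <- result$specular + result$reflected + result$transmitted +
    result$absorbed + result$lateral + result$layout_absorbed
  net <- result$roulette_killed - result$roulette_boost + result$cutoff_killed
  list(total = phys / N,
       residual = abs((phys + net) / N - 1),
       specular = result$specular / N,
       reflectance = result$reflected / N,
       transmittance = result$transmitted / N,
       absorbance = (result$absorbed + result$layout_absorbed) / N,
       lateral = result$lateral / N,
       roulette_net = net / N)
}
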