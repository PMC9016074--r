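#' Refractive-index dispersion models
#'
#' Wavelength-dependent refractive indices of the materials used in fiber-optic
#' probes and optical phantoms. Built-in models:
#' \describe{
#'   \item{\code{"fused_silica"}}{Malitson three-term Sellmeier fit
#'     (0.21--3.71 um validity).}
#'   \item{\code{"water"}}{Daimon--Masumura four-term Sellmeier fit at 20 degC
#'     (0.18--1.13 um). The temperature variant is recorded in the material
#'     metadata.}
#'   \item{\code{"polystyrene"}}{Cauchy fit to suspension measurements,
#'     n = 1.5663 + 0.00785/lambda^2 + 0.000334/lambda^4 (lambda in um;
#'     0.40--1.00 um).}
#'   \item{\code{"vacuum"}/\code{"air"}}{n = 1 at all wavelengths.}
#' }
#' A constant-index material can be made with [constantMaterial()].
#'
#' @param name material name (see above) or a `material` object.
#' @param wavelength wavelength in metres (vectorised).
#' @return refractive index (dimensionless), same length as `wavelength`.
#' @examples
#' refractiveIndex("fused_silica", 500e-9)  # 1.4623
#' refractiveIndex("water", 500e-9)         # 1.3368
#' @export
refractiveIndex <- function(name, wavelength) {
  m <- if (inherits(name, "material")) name else material(name)
  stopifnot(is.numeric(wavelength), all(wavelength > 0))
  lo <- m$range[1]; hi <- m$range[2]
  if (any(wavelength < lo | wavelength > hi)) {
    stop(sprintf("wavelength outside the validity range [%g, %g] m of material '%s'",
                 lo, hi, m$name))
  }
  n <- m$fun(wavelength)
  stopifnot(all(n >= 1))
  n
}

#' Look up or construct a material by name
#'
#' @param name one of \code{"fused_silica"}, \code{"water"},
#'   \code{"polystyrene"}, \code{"vacuum"}, \code{"air"}.
#' @return a `material` object with fields `name`, `fun` (wavelength in m ->
#'   n), `range` (validity range in m) and `meta`.
#' @export
material <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  switch(name,
    fused_silica = newMaterial(name, sellmeier(
      B = c(0.6961663, 0.4079426, 0.8974794),
      C2 = c(0.0684043, 0.1162414, 9.896161)^2),
      range = c(0.21e-6, 3.71e-6), meta = list(model = "Sellmeier (Malitson)")),
    water = newMaterial(name, sellmeier(
      B = c(5.684027565e-1, 1.726177391e-1, 2.086189578e-2, 1.130748688e-1),
      C2 = c(5.101829712e-3, 1.821153936e-2, 2.620722293e-2, 1.069792721e1)),
      range = c(0.18e-6, 1.13e-6),
      meta = list(model = "Sellmeier (Daimon-Masumura)", temperature_C = 20)),
    polystyrene = newMaterial(name, function(um) {
      1.5663 + 0.00785 / um^2 + 0.000334 / um^4
    }, range = c(0.40e-6, 1.00e-6), meta = list(model = "Cauchy (suspension fit)")),
    vacuum = ,
    air = newMaterial(name, function(um) rep(1, length(um)),
      range = c(1e-9, Inf), meta = list(model = "constant")),
    stop("unknown material: ", name)
  )
}

#' Constant-index material
#'
#' @param n refractive index, `n >= 1`.
#' @param name label.
#' @return a `material` object.
#' @export
constantMaterial <- function(n, name = sprintf("n=%g", n)) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  newMaterial(name, function(um) rep(n, length(um)), range = c(1e-9, Inf),
              meta = list(model = "constant", n = n))
}

newMaterial <- function(name, fun_um, range, meta = list()) {
  structure(list(
    name = name,
    # fun takes metres; dispersion formulas are written in micrometres
    fun = function(wavelength) fun_um(wavelength * 1e6),
    range = range, meta = meta
  ), class = "material")
}

# Sellmeier form n^2 - 1 = sum_i B_i l^2 / (l^2 - C2_i), l in micrometres
sellmeier <- function(B, C2) {
  force(B); force(C2)
  function(um) {
    l2 <- um^2
    n2 <- 1 + vapply(l2, function(x) sum(B * x / (x - C2)), numeric(1))
    sqrt(n2)
  }
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material '%s'> model: %s, validity %g-%g nm\n", x$name,
              x$meta$model, x$range[1] * 1e9, min(x$range[2], 1) * 1e9))
  invisible(x)
}

#' Unpolarized Fresnel reflection at a planar interface
#'
#' Average of the s- and p-polarized Fresnel reflectances, as in MCML-style
#' photon-packet codes. Beyond the critical angle the reflectance is 1 and no
#' transmitted direction exists (total internal reflection).
#'
#' @param n1,n2 refractive indices of the incident and transmitting media.
#' @param cos_i cosine of the incidence angle w.r.t. the interface normal,
#'   in (0, 1].
#' @return an `interface_event` list with `n_incident`, `n_transmitted`,
#'   `cos_incident`, `reflectance` in [0,1] and `cos_transmitted` (NA under
#'   total internal reflection).
#' @examples
#' fresnel(1.0, 1.462, 1)$reflectance       # 0.03521
#' fresnel(1.462, 1.0, 0.5)$reflectance     # 1 (beyond critical angle)
#' @export
fresnel <- function(n1, n2, cos_i) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (!is.numeric(cos_i) || length(cos_i) != 1L || cos_i <= 0 || cos_i > 1)
    stop("cos_i must be a single value in (0, 1]")
  ev <- list(n_incident = n1, n_transmitted = n2, cos_incident = cos_i)
  if (n1 == n2) {
    ev$reflectance <- 0
    ev$cos_transmitted <- cos_i
  } else {
    sin_i <- sqrt(max(0, 1 - cos_i^2))
    sin_t <- n1 / n2 * sin_i
    if (sin_t >= 1) {                     # total internal reflection
      ev$reflectance <- 1
      ev$cos_transmitted <- NA_real_
    } else {
      cos_t <- sqrt(1 - sin_t^2)
      if (cos_i >= 1 - 1e-12) {           # normal incidence limit
        ev$reflectance <- ((n1 - n2) / (n1 + n2))^2
      } else {
        rs <- (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
        rp <- (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i)
        ev$reflectance <- 0.5 * (rs^2 + rp^2)
      }
      ev$cos_transmitted <- cos_t
    }
  }
  ev$reflectance <- min(1, max(0, ev$reflectance))
  structure(ev, class = "interface_event")
}

#' Specular reflectance at packet launch
#'
#' Normal-incidence Fresnel reflectance caused by the source-tissue (or
#' surrounding-medium/tissue) refractive index mismatch. A launched packet
#' starts with weight `1 - Rsp`; the specular detector records `Rsp`.
#'
#' @param n_source refractive index of the source/surrounding medium.
#' @param n_first refractive index of the first tissue layer.
#' @return specular reflectance R_sp in [0, 1).
#' @examples
#' specularReflectance(1.0, 1.4)  # 0.02778
#' @export
specularReflectance <- function(n_source, n_first) {
  stopifnot(n_source >= 1, n_first >= 1)
  ((n_source - n_first) / (n_source + n_first))^2
}
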