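#' Declarative JSON simulation configurations
#'
#' A simulation can be described by a declarative JSON document (versioned
#' schema) and executed with [runConfig()]. Quantities may be plain numbers
#' (SI units) or tagged objects `{"value": 2.5, "unit": "1/cm"}`; supported
#' unit tags are listed in [toSI()]. Refractive indices may be numbers,
#' `{"n": 1.337}`, or a material reference
#' `{"material": "fused_silica", "wavelength": {"value": 500, "unit": "nm"}}`.
#'
#' Top-level fields: `engine` ("layered"/"voxel"), `n_packets`, `seed`,
#' `rng`, `stepping`, `geometry`, `source`, `layout`, `detectors`,
#' `fluence`, `trace`, `roulette`.
#'
#' @param path file path of a JSON config.
#' @return `readConfig()`: the parsed config list (class `mc_config`);
#'   `writeConfig()`: `path`, invisibly.
#' @seealso [runConfig()]
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  validateConfig(cfg)
}

#' @rdname readConfig
#' @param cfg a config list.
#' @export
writeConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname readConfig
#' @export
validateConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$version)) cfg$version <- 1L
  if (!cfg$version %in% 1L) stop("unsupported config version: ", cfg$version)
  cfg$engine <- cfg$engine %||% "layered"
  if (!cfg$engine %in% c("layered", "voxel"))
    stop("engine must be 'layered' or 'voxel'")
  if (is.null(cfg$n_packets) || cfg$n_packets < 1)
    stop("n_packets must be >= 1")
  if (is.null(cfg$geometry)) stop("config lacks a geometry")
  if (is.null(cfg$source)) stop("config lacks a source")
  structure(cfg, class = "mc_config")
}

#' Execute a declarative configuration
#'
#' Builds the geometry, source, layout, detectors and accumulators described
#' by the config and calls [mcSimulate()].
#'
#' @param cfg an `mc_config` (from [readConfig()]) or a plain list.
#' @param n_packets,seed optional overrides of the config values.
#' @return an `mc_result`.
#' @export
runConfig <- function(cfg, n_packets = NULL, seed = NULL) {
  cfg <- validateConfig(cfg)
  geom <- parseGeometry(cfg$geometry, cfg$engine)
  det <- parseDetectors(cfg$detectors)
  mcSimulate(
    geometry = geom,
    source = parseSource(cfg$source),
    n_packets = n_packets %||% cfg$n_packets,
    seed = seed %||% (cfg$seed %||% 1L),
    rng = cfg$rng %||% "xoshiro",
    stepping = cfg$stepping %||% "aw",
    layout = parseLayout(cfg$layout),
    detectors = det,
    fluence = parseFluence(cfg$fluence),
    trace = if (is.null(cfg$trace)) NULL else
      mcTrace(cfg$trace$capacity %||% 1000L,
              filter = if (is.null(cfg$trace$filter)) NULL else
                list(center = c(qty(cfg$trace$filter$center[[1]]),
                                qty(cfg$trace$filter$center[[2]])),
                     radius = qty(cfg$trace$filter$radius),
                     na = cfg$trace$filter$na,
                     n_exit = cfg$trace$filter$n_exit %||% 1)),
    roulette = cfg$roulette %||% TRUE,
    roulette_threshold = cfg$roulette_threshold %||% 1e-4,
    roulette_m = cfg$roulette_m %||% 10,
    lut_size = cfg$lut_size %||% 4096L)
}

# -- parsing helpers ---------------------------------------------------------

qty <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) return(x)
  if (is.list(x) && !is.null(x$value)) {
    v <- as.numeric(x$value)
    if (identical(x$unit, "inf") || any(!is.finite(v))) return(v)
    return(toSI(v, x$unit %||% "m"))
  }
  if (is.character(x) && x %in% c("Inf", "inf")) return(Inf)
  stop("cannot interpret quantity: ", deparse(x))
}

refIndex <- function(x) {
  if (is.null(x)) return(1)
  if (is.numeric(x)) return(x)
  if (!is.null(x$n)) return(as.numeric(x$n))
  if (!is.null(x$material))
    return(refractiveIndex(x$material, qty(x$wavelength)))
  stop("cannot interpret refractive index entry")
}

parsePF <- function(p) {
  if (is.null(p)) stop("layer/material lacks a phase_function")
  switch(p$family,
    HG = pfHG(p$g),
    MHG = pfMHG(p$g, p$beta),
    GK = pfGK(p$g, p$alpha),
    PC = pfPC(p$n),
    Mie = pfMie(qty(p$diameter), refIndex(p$n_sphere), refIndex(p$n_medium),
                qty(p$wavelength)),
    tabulated = {
      tab <- if (!is.null(p$file)) {
        # two-column text table: cos_theta, density
        m <- utils::read.table(p$file)
        list(cos_theta = m[[1]], p = m[[2]])
      } else {
        list(cos_theta = as.numeric(unlist(p$cos_theta)),
             p = as.numeric(unlist(p$p)))
      }
      pfTabulated(tab$cos_theta, tab$p)
    },
    stop("unknown phase-function family: ", p$family))
}

parseGeometry <- function(g, engine) {
  if (engine == "layered") {
    ls <- g$layers
    if (length(ls) < 3) stop("a layer stack needs at least 3 entries")
    entries <- vector("list", length(ls))
    entries[[1]] <- boundingMedium(refIndex(ls[[1]]$n %||% ls[[1]]))
    entries[[length(ls)]] <-
      boundingMedium(refIndex(ls[[length(ls)]]$n %||% ls[[length(ls)]]))
    for (i in seq(2, length(ls) - 1)) {
      l <- ls[[i]]
      entries[[i]] <- mcLayer(
        mua = qty(l$mua), mus = qty(l$mus), n = refIndex(l$n),
        thickness = qty(l$thickness), pf = parsePF(l$phase_function))
    }
    mcLayerStack(entries)
  } else {
    shape <- as.integer(unlist(g$shape))
    labels <- array(as.integer(unlist(g$labels)), shape)
    mats <- lapply(g$materials, function(m) {
      list(mua = qty(m$mua), mus = qty(m$mus), n = refIndex(m$n),
           pf = parsePF(m$phase_function))
    })
    mcVoxelVolume(labels,
                  voxel_size = vapply(g$voxel_size, qty, numeric(1)),
                  materials = mats,
                  origin = if (is.null(g$origin)) NULL
                           else vapply(g$origin, qty, numeric(1)),
                  n_above = refIndex(g$n_above), n_below = refIndex(g$n_below))
  }
}

parseSource <- function(s) {
  kind <- s$kind %||% "pencil"
  switch(kind,
    pencil = , line = mcSource(kind),
    isotropic = mcSource("isotropic",
                         position = vapply(s$position, qty, numeric(1))),
    gaussian_beam = mcSource("gaussian_beam", fwhm = qty(s$fwhm)),
    uniform_beam = mcSource("uniform_beam", radius = qty(s$radius)),
    rectangular = mcSource("rectangular", width = qty(s$width),
                           height = qty(s$height)),
    fiber = mcSource("fiber", core_diameter = qty(s$core_diameter),
                     cladding_diameter = qty(s$cladding_diameter),
                     na = s$na, n_core = refIndex(s$n_core)),
    stop("unsupported source kind: ", kind))
}

parseLayout <- function(l) {
  if (is.null(l)) return(NULL)
  switch(l$kind %||% "uniform",
    uniform = mcLayoutUniform(),
    fiber_probe = mcLayoutFiberProbe(
      fiber_x = vapply(l$fiber_x, qty, numeric(1)),
      fiber_y = vapply(l$fiber_y, qty, numeric(1)),
      core_diameter = qty(l$core_diameter),
      cladding_diameter = qty(l$cladding_diameter),
      na = l$na, n_core = refIndex(l$n_core),
      tip_radius = qty(l$tip_radius),
      reflectivity = l$reflectivity %||% 0.6,
      lambertian = isTRUE(l$lambertian)),
    six_around_one = sixAroundOneLayout(
      core_diameter = qty(l$core_diameter),
      cladding_diameter = qty(l$cladding_diameter),
      na = l$na, n_core = refIndex(l$n_core),
      tip_radius = qty(l$tip_radius),
      reflectivity = l$reflectivity %||% 0.6),
    linear_array = linearArrayLayout(
      n_fib = l$n_fib,
      core_diameter = qty(l$core_diameter),
      cladding_diameter = qty(l$cladding_diameter),
      na = l$na, n_core = refIndex(l$n_core),
      tip_radius = qty(l$tip_radius),
      reflectivity = l$reflectivity %||% 0.6),
    stop("unsupported layout kind: ", l$kind))
}

parseDetectors <- function(d) {
  if (is.null(d)) return(mcDetectors())
  rad <- function(x) {
    if (is.null(x)) return(NULL)
    mcRadialDetector(r_max = qty(x$r_max), n_bins = x$n_bins,
                     log = isTRUE(x$log),
                     r_min = qty(x$r_min) %||% 10e-6,
                     cos_min = x$cos_min, na = x$na,
                     n_exterior = refIndex(x$n_exterior))
  }
  cart <- function(x) {
    if (is.null(x)) return(NULL)
    mcCartesianDetector(
      xlim = vapply(x$xlim, qty, numeric(1)),
      ylim = vapply(x$ylim, qty, numeric(1)),
      nx = x$nx, ny = x$ny, cos_min = x$cos_min, na = x$na,
      n_exterior = refIndex(x$n_exterior),
      tilt = (x$tilt_deg %||% 0) * pi / 180)
  }
  fib <- function(x) {
    if (is.null(x)) return(NULL)
    mcFiberArrayDetector(
      centers = cbind(vapply(x$fiber_x, qty, numeric(1)),
                      vapply(x$fiber_y, qty, numeric(1))),
      core_diameter = qty(x$core_diameter), na = x$na)
  }
  mcDetectors(radial_top = rad(d$radial_top),
              radial_bottom = rad(d$radial_bottom),
              cartesian_top = cart(d$cartesian_top),
              cartesian_bottom = cart(d$cartesian_bottom),
              fiber_top = fib(d$fiber_top))
}

parseFluence <- function(f) {
  if (is.null(f)) return(NULL)
  mcFluenceGrid(xlim = vapply(f$xlim, qty, numeric(1)),
                ylim = vapply(f$ylim, qty, numeric(1)),
                zlim = vapply(f$zlim, qty, numeric(1)),
                nx = f$nx, ny = f$ny, nz = f$nz,
                mode = f$mode %||% "energy_deposition")
}
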