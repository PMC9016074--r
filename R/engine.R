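#' Run a Monte Carlo photon-transport simulation
#'
#' Propagates `n_packets` photon packets through a layered
#' ([mcLayerStack()]) or voxelated ([mcVoxelVolume()]) sample following the
#' standard MCML propagation logic: exponential steps, Fresnel decisions at
#' boundaries, lookup-table phase-function sampling, weight deposition and
#' Russian roulette. Escaping packets are scored by the configured surface
#' detectors; absorbed weight is accumulated into the optional fluence grid.
#'
#' Stepping methods (voxel engine only; the layered engine uses
#' Albedo-Weight):
#' \describe{
#'   \item{`"aw"` (Albedo-Weight)}{extinction events sampled with
#'     `mut = mua + mus`; the fraction `mua/mut` of the packet weight is
#'     deposited at each event.}
#'   \item{`"ar"` (Albedo-Reject)}{the "ballistic" scheme: at each extinction
#'     event the full packet weight is deposited with probability `mua/mut`
#'     and the packet is terminated.}
#'   \item{`"mbl"` (Microscopic Beer-Lambert)}{scattering events sampled with
#'     `mus`; absorbed energy `W (1 - exp(-mua * l))` is deposited
#'     continuously along each path segment, at scattering events and at
#'     every sample-voxel face crossing.}
#' }
#' All three are equivalent in expectation and converge to equal results;
#' they differ in variance per packet. For fluence work on grids much finer
#' than the mean free path, MBL gives the higher deposition SNR.
#'
#' When a trace is requested, roulette is disabled (so recorded packet
#' weights are physical and non-increasing) and packets are terminated when
#' their weight falls below `weight_cutoff`; the discarded weight is tracked
#' in the energy balance.
#'
#' @param geometry an `mc_layer_stack` or `mc_voxel_volume`.
#' @param source an [mcSource()].
#' @param n_packets number of photon packets to launch (`>= 1`).
#' @param seed RNG seed (integer-valued).
#' @param rng `"xoshiro"` (default, xoshiro256++) or `"ran3"` (the lagged
#'   subtractive generator of the original multilayer code, shipped for bias
#'   experiments).
#' @param stepping `"aw"`, `"ar"` or `"mbl"`.
#' @param layout optional [mcLayoutFiberProbe()] / [mcLayoutUniform()].
#' @param detectors an [mcDetectors()] bundle.
#' @param fluence optional [mcFluenceGrid()].
#' @param trace optional [mcTrace()].
#' @param roulette enable Russian roulette (default TRUE; forced off by
#'   `trace`).
#' @param roulette_threshold weight threshold below which roulette is played.
#' @param roulette_m roulette multiplier m: survive with probability `1/m`
#'   and weight `* m`.
#' @param weight_cutoff hard termination weight used when roulette is off.
#' @param lut_size phase-function lookup-table size.
#' @param max_steps safety cap on propagation steps per packet.
#' @return an `mc_result`: totals (`specular`, `reflected`, `transmitted`,
#'   `absorbed`, ...), raw detector accumulators, optional `fluence` and
#'   `trace`, the launch count `n_packets`, the `seed` and a `config` echo.
#' @examples
#' stack <- mcLayerStack(list(
#'   boundingMedium(1.0),
#'   mcLayer(mua = 100, mus = 0, n = 1.0, thickness = 0.01, pf = pfHG(0)),
#'   boundingMedium(1.0)))
#' res <- mcSimulate(stack, mcSource("pencil"), n_packets = 1e4, seed = 7)
#' energyBalance(res)$transmittance  # about exp(-1)
#' @export
mcSimulate <- function(geometry, source, n_packets, seed = 1L,
                       rng = c("xoshiro", "ran3"),
                       stepping = c("aw", "ar", "mbl"),
                       layout = NULL, detectors = mcDetectors(),
                       fluence = NULL, trace = NULL,
                       roulette = TRUE, roulette_threshold = 1e-4,
                       roulette_m = 10, weight_cutoff = 1e-4,
                       lut_size = 4096L, max_steps = 1e7) {
  rng <- match.arg(rng)
  stepping <- match.arg(stepping)
  stopifnot(inherits(source, "mc_source"), n_packets >= 1,
            roulette_threshold > 0, roulette_threshold < 1, roulette_m >= 1)
  layered <- inherits(geometry, "mc_layer_stack")
  if (!layered && !inherits(geometry, "mc_voxel_volume"))
    stop("geometry must be an mc_layer_stack or mc_voxel_volume")
  if (layered && stepping != "aw")
    stop("the layered engine supports the Albedo-Weight ('aw') stepping method")
  if (!is.null(trace)) {
    if (!layered) stop("event traces are supported by the layered engine")
    stopifnot(inherits(trace, "mc_trace_spec"))
    roulette <- FALSE
  }
  if (!is.null(fluence)) stopifnot(inherits(fluence, "mc_fluence_grid"))
  if (!is.null(layout)) stopifnot(inherits(layout, "mc_surface_layout"))
  stopifnot(inherits(detectors, "mc_detectors"))

  # one LUT per interior layer / material
  pfs <- if (layered) lapply(geometry$layers, `[[`, "pf")
         else lapply(geometry$materials, `[[`, "pf")
  luts <- lapply(pfs, function(pf) pfBuildLut(pf, size = lut_size)$cos_theta)

  cfg <- list(
    n_packets = as.numeric(n_packets),
    seed = as.numeric(seed),
    rng_kind = rngKindCode(rng),
    stepping = match(stepping, c("aw", "ar", "mbl")) - 1L,
    roulette = isTRUE(roulette),
    roulette_threshold = roulette_threshold,
    roulette_m = roulette_m,
    weight_cutoff = weight_cutoff,
    max_steps = as.numeric(max_steps),
    luts = luts,
    n_above = geometry$n_above,
    n_below = geometry$n_below,
    layout = layoutCfg(layout),
    detectors = detectorCfg(detectors),
    fluence = fluenceCfg(fluence),
    trace = if (is.null(trace)) NULL else
      list(capacity = trace$capacity, filter = trace$filter),
    source = list(kind = source$code, params = source$params)
  )
  raw <- if (layered) {
    cfg$layers <- list(
      mua = vapply(geometry$layers, `[[`, numeric(1), "mua"),
      mus = vapply(geometry$layers, `[[`, numeric(1), "mus"),
      n = vapply(geometry$layers, `[[`, numeric(1), "n"),
      z_top = geometry$z_top, z_bottom = geometry$z_bottom,
      lut = seq_along(geometry$layers) - 1L)
    cpp_run_layered(cfg)
  } else {
    d <- geometry$shape
    cfg$volume <- list(
      nx = d[1], ny = d[2], nz = d[3],
      x0 = geometry$origin[1], y0 = geometry$origin[2], z0 = 0,
      dx = geometry$voxel_size[1], dy = geometry$voxel_size[2],
      dz = geometry$voxel_size[3],
      labels = as.integer(geometry$labels) - 1L,
      mua = vapply(geometry$materials, `[[`, numeric(1), "mua"),
      mus = vapply(geometry$materials, `[[`, numeric(1), "mus"),
      n = vapply(geometry$materials, `[[`, numeric(1), "n"),
      lut = seq_along(geometry$materials) - 1L)
    cpp_run_voxel(cfg)
  }
  raw$seed <- seed
  raw$engine <- if (layered) "layered" else "voxel"
  raw$stepping <- stepping
  raw$rng <- rng
  raw$config <- list(geometry = geometry, source = source, layout = layout,
                     detectors = detectors, fluence = fluence, trace = trace,
                     roulette = roulette,
                     roulette_threshold = roulette_threshold,
                     roulette_m = roulette_m, weight_cutoff = weight_cutoff,
                     lut_size = lut_size)
  class(raw) <- "mc_result"
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rngKindCode <- function(rng) {
  switch(rng, xoshiro = 0L, ran3 = 1L, stop("unknown rng kind: ", rng))
}

layoutCfg <- function(layout) {
  if (is.null(layout) || layout$kind == "uniform") return(list(kind = 0L))
  list(kind = 1L, cx = layout$fiber_x, cy = layout$fiber_y,
       core_radius = layout$core_radius,
       cladding_radius = layout$cladding_radius,
       n_core = layout$n_core, na = layout$na,
       tip_radius = layout$tip_radius, reflectivity = layout$reflectivity,
       lambertian = isTRUE(layout$lambertian))
}

detectorCfg <- function(det) {
  cvt <- function(d, what) {
    if (is.null(d)) return(NULL)
    switch(what,
      radial = list(edges = d$edges, cos_min = d$cos_min),
      cart = list(x0 = d$x0, dx = d$dx, nx = d$nx, y0 = d$y0, dy = d$dy,
                  ny = d$ny, cos_min = d$cos_min, tilt = d$tilt),
      fiber = list(cx = d$cx, cy = d$cy, core_radius = d$core_radius,
                   na = d$na))
  }
  list(radial_top = cvt(det$radial_top, "radial"),
       radial_bottom = cvt(det$radial_bottom, "radial"),
       cartesian_top = cvt(det$cartesian_top, "cart"),
       cartesian_bottom = cvt(det$cartesian_bottom, "cart"),
       fiber_top = cvt(det$fiber_top, "fiber"))
}

fluenceCfg <- function(fl) {
  if (is.null(fl)) return(NULL)
  fl[c("x0", "dx", "nx", "y0", "dy", "ny", "z0", "dz", "nz")]
}

#' @export
print.mc_result <- function(x, ...) {
  eb <- energyBalance(x)
  cat(sprintf("<mc_result %s/%s> N = %g, seed = %s\n", x$engine, x$stepping,
              x$n_packets, format(x$seed)))
  cat(sprintf("  specular %.5f  R %.5f  T %.5f  A %.5f\n",
              eb$specular, eb$reflectance, eb$transmittance, eb$absorbance))
  cat(sprintf("  energy-balance residual %.3g\n", eb$residual))
  invisible(x)
}

#' Convenience accessors for simulation totals
#'
#' Total diffuse reflectance, transmittance and specular fraction relative to
#' the launch count N.
#'
#' @param result an `mc_result`.
#' @return a single number.
#' @export
totalReflectance <- function(result) result$reflected / result$n_packets

#' @rdname totalReflectance
#' @export
totalTransmittance <- function(result) result$transmitted / result$n_packets

#' @rdname totalReflectance
#' @export
totalSpecular <- function(result) result$specular / result$n_packets

#' Uniform random deviates from the engine RNG streams
#'
#' Exposes the transport engine's random number generators: the default
#' xoshiro256++ stream and the shipped ran3 clone (the lagged subtractive
#' generator of Numerical Recipes, used by the original multilayer MC code).
#' Streams are reproducible given a seed.
#'
#' @param n number of deviates.
#' @param rng `"xoshiro"` or `"ran3"`.
#' @param seed seed.
#' @return numeric vector of deviates in `[0, 1)`.
#' @export
rngUniform <- function(n, rng = c("xoshiro", "ran3"), seed = 1) {
  rng <- match.arg(rng)
  cpp_rng_uniform(as.integer(n), rngKindCode(rng), as.numeric(seed))
}

#' Sample an exponential propagation step
#'
#' Draws `s = -log(1 - xi) / mut`, the free path between interaction events
#' in a medium with extinction coefficient `mut`. With `mut = 0` the step is
#' infinite (clear medium: the packet propagates to the next boundary); this
#' is signalled by returning `Inf`, not an error.
#'
#' @param n number of draws.
#' @param mut extinction coefficient (1/m), `>= 0`.
#' @param rng,seed RNG selection as in [rngUniform()].
#' @return step lengths (m).
#' @export
sampleStep <- function(n, mut, rng = c("xoshiro", "ran3"), seed = 1) {
  stopifnot(mut >= 0)
  if (mut == 0) return(rep(Inf, n))
  -log1p(-rngUniform(n, rng, seed)) / mut
}
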