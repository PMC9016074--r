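#' Sample layers and layer stacks
#'
#' `mcLayer()` describes one interior layer of a multilayered sample:
#' absorption and scattering coefficients, refractive index, thickness and
#' scattering phase function. `mcLayerStack()` assembles the ordered
#' top-to-bottom stack; the first and last entries are the bounding media and
#' carry only a refractive index (use `boundingMedium()`).
#'
#' @param mua absorption coefficient (1/m), `>= 0`.
#' @param mus scattering coefficient (1/m), `>= 0`.
#' @param n refractive index, `>= 1`.
#' @param thickness layer thickness (m), `> 0`; `Inf` is allowed for the last
#'   interior layer (semi-infinite sample).
#' @param pf a `phase_function` object.
#' @return `mcLayer()` an `mc_layer`; `boundingMedium()` an
#'   `mc_bounding_medium`; `mcLayerStack()` an `mc_layer_stack`.
#' @examples
#' stack <- mcLayerStack(list(
#'   boundingMedium(1.0),
#'   mcLayer(mua = 250, mus = 30000, n = 1.337, thickness = 100e-6,
#'           pf = pfHG(0.9)),
#'   mcLayer(mua = 100, mus = 10000, n = 1.337, thickness = 1e-3,
#'           pf = pfHG(0.9)),
#'   boundingMedium(1.0)))
#' locateLayer(stack, 50e-6)  # 1
#' @export
mcLayer <- function(mua, mus, n, thickness, pf) {
  stopifnot(mua >= 0, mus >= 0, n >= 1, thickness > 0,
            inherits(pf, "phase_function"))
  structure(list(mua = mua, mus = mus, n = n, thickness = thickness, pf = pf),
            class = "mc_layer")
}

#' @rdname mcLayer
#' @export
boundingMedium <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  structure(list(n = n), class = "mc_bounding_medium")
}

#' @rdname mcLayer
#' @param layers list: a bounding medium, one or more `mc_layer`s, a bounding
#'   medium.
#' @export
mcLayerStack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 3,
            inherits(layers[[1]], "mc_bounding_medium"),
            inherits(layers[[length(layers)]], "mc_bounding_medium"))
  interior <- layers[-c(1, length(layers))]
  ok <- vapply(interior, inherits, logical(1), what = "mc_layer")
  if (!all(ok)) stop("interior entries must be mc_layer objects")
  thick <- vapply(interior, `[[`, numeric(1), "thickness")
  if (any(!is.finite(thick[-length(thick)])))
    stop("only the last interior layer may be semi-infinite")
  z_top <- cumsum(c(0, thick[-length(thick)]))
  structure(list(
    n_above = layers[[1]]$n, n_below = layers[[length(layers)]]$n,
    layers = interior, z_top = z_top, z_bottom = z_top + thick
  ), class = "mc_layer_stack")
}

#' @export
print.mc_layer_stack <- function(x, ...) {
  cat(sprintf("<mc_layer_stack> %d interior layer(s), n_above=%g, n_below=%g\n",
              length(x$layers), x$n_above, x$n_below))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d] mua=%g mus=%g 1/m, n=%g, d=%g m, pf=%s\n",
                i, l$mua, l$mus, l$n, l$thickness, l$pf$family))
  }
  invisible(x)
}

#' Locate the region containing a depth
#'
#' Layer intervals are half-open `[z_top, z_bottom)`: a packet exactly on a
#' boundary belongs to the deeper layer. Depths above the surface return 0
#' (top bounding medium) and depths below the last interior layer return
#' `length + 1` (bottom bounding medium).
#'
#' @param stack an `mc_layer_stack`.
#' @param z depth (m).
#' @return integer region index: 0 = top bounding medium, 1..L = interior
#'   layers, L+1 = bottom bounding medium.
#' @export
locateLayer <- function(stack, z) {
  stopifnot(inherits(stack, "mc_layer_stack"))
  L <- length(stack$layers)
  vapply(z, function(zz) {
    if (zz < 0) return(0L)
    i <- findInterval(zz, c(stack$z_top, stack$z_bottom[L]),
                      left.open = FALSE)
    if (i > L) L + 1L else as.integer(i)
  }, integer(1))
}

#' Voxelated sample volumes
#'
#' A voxel volume labels a 3D grid with integer material labels; each label
#' maps to optical properties (mua, mus, n) and a phase function. The volume
#' origin is at the top surface: voxel `[1,1,1]` spans
#' `[x0, x0+dx) x [y0, y0+dy) x [0, dz)`. Voxels are half-open on their
#' positive faces.
#'
#' @param labels 3D integer array (`nx x ny x nz`); values must index
#'   `materials` (1-based).
#' @param voxel_size length-3 numeric, voxel edge lengths (m), all `> 0`.
#' @param materials list of material entries, each a list with `mua`, `mus`,
#'   `n` and `pf` (a `phase_function`).
#' @param origin length-2 numeric: x/y coordinate of the volume corner
#'   (default centers the volume on the beam axis).
#' @param n_above,n_below refractive indices of the media above and below
#'   the volume.
#' @return an `mc_voxel_volume`.
#' @export
mcVoxelVolume <- function(labels, voxel_size, materials, origin = NULL,
                          n_above = 1, n_below = 1) {
  stopifnot(is.array(labels), length(dim(labels)) == 3,
            length(voxel_size) == 3, all(voxel_size > 0), is.list(materials))
  labs <- as.integer(labels)
  if (any(labs < 1L) || any(labs > length(materials)))
    stop("every label must have a materials entry")
  for (m in materials) {
    stopifnot(m$mua >= 0, m$mus >= 0, m$n >= 1,
              inherits(m$pf, "phase_function"))
  }
  d <- dim(labels)
  if (is.null(origin))
    origin <- c(-d[1] * voxel_size[1] / 2, -d[2] * voxel_size[2] / 2)
  stopifnot(n_above >= 1, n_below >= 1)
  structure(list(
    shape = d, voxel_size = as.numeric(voxel_size),
    labels = array(labs, d), materials = materials,
    origin = as.numeric(origin), n_above = n_above, n_below = n_below
  ), class = "mc_voxel_volume")
}

#' @export
print.mc_voxel_volume <- function(x, ...) {
  cat(sprintf("<mc_voxel_volume> %dx%dx%d voxels of %gx%gx%g m, %d material(s)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size[1],
              x$voxel_size[2], x$voxel_size[3], length(x$materials)))
  invisible(x)
}

#' Locate the voxel containing a position
#'
#' Floor division by the voxel size; voxels are half-open on their positive
#' faces, so a position exactly on a voxel corner belongs to the voxel whose
#' minimal corner it is.
#'
#' @param volume an `mc_voxel_volume`.
#' @param position length-3 numeric (x, y, z) in metres.
#' @return list with `index` (1-based voxel triple) and `material` (the
#'   material entry), or `NULL` when the position is outside the volume
#'   bounding box (an escape, not an error).
#' @export
voxelAt <- function(volume, position) {
  stopifnot(inherits(volume, "mc_voxel_volume"), length(position) == 3)
  o <- c(volume$origin, 0)
  i <- floor((position - o) / volume$voxel_size) + 1
  if (any(i < 1) || any(i > volume$shape)) return(NULL)
  i <- as.integer(i)
  lab <- volume$labels[i[1], i[2], i[3]]
  list(index = i, material = volume$materials[[lab]])
}

#' Photon sources
#'
#' Source descriptions for packet launch. All collimated sources launch along
#' +z (into the sample) from the top surface and lose the specular fraction
#' of their weight to the surrounding-medium/sample index mismatch; the fiber
#' source loses the core/sample Fresnel fraction at the actual incidence
#' angle. The line source of a focused ideal lens is the pencil beam.
#'
#' @param kind one of `"pencil"`, `"line"`, `"isotropic"`, `"gaussian_beam"`,
#'   `"uniform_beam"`, `"fiber"`, `"rectangular"`.
#' @param ... kind-specific parameters: `fwhm` (m) for `gaussian_beam`;
#'   `radius` (m) for `uniform_beam`; `width`, `height` (m) for
#'   `rectangular`; `position` (length-3, interior point) for `isotropic`;
#'   `core_diameter`, `cladding_diameter`, `na`, `n_core` for `fiber`.
#' @return an `mc_source`.
#' @examples
#' mcSource("gaussian_beam", fwhm = 100e-6)
#' mcSource("fiber", core_diameter = 200e-6, cladding_diameter = 220e-6,
#'          na = 0.22, n_core = 1.462)
#' @export
mcSource <- function(kind, ...) {
  p <- list(...)
  kinds <- c(pencil = 0L, line = 0L, isotropic = 1L, gaussian_beam = 2L,
             uniform_beam = 3L, fiber = 4L, rectangular = 5L)
  if (!kind %in% names(kinds)) stop("unsupported source kind: ", kind)
  code <- kinds[[kind]]
  params <- switch(kind,
    pencil = , line = numeric(0),
    isotropic = {
      stopifnot(length(p$position) == 3, p$position[3] > 0)
      as.numeric(p$position)
    },
    gaussian_beam = {
      stopifnot(p$fwhm > 0)
      p$fwhm
    },
    uniform_beam = {
      stopifnot(p$radius > 0)
      p$radius
    },
    fiber = {
      stopifnot(p$core_diameter > 0, p$na > 0, p$na <= 1, p$n_core >= 1)
      if (!is.null(p$cladding_diameter) &&
          p$cladding_diameter <= p$core_diameter)
        stop("cladding diameter must exceed the core diameter")
      c(p$core_diameter / 2, p$na, p$n_core)
    },
    rectangular = {
      stopifnot(p$width > 0, p$height > 0)
      c(p$width, p$height)
    })
  structure(list(kind = kind, code = code, params = as.numeric(params),
                 extra = p), class = "mc_source")
}

#' @export
print.mc_source <- function(x, ...) {
  cat(sprintf("<mc_source %s>", x$kind))
  if (length(x$params)) cat(" params:", paste(signif(x$params, 6),
                                              collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Sample packet launches from a source
#'
#' Draws initial packet states (position, direction, weight and specular
#' fraction) from a source, exactly as the transport kernels launch them.
#' Mostly useful for inspecting source geometry.
#'
#' @param source an `mc_source`.
#' @param n number of draws.
#' @param n_above refractive index of the surrounding medium.
#' @param n_entry refractive index of the sample at the entry point.
#' @param seed RNG seed.
#' @param rng RNG kind, `"xoshiro"` or `"ran3"`.
#' @return matrix with columns x, y, z, ux, uy, uz, w, specular.
#' @export
sampleLaunch <- function(source, n, n_above = 1, n_entry = 1.4, seed = 1,
                         rng = "xoshiro") {
  stopifnot(inherits(source, "mc_source"))
  cpp_sample_launch(list(kind = source$code, params = source$params),
                    as.integer(n), as.numeric(seed), rngKindCode(rng),
                    n_above, n_entry)
}

#' Surface layouts of the sample top boundary
#'
#' `mcLayoutUniform()` is the laterally uniform boundary (plain Fresnel
#' optics everywhere, the standard multilayer setup). `mcLayoutFiberProbe()`
#' describes the tip of a metal-housed optical fiber probe: packets arriving
#' under a fiber core undergo Fresnel optics against the core; packets under
#' the housing (inside the tip radius but outside every core) are reflected
#' with the housing reflectivity (specular by default, optionally
#' Lambertian); packets outside the tip see the plain boundary.
#'
#' Helper constructors: `sixAroundOneLayout()` places one central fiber and
#' six tightly packed around it (smallest source-detector separation equals
#' the cladding diameter); `linearArrayLayout()` places `n_fib` fibers in a
#' tightly packed row starting at the origin.
#'
#' @param fiber_x,fiber_y fiber center coordinates (m).
#' @param core_diameter,cladding_diameter fiber core/cladding diameters (m).
#' @param na fiber numerical aperture (in air).
#' @param n_core fiber core refractive index.
#' @param tip_radius probe tip (housing) radius (m).
#' @param reflectivity housing reflectivity in [0, 1].
#' @param lambertian if `TRUE` housing reflection is Lambertian instead of
#'   specular.
#' @return an `mc_surface_layout`.
#' @examples
#' sixAroundOneLayout(core_diameter = 200e-6, cladding_diameter = 220e-6,
#'                    na = 0.22, n_core = 1.462, tip_radius = 3e-3)
#' @export
mcLayoutFiberProbe <- function(fiber_x, fiber_y, core_diameter,
                               cladding_diameter, na, n_core, tip_radius,
                               reflectivity = 0.6, lambertian = FALSE) {
  stopifnot(length(fiber_x) == length(fiber_y), core_diameter > 0,
            cladding_diameter > core_diameter, na > 0, na <= 1, n_core >= 1,
            tip_radius > 0, reflectivity >= 0, reflectivity <= 1)
  if (length(fiber_x) > 1) {
    dmin <- min(stats::dist(cbind(fiber_x, fiber_y)))
    if (dmin < cladding_diameter - 1e-12) stop("fibers overlap")
  }
  structure(list(kind = "fiber_probe", fiber_x = fiber_x, fiber_y = fiber_y,
                 core_radius = core_diameter / 2,
                 cladding_radius = cladding_diameter / 2,
                 na = na, n_core = n_core, tip_radius = tip_radius,
                 reflectivity = reflectivity, lambertian = lambertian),
            class = "mc_surface_layout")
}

#' @rdname mcLayoutFiberProbe
#' @export
mcLayoutUniform <- function() {
  structure(list(kind = "uniform"), class = "mc_surface_layout")
}

#' @rdname mcLayoutFiberProbe
#' @export
sixAroundOneLayout <- function(core_diameter, cladding_diameter, na, n_core,
                               tip_radius, reflectivity = 0.6) {
  sep <- cladding_diameter                    # tight packing
  ang <- (0:5) * pi / 3
  mcLayoutFiberProbe(
    fiber_x = c(0, sep * cos(ang)), fiber_y = c(0, sep * sin(ang)),
    core_diameter = core_diameter, cladding_diameter = cladding_diameter,
    na = na, n_core = n_core, tip_radius = tip_radius,
    reflectivity = reflectivity)
}

#' @rdname mcLayoutFiberProbe
#' @param n_fib number of fibers in the linear array.
#' @export
linearArrayLayout <- function(n_fib, core_diameter, cladding_diameter, na,
                              n_core, tip_radius, reflectivity = 0.6) {
  stopifnot(n_fib >= 1)
  sep <- cladding_diameter
  mcLayoutFiberProbe(
    fiber_x = (seq_len(n_fib) - 1) * sep, fiber_y = rep(0, n_fib),
    core_diameter = core_diameter, cladding_diameter = cladding_diameter,
    na = na, n_core = n_core, tip_radius = tip_radius,
    reflectivity = reflectivity)
}

#' @export
print.mc_surface_layout <- function(x, ...) {
  if (x$kind == "uniform") {
    cat("<mc_surface_layout uniform>\n")
  } else {
    cat(sprintf(
      "<mc_surface_layout fiber_probe> %d fiber(s), core r=%g m, NA=%g, tip r=%g m, housing reflectivity=%g\n",
      length(x$fiber_x), x$core_radius, x$na, x$tip_radius, x$reflectivity))
  }
  invisible(x)
}

#' Reference semantics of the probe-tip surface interaction
#'
#' Applies the surface-layout decision to one upward-moving packet at the top
#' surface: Fresnel optics against a fiber core, partial specular (or
#' Lambertian) reflection from the metal housing, or plain boundary optics
#' outside the tip. This mirrors the decision taken inside the transport
#' kernels and documents the layout module's contract.
#'
#' @param layout an `mc_surface_layout`.
#' @param packet list with `position` (x, y, z = 0), `direction` (unit,
#'   `uz < 0`), `weight`.
#' @param n_tissue refractive index of the first layer.
#' @param n_above refractive index of the surrounding medium.
#' @param xi uniform deviate driving the Fresnel decision.
#' @return the updated packet: `status` one of `"reflected"`,
#'   `"transmitted_core"` (plus `fiber`), `"escaped"`, `"terminated"`, with
#'   updated `direction` and `weight`.
#' @export
surfaceInteract <- function(layout, packet, n_tissue, n_above = 1,
                            xi = stats::runif(1)) {
  stopifnot(inherits(layout, "mc_surface_layout"),
            packet$direction[3] < 0, abs(packet$position[3]) < 1e-12)
  u <- packet$direction; w <- packet$weight
  x <- packet$position[1]; y <- packet$position[2]
  cos_i <- abs(u[3])
  reflectBack <- function(p) {
    p$direction[3] <- -p$direction[3]; p$status <- "reflected"; p
  }
  if (layout$kind == "uniform") {
    ev <- fresnel(n_tissue, n_above, cos_i)
    if (is.na(ev$cos_transmitted) || xi < ev$reflectance)
      return(reflectBack(packet))
    packet$status <- "escaped"
    packet$direction <- exitDirection(u, n_tissue, n_above, ev$cos_transmitted)
    return(packet)
  }
  in_core <- which((x - layout$fiber_x)^2 + (y - layout$fiber_y)^2 <=
                     layout$core_radius^2)
  if (length(in_core) > 0) {
    ev <- fresnel(n_tissue, layout$n_core, cos_i)
    if (is.na(ev$cos_transmitted) || xi < ev$reflectance)
      return(reflectBack(packet))
    packet$status <- "transmitted_core"
    packet$fiber <- in_core[1]
    packet$direction <- exitDirection(u, n_tissue, layout$n_core,
                                      ev$cos_transmitted)
    return(packet)
  }
  if (x^2 + y^2 <= layout$tip_radius^2) {
    packet$weight <- w * layout$reflectivity
    if (packet$weight <= 0) { packet$status <- "terminated"; return(packet) }
    packet$direction[3] <- -packet$direction[3]
    packet$status <- "reflected"
    return(packet)
  }
  ev <- fresnel(n_tissue, n_above, cos_i)
  if (is.na(ev$cos_transmitted) || xi < ev$reflectance)
    return(reflectBack(packet))
  packet$status <- "escaped"
  packet$direction <- exitDirection(u, n_tissue, n_above, ev$cos_transmitted)
  packet
}

exitDirection <- function(u, n1, n2, cos_t) {
  scale <- n1 / n2
  c(u[1] * scale, u[2] * scale, -cos_t)
}
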