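test_that("layer location follows the half-open convention", {
  stack <- mcLayerStack(list(
    boundingMedium(1.0),
    mcLayer(1e2, 1e4, 1.4, 100e-6, pfHG(0.9)),
    mcLayer(1e2, 1e4, 1.4, 1e-3, pfHG(0.9)),
    boundingMedium(1.0)))
  expect_equal(locateLayer(stack, 50e-6), 1L)
  expect_equal(locateLayer(stack, 100e-6), 2L)   # boundary -> deeper layer
  expect_equal(locateLayer(stack, 0), 1L)
  expect_equal(locateLayer(stack, 1.2e-3), 3L)   # bottom bounding medium
  expect_equal(locateLayer(stack, -1e-6), 0L)    # above the surface
  expect_error(mcLayerStack(list(boundingMedium(1), boundingMedium(1))))
  expect_error(mcLayerStack(list(
    boundingMedium(1), mcLayer(1, 1, 1.4, Inf, pfHG(0)),
    mcLayer(1, 1, 1.4, 1e-3, pfHG(0)), boundingMedium(1))),
    "semi-infinite")
})

test_that("voxel lookup uses floor division and half-open boxes", {
  labels <- array(1L, c(4, 5, 6))
  labels[1, 1, 1] <- 2L
  vol <- mcVoxelVolume(labels, c(1e-4, 1e-4, 1e-4), list(
    list(mua = 1, mus = 2, n = 1.4, pf = pfHG(0)),
    list(mua = 9, mus = 2, n = 1.4, pf = pfHG(0))),
    origin = c(0, 0))
  expect_equal(voxelAt(vol, c(0, 0, 0))$index, c(1L, 1L, 1L))
  expect_equal(voxelAt(vol, c(0, 0, 0))$material$mua, 9)
  # exact corner belongs to the voxel whose minimal corner it is
  expect_equal(voxelAt(vol, c(1e-4, 1e-4, 1e-4))$index, c(2L, 2L, 2L))
  expect_null(voxelAt(vol, c(5e-4, 0, 0)))       # escape, not an error
  # brute-force agreement on random positions
  set.seed(9)
  for (i in 1:200) {
    p <- c(runif(1, 0, 4e-4), runif(1, 0, 5e-4), runif(1, 0, 6e-4))
    got <- voxelAt(vol, p)$index
    want <- vapply(1:3, function(a) {
      edges <- seq(0, dim(labels)[a] * 1e-4, by = 1e-4)
      which(p[a] >= edges[-length(edges)] & p[a] < edges[-1])[1]
    }, integer(1))
    expect_equal(got, want)
  }
  expect_error(mcVoxelVolume(array(3L, c(2, 2, 2)), rep(1e-4, 3),
                             list(list(mua = 1, mus = 1, n = 1.4,
                                       pf = pfHG(0)))),
               "materials entry")
})

test_that("launch weights and directions follow the source optics", {
  # pencil onto an index-matched medium: weight exactly 1
  m <- sampleLaunch(mcSource("pencil"), 10, n_above = 1, n_entry = 1)
  expect_equal(m[, "w"], rep(1, 10))
  expect_equal(m[, "specular"], rep(0, 10))
  # pencil onto tissue: normal-incidence specular fraction
  m <- sampleLaunch(mcSource("pencil"), 10, n_above = 1, n_entry = 1.4)
  expect_lt(abs(unique(m[, "specular"]) - 0.02778), 1e-5)
  expect_equal(m[, "w"] + m[, "specular"], rep(1, 10))
  # gaussian beam: sd of the launch x equals FWHM / 2.3548 within 2%
  m <- sampleLaunch(mcSource("gaussian_beam", fwhm = 100e-6), 1e5,
                    n_above = 1, n_entry = 1.337, seed = 5)
  expect_equal(stats::sd(m[, "x"]), 100e-6 / 2.3548, tolerance = 0.02)
  # all launches: unit directions, weights in [0, 1]
  srcs <- list(mcSource("pencil"),
               mcSource("uniform_beam", radius = 1e-4),
               mcSource("rectangular", width = 2e-4, height = 1e-4),
               mcSource("isotropic", position = c(0, 0, 1e-4)),
               mcSource("fiber", core_diameter = 200e-6,
                        cladding_diameter = 220e-6, na = 0.22,
                        n_core = 1.462))
  for (s in srcs) {
    m <- sampleLaunch(s, 2000, n_above = 1, n_entry = 1.337, seed = 3)
    nrm <- sqrt(rowSums(m[, c("ux", "uy", "uz")]^2))
    expect_true(all(abs(nrm - 1) < 1e-9))
    expect_true(all(m[, "w"] >= 0 & m[, "w"] <= 1))
  }
})

test_that("fiber launches stay inside the refracted acceptance cone", {
  n_sample <- 1.337
  m <- sampleLaunch(mcSource("fiber", core_diameter = 200e-6,
                             cladding_diameter = 220e-6, na = 0.22,
                             n_core = 1.462),
                    1e4, n_above = 1, n_entry = n_sample, seed = 8)
  sin_s <- sqrt(m[, "ux"]^2 + m[, "uy"]^2)
  expect_true(all(sin_s <= 0.22 / n_sample + 1e-9))
  r <- sqrt(m[, "x"]^2 + m[, "y"]^2)
  expect_true(all(r <= 100e-6 + 1e-12))
  expect_error(mcSource("fiber", core_diameter = 200e-6,
                        cladding_diameter = 150e-6, na = 0.22,
                        n_core = 1.462), "cladding")
  expect_error(mcSource("vortex"), "unsupported")
})

test_that("probe-layout constructors enforce the tight-packing geometry", {
  six <- sixAroundOneLayout(core_diameter = 200e-6,
                            cladding_diameter = 220e-6, na = 0.22,
                            n_core = 1.462, tip_radius = 3e-3)
  expect_length(six$fiber_x, 7)
  d <- as.matrix(stats::dist(cbind(six$fiber_x, six$fiber_y)))
  expect_equal(min(d[d > 0]), 220e-6, tolerance = 1e-12)
  lin <- linearArrayLayout(6, core_diameter = 200e-6,
                           cladding_diameter = 220e-6, na = 0.22,
                           n_core = 1.462, tip_radius = 3e-3)
  expect_length(lin$fiber_x, 6)
  expect_equal(diff(lin$fiber_x), rep(220e-6, 5))
  expect_error(mcLayoutFiberProbe(c(0, 1e-4), c(0, 0), 200e-6, 220e-6,
                                  0.22, 1.462, 1e-3), "overlap")
})

test_that("surface interaction applies housing reflectivity and core optics", {
  probe <- mcLayoutFiberProbe(fiber_x = 0, fiber_y = 0,
                              core_diameter = 200e-6,
                              cladding_diameter = 220e-6,
                              na = 0.22, n_core = 1.462, tip_radius = 1e-3,
                              reflectivity = 0.6)
  up <- list(position = c(5e-4, 0, 0), direction = c(0, 0, -1), weight = 0.5)
  # under the housing: weight times reflectivity, z-direction flipped
  out <- surfaceInteract(probe, up, n_tissue = 1.337)
  expect_equal(out$status, "reflected")
  expect_equal(out$weight, 0.3)
  expect_equal(out$direction[3], 1)
  # zero reflectivity terminates
  probe0 <- mcLayoutFiberProbe(0, 0, 200e-6, 220e-6, 0.22, 1.462, 1e-3,
                               reflectivity = 0)
  expect_equal(surfaceInteract(probe0, up, 1.337)$status, "terminated")
  # under the core: Fresnel against the core index
  core_hit <- list(position = c(0, 0, 0), direction = c(0, 0, -1),
                   weight = 1)
  out <- surfaceInteract(probe, core_hit, n_tissue = 1.337, xi = 0.99)
  expect_equal(out$status, "transmitted_core")
  expect_equal(out$fiber, 1L)
  # uniform layout behaves like the plain boundary
  set.seed(12)
  for (i in 1:25) {
    ct <- runif(1, 0.05, 1)
    st <- sqrt(1 - ct^2); ph <- runif(1, 0, 2 * pi)
    pk <- list(position = c(runif(1, -1e-3, 1e-3), runif(1, -1e-3, 1e-3), 0),
               direction = c(st * cos(ph), st * sin(ph), -ct), weight = 1)
    xi <- runif(1)
    a <- surfaceInteract(mcLayoutUniform(), pk, 1.337, 1.0, xi = xi)
    ev <- fresnel(1.337, 1.0, ct)
    want <- if (is.na(ev$cos_transmitted) || xi < ev$reflectance)
      "reflected" else "escaped"
    expect_equal(a$status, want)
  }
})
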