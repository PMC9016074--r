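test_that("step sampling is exponential with the mean free path", {
  # dermis-like extinction: mean free path 1/(mua+mus) of about 25 um
  mut <- 45.9e2 + 356.5e2
  s <- sampleStep(1e6, mut, seed = 21)
  expect_equal(mean(s), 25e-6, tolerance = 0.1 / 25)
  expect_equal(1 / mut, 24.85e-6, tolerance = 1e-3)
  # -log(xi)/mut at xi = exp(-1) gives exactly one mean free path
  expect_equal(-log(exp(-1)) / mut, 1 / mut)
  # sample mean within 3 sigma for random rates (exponential: sd = mean)
  for (mu in c(10, 1e3, 5e4)) {
    s <- sampleStep(1e5, mu, seed = 31)
    expect_lt(abs(mean(s) - 1 / mu), 3 * (1 / mu) / sqrt(1e5))
  }
  # clear medium: infinite step, signalled not thrown
  expect_true(all(is.infinite(sampleStep(5, 0))))
})

test_that("deposition operations obey their closed forms", {
  # Albedo-Weight
  expect_equal(depositAW(1, 0, 100)$deposited, 0)
  expect_equal(depositAW(0.7, 100, 100), list(deposited = 0.7, surviving = 0))
  d <- depositAW(1, 45.9e2, 45.9e2 + 356.5e2)
  expect_lt(abs(d$deposited - 0.11407), 1e-5)
  expect_identical(d$deposited + d$surviving, 1)
  # Microscopic Beer-Lambert
  expect_equal(depositMBL(1, 100, 0)$deposited, 0)
  expect_equal(depositMBL(1, log(2), 1)$deposited, 0.5)
  # chaining over sub-segments equals one deposition over the summed path
  w <- 1; mua <- 250; lens <- c(1e-4, 3e-4, 2.5e-4, 4e-5)
  for (l in lens) w <- depositMBL(w, mua, l)$surviving
  expect_equal(w, depositMBL(1, mua, sum(lens))$surviving, tolerance = 1e-12)
  # Albedo-Reject: empirical absorption fraction is the single-event albedo
  xi <- rngUniform(1e6, seed = 13)
  frac <- mean(arDecide(xi, 45.9e2, 402.4e2))
  p <- 45.9 / 402.4
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1e6))
  expect_true(all(!arDecide(xi, 0, 100)))
  expect_true(all(arDecide(xi, 100, 100)))
})

test_that("direction update preserves norms and the stated convention", {
  expect_equal(cpp_scatter_direction(c(0, 0, 1), 1, 0.7), c(0, 0, 1))
  expect_equal(cpp_scatter_direction(c(0, 0, 1), 0, 0), c(1, 0, 0),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:2000) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- cpp_scatter_direction(u, runif(1, -1, 1), runif(1, 0, 2 * pi))
    expect_lt(abs(sum(v^2) - 1), 1e-12)
  }
  # deflection angle is the sampled one
  u <- c(0.3, -0.5, sqrt(1 - 0.34)); ct <- -0.4
  v <- cpp_scatter_direction(u, ct, 1.3)
  expect_equal(sum(u * v), ct, tolerance = 1e-12)
})

test_that("Russian roulette conserves expected weight", {
  w <- 5e-5; thr <- 1e-4; m <- 10
  xi <- rngUniform(1e6, seed = 17)
  out <- rouletteSpin(w, thr, m, xi)
  expect_true(all(out %in% c(0, w * m)))
  se <- stats::sd(out) / sqrt(length(xi))
  expect_lt(abs(mean(out) - w), 3 * se)
  # above threshold: unchanged; m = 1: always survives unchanged
  expect_equal(rouletteSpin(0.5, thr, m, 0.99), 0.5)
  expect_equal(rouletteSpin(w, thr, 1, 0.999999), w)
})

test_that("layered transport reproduces the Beer-Lambert limit", {
  # mus = 0, matched indices, mua * d = 1 -> T = exp(-1)
  res <- mcSimulate(matchedSlab(mua = 100, mus = 0, d = 0.01),
                    mcSource("pencil"), 1e5, seed = 23)
  Texp <- exp(-1)
  expect_lt(abs(totalTransmittance(res) - Texp),
            3 * sqrt(Texp * (1 - Texp) / 1e5))
  expect_equal(totalSpecular(res), 0)
})

test_that("energy is conserved packet by packet", {
  stack <- mcLayerStack(list(
    boundingMedium(1.0),
    mcLayer(2.5e2, 300e2, 1.337, 100e-6, pfHG(0.9)),
    mcLayer(1e2, 100e2, 1.337, 1e-3, pfHG(0.7)),
    boundingMedium(1.0)))
  # exact balance with roulette disabled
  res <- mcSimulate(stack, mcSource("pencil"), 2e4, seed = 41,
                    roulette = FALSE, weight_cutoff = 1e-7)
  eb <- energyBalance(res)
  expect_lt(eb$residual, 1e-9)
  expect_lt(abs(eb$total + eb$roulette_net - 1), 1e-9)
  # with roulette: the drift-corrected identity stays exact and the physical
  # sum is within 5 sigma of 1
  res <- mcSimulate(stack, mcSource("pencil"), 5e4, seed = 42)
  eb <- energyBalance(res)
  expect_lt(eb$residual, 1e-9)
  expect_lt(abs(eb$total - 1), 5 * rouletteSigma(res) + 1e-9)
  # no absorption: reflectance + transmittance = 1 up to roulette losses
  res <- mcSimulate(matchedSlab(0, 100e2, 1e-3, g = 0.5),
                    mcSource("pencil"), 2e4, seed = 43, roulette = FALSE,
                    weight_cutoff = 1e-12)
  eb <- energyBalance(res)
  expect_equal(eb$reflectance + eb$transmittance, 1, tolerance = 1e-9)
})

test_that("splitting a layer in two leaves reflectance unchanged", {
  one <- mcLayerStack(list(
    boundingMedium(1.0),
    mcLayer(2.5e2, 150e2, 1.4, 1e-3, pfHG(0.8)),
    boundingMedium(1.0)))
  two <- mcLayerStack(list(
    boundingMedium(1.0),
    mcLayer(2.5e2, 150e2, 1.4, 4e-4, pfHG(0.8)),
    mcLayer(2.5e2, 150e2, 1.4, 6e-4, pfHG(0.8)),
    boundingMedium(1.0)))
  r1 <- mcSimulate(one, mcSource("pencil"), 1e5, seed = 51)
  r2 <- mcSimulate(two, mcSource("pencil"), 1e5, seed = 52)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  for (f in list(totalReflectance, totalTransmittance)) {
    p <- f(r1)
    expect_lt(abs(f(r1) - f(r2)), 3 * sqrt(2) * se(p, 1e5))
  }
})

test_that("voxel transport matches the layered engine on a slab", {
  stack <- mcLayerStack(list(
    boundingMedium(1.0),
    mcLayer(2.5e2, 300e2, 1.337, 100e-6, pfHG(0.9)),
    mcLayer(1e2, 100e2, 1.337, 1e-3, pfHG(0.9)),
    boundingMedium(1.0)))
  vol <- layeredAsVoxels(stack, dz = 10e-6)
  rl <- mcSimulate(stack, mcSource("pencil"), 1e5, seed = 61)
  rv <- mcSimulate(vol, mcSource("pencil"), 1e5, seed = 62)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(totalReflectance(rl) - totalReflectance(rv)),
            3 * sqrt(2) * se(totalReflectance(rl), 1e5))
  expect_lt(abs(totalTransmittance(rl) - totalTransmittance(rv)),
            3 * sqrt(2) * se(totalTransmittance(rl), 1e5))
  expect_lt(energyBalance(rv)$residual, 1e-9)
})

test_that("the three stepping methods deposit the same expected energy", {
  stack <- matchedSlab(5e2, 100e2, 1e-3, g = 0.7, n = 1.337)
  vol <- layeredAsVoxels(stack, dz = 50e-6)
  n <- 5e4
  res <- lapply(c(aw = "aw", ar = "ar", mbl = "mbl"), function(st)
    mcSimulate(vol, mcSource("pencil"), n, seed = 71, stepping = st))
  A <- vapply(res, function(r) r$absorbed / r$n_packets, numeric(1))
  seA <- sqrt(max(A) * (1 - max(A)) / n)
  expect_lt(abs(A[["aw"]] - A[["mbl"]]), 3 * sqrt(2) * seA)
  expect_lt(abs(A[["aw"]] - A[["ar"]]), 3 * sqrt(2) * seA)
  for (r in res) expect_lt(energyBalance(r)$residual, 1e-9)
})

test_that("an empty voxel volume transmits every packet ballistically", {
  vol <- mcVoxelVolume(array(1L, c(3, 3, 10)), c(1e-3, 1e-3, 1e-4),
                       list(list(mua = 0, mus = 0, n = 1, pf = pfHG(0))),
                       n_above = 1, n_below = 1)
  res <- mcSimulate(vol, mcSource("pencil"), 1000, seed = 81)
  expect_equal(totalTransmittance(res), 1)
  expect_equal(totalReflectance(res), 0)
  expect_equal(res$absorbed, 0)
})

test_that("replay with the same seed is bit-identical", {
  stack <- semiInfiniteStack()
  det <- mcDetectors(radial_top = mcRadialDetector(5e-3, 50))
  a <- mcSimulate(stack, mcSource("pencil"), 5e3, seed = 91, detectors = det)
  b <- mcSimulate(stack, mcSource("pencil"), 5e3, seed = 91, detectors = det)
  expect_identical(a$reflected, b$reflected)
  expect_identical(a$absorbed, b$absorbed)
  expect_identical(a$radial_top$raw, b$radial_top$raw)
  # a different seed gives a different stream
  c <- mcSimulate(stack, mcSource("pencil"), 5e3, seed = 92, detectors = det)
  expect_false(identical(a$reflected, c$reflected))
})

test_that("RNG streams are reproducible and statistically sane", {
  expect_identical(rngUniform(100, "ran3", 7), rngUniform(100, "ran3", 7))
  expect_identical(rngUniform(100, "xoshiro", 7), rngUniform(100, "xoshiro", 7))
  for (k in c("xoshiro", "ran3")) {
    u <- rngUniform(2e5, k, 3)
    expect_true(all(u >= 0 & u < 1))
    expect_lt(abs(mean(u) - 0.5), 3 * sqrt(1 / 12 / 2e5))
  }
  # two seeds of the default generator agree within 3 sigma on reflectance
  stack <- semiInfiniteStack()
  r1 <- mcSimulate(stack, mcSource("pencil"), 5e4, seed = 101)
  r2 <- mcSimulate(stack, mcSource("pencil"), 5e4, seed = 202)
  p <- totalReflectance(r1)
  expect_lt(abs(totalReflectance(r1) - totalReflectance(r2)),
            3 * sqrt(2 * p * (1 - p) / 5e4))
})

test_that("the layered engine rejects unsupported stepping methods", {
  expect_error(mcSimulate(semiInfiniteStack(), mcSource("pencil"), 10,
                          stepping = "mbl"), "Albedo-Weight")
  expect_error(mcSimulate(list(), mcSource("pencil"), 10), "geometry")
})
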