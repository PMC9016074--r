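# probe geometry of the sampling-volume configuration: source and detector
# fibers 500 um apart, 200/220 um core/cladding, NA 0.22, housing
# reflectivity 60%
svProbeRun <- function(n, trace) {
  stack <- semiInfiniteStack(mua = 2.5e2, mus = 300e2, g = 0.9,
                             n_above = 1.0)
  layout <- mcLayoutFiberProbe(
    fiber_x = c(0, 500e-6), fiber_y = c(0, 0),
    core_diameter = 200e-6, cladding_diameter = 220e-6,
    na = 0.22, n_core = 1.462, tip_radius = 1e-3, reflectivity = 0.6)
  src <- mcSource("fiber", core_diameter = 200e-6,
                  cladding_diameter = 220e-6, na = 0.22, n_core = 1.462)
  mcSimulate(stack, src, n, seed = 11, layout = layout, trace = trace,
             weight_cutoff = 1e-3)
}

svDetectorFilter <- list(center = c(500e-6, 0), radius = 100e-6,
                         na = 0.22, n_exit = 1.462)

# small run with unfiltered traces (event-structure tests)
svFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- svProbeRun(8e3, mcTrace(1000))
    cache
  }
})

# larger run with recording-time filtering (sampling-volume tests)
svFixtureBig <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- svProbeRun(1.5e5, mcTrace(1000, filter = svDetectorFilter))
    cache
  }
})

test_that("traces record complete, weight-monotone event sequences", {
  res <- svFixture()
  tr <- res$trace
  expect_true(all(tr$n_events <= 1000))
  # launch event first, terminal event last for every traced packet
  first <- tr$type[!duplicated(tr$id)]
  expect_true(all(first == 0L))
  # weights never increase along a packet's trace (roulette is disabled)
  dw <- diff(tr$w)
  same <- diff(tr$id) == 0
  expect_true(all(dw[same] <= 1e-12))
  # terminal records match the last event of non-overflowed packets
  last_idx <- cumsum(tr$n_events)[tr$overflowed == 0 & tr$n_events > 0]
  expect_true(all(tr$type[last_idx] == 3L))
})

test_that("trace filtering equals a brute-force scan of terminal events", {
  res <- svFixture()
  tr <- res$trace
  keep <- filterTraces(res, center = c(500e-6, 0), core_radius = 100e-6,
                       na = 0.22, n_exit = 1.462)
  brute <- tr$fate == 1L & tr$overflowed == 0L &
    (tr$term_x - 500e-6)^2 + tr$term_y^2 <= (100e-6)^2 &
    sqrt(tr$term_ux^2 + tr$term_uy^2) <= 0.22 / 1.462 + 1e-9
  expect_equal(as.logical(keep), brute)
  expect_gt(sum(keep), 0)
  # a detector covering the whole surface with NA = 1 keeps every
  # top-escaping, non-overflowed packet
  all_top <- filterTraces(res)
  expect_equal(sum(all_top), sum(tr$fate == 1L & tr$overflowed == 0L))
  # zero-radius detector keeps nothing
  none <- filterTraces(res, center = c(0, 0), core_radius = 0)
  expect_equal(sum(none), 0)
})

test_that("sampling volumes conserve path length times terminal weight", {
  res <- svFixtureBig()
  keep <- filterTraces(res, center = c(500e-6, 0), core_radius = 100e-6,
                       na = 0.22, n_exit = 1.462)
  sv <- computeSamplingVolume(res, keep,
                              xlim = c(-0.5e-3, 1e-3),
                              ylim = c(-0.5e-3, 0.5e-3),
                              zlim = c(0, 1e-3), nx = 30, ny = 20, nz = 20)
  expect_true(all(sv$value >= 0))
  # independent R-side accounting of clipped in-grid path length
  tr <- res$trace
  wterm <- attr(keep, "terminal_weight")
  total <- 0
  inb <- function(p) all(p >= c(-0.5e-3, -0.5e-3, 0)) &&
    all(p < c(1e-3, 0.5e-3, 1e-3))
  for (pid in which(keep) - 1L) {
    idx <- which(tr$id == pid)
    P <- cbind(tr$x[idx], tr$y[idx], tr$z[idx])
    for (j in seq_len(nrow(P) - 1)) {
      a <- P[j, ]; b <- P[j + 1, ]
      L <- sqrt(sum((b - a)^2))
      if (L == 0) next
      # sub-sample the segment to estimate its in-grid fraction exactly
      # enough for segments that never touch the grid faces laterally
      if (inb(a) && inb(b)) total <- total + L * wterm[pid + 1]
      else {
        tt <- seq(0, 1, length.out = 201)
        frac <- mean(vapply(tt, function(s) inb(a + s * (b - a)), logical(1)))
        total <- total + L * frac * wterm[pid + 1]
      }
    }
  }
  expect_equal(sum(sv$value), sv$in_grid, tolerance = 1e-12)
  expect_equal(sv$in_grid, total, tolerance = 2e-3)
})

test_that("a straight vertical trace deposits its length in each voxel", {
  # synthetic one-packet trace: straight down through the grid
  res <- svFixture()
  fake <- res
  fake$n_packets <- 1
  fake$trace <- list(
    id = rep(0L, 2), type = c(0L, 3L),
    x = c(1e-6, 1e-6), y = c(1e-6, 1e-6), z = c(0, 1e-3),
    ux = c(0, 0), uy = c(0, 0), uz = c(1, 1), w = c(1, 0.25),
    fate = 2L, n_events = 2L, overflowed = 0L,
    term_x = 1e-6, term_y = 1e-6, term_z = 1e-3,
    term_ux = 0, term_uy = 0, term_uz = 1, term_w = 0.25)
  sv <- computeSamplingVolume(fake, TRUE, xlim = c(-5e-4, 5e-4),
                              ylim = c(-5e-4, 5e-4), zlim = c(0, 1e-3),
                              nx = 2, ny = 2, nz = 10)
  nonzero <- sv$value[sv$value > 0]
  expect_length(nonzero, 10)
  expect_equal(unname(nonzero), rep(1e-4 * 0.25, 10), tolerance = 1e-6)
  # empty filtered set gives an all-zero volume
  sv0 <- computeSamplingVolume(fake, FALSE, xlim = c(-5e-4, 5e-4),
                               ylim = c(-5e-4, 5e-4), zlim = c(0, 1e-3),
                               nx = 2, ny = 2, nz = 10)
  expect_true(all(sv0$value == 0))
})

test_that("coarsening the grid twofold preserves the voxelized mass", {
  res <- svFixtureBig()
  keep <- filterTraces(res, center = c(500e-6, 0), core_radius = 100e-6,
                       na = 0.22, n_exit = 1.462)
  fine <- computeSamplingVolume(res, keep, c(-0.5e-3, 1e-3),
                                c(-0.5e-3, 0.5e-3), c(0, 1e-3), 20, 10, 16)
  coarse <- computeSamplingVolume(res, keep, c(-0.5e-3, 1e-3),
                                  c(-0.5e-3, 0.5e-3), c(0, 1e-3), 10, 5, 8)
  agg <- array(0, c(10, 5, 8))
  for (i in 1:10) for (j in 1:5) for (k in 1:8)
    agg[i, j, k] <- sum(fine$value[(2 * i - 1):(2 * i),
                                   (2 * j - 1):(2 * j),
                                   (2 * k - 1):(2 * k)])
  expect_equal(agg, coarse$value, tolerance = 1e-9)
})

test_that("the probe sampling volume concentrates between the fibers", {
  res <- svFixtureBig()
  keep <- filterTraces(res, center = c(500e-6, 0), core_radius = 100e-6,
                       na = 0.22, n_exit = 1.462)
  sv <- computeSamplingVolume(res, keep, c(-1e-3, 1.5e-3), c(-1e-3, 1e-3),
                              c(0, 1.5e-3), nx = 50, ny = 20, nz = 15)
  xc <- -1e-3 + (seq_len(50) - 0.5) * (2.5e-3 / 50)
  mass_x <- apply(sv$value, 1, sum)
  between <- xc >= 0 & xc <= 500e-6
  expect_gt(sum(mass_x[between]), sum(mass_x[!between]))
  # y-averaged volume is mirror-symmetric about the fiber axis plane
  yc <- -1e-3 + (seq_len(20) - 0.5) * 1e-4
  mass_y <- apply(sv$value, 2, sum)
  asym <- abs(sum(mass_y[yc > 0]) - sum(mass_y[yc < 0])) /
    (sum(mass_y) + 1e-300)
  expect_lt(asym, 0.2)
})
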