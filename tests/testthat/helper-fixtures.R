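# shared fixtures built in code

# single semi-infinite layer of tissue-like properties
semiInfiniteStack <- function(mua = 2.5e2, mus = 300e2, g = 0.9, n = 1.337,
                              n_above = 1.0) {
  mcLayerStack(list(
    boundingMedium(n_above),
    mcLayer(mua, mus, n, Inf, pfHG(g)),
    boundingMedium(n)))
}

# finite slab with matched indices (conservation / closed-form checks)
matchedSlab <- function(mua, mus, d, g = 0, n = 1.0) {
  mcLayerStack(list(
    boundingMedium(n),
    mcLayer(mua, mus, n, d, pfHG(g)),
    boundingMedium(n)))
}

# laterally homogeneous voxel version of a one- or two-layer stack
layeredAsVoxels <- function(stack, dz = 10e-6) {
  zb <- stack$z_bottom
  nz <- round(zb[length(zb)] / dz)
  labels <- array(0L, c(1, 1, nz))
  zc <- (seq_len(nz) - 0.5) * dz
  labels[1, 1, ] <- locateLayer(stack, zc)
  mats <- lapply(stack$layers, function(l)
    list(mua = l$mua, mus = l$mus, n = l$n, pf = l$pf))
  mcVoxelVolume(array(as.integer(labels), dim(labels)), c(2, 2, dz), mats,
                n_above = stack$n_above, n_below = stack$n_below)
}

# standard deviation (relative to N) of the roulette-induced energy-balance
# drift: each roulette event at weight ~ w0 has outcomes -w0 (p = 1 - 1/m)
# or +(m-1) w0 (p = 1/m), zero mean and variance (m-1) w0^2; the event count
# is recovered from the recorded killed/boost totals
rouletteSigma <- function(res) {
  m <- res$config$roulette_m
  w0 <- res$config$roulette_threshold
  n_ev <- res$roulette_killed / w0 +
    res$roulette_boost / ((m - 1) * w0) + 1
  sqrt((m - 1) * w0^2 * n_ev) / res$n_packets
}

# analytic inverse CDF of the Henyey-Greenstein deflection cosine
hgInverse <- function(g, xi) {
  if (g == 0) return(2 * xi - 1)
  (1 + g^2 - ((1 - g^2) / (1 - g + 2 * g * xi))^2) / (2 * g)
}
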