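#' Weight-deposition stepping operations
#'
#' The elementary deposition rules of the three packet stepping methods, as
#' applied inside the transport kernels.
#'
#' `depositAW()` — Albedo-Weight: at each extinction event the fraction
#' `mua/mut` of the packet weight is deposited and the rest survives;
#' deposited + surviving equals the input weight exactly.
#'
#' `depositMBL()` — Microscopic Beer-Lambert: along a path segment of length
#' `path` the deposited weight is `w * (1 - exp(-mua * path))` and the
#' survivor carries `w * exp(-mua * path)`; chaining over sub-segments is
#' exactly equivalent to one deposition over the summed path.
#'
#' `arDecide()` — Albedo-Reject: the packet is absorbed (full weight
#' deposited, packet terminated) with probability `mua/mut`.
#'
#' `rouletteSpin()` — Russian roulette: a packet below the weight threshold
#' survives with probability `1/m` carrying `m` times its weight, otherwise
#' it is terminated; the expected weight is conserved.
#'
#' @param w packet weight(s).
#' @param mua absorption coefficient (1/m), `0 <= mua <= mut`.
#' @param mut extinction coefficient (1/m), `> 0`.
#' @param path path length (m), `>= 0`.
#' @param xi uniform deviate(s) in `[0, 1)`.
#' @param threshold roulette weight threshold in `(0, 1)`.
#' @param m roulette multiplier, `>= 1`.
#' @return `depositAW()`/`depositMBL()`: list with `deposited` and
#'   `surviving`; `arDecide()`: logical (absorbed?); `rouletteSpin()`: the
#'   post-roulette weight(s) (0 for terminated packets).
#' @examples
#' depositAW(1, 45.9e2, 45.9e2 + 356.5e2)$deposited  # 0.11407
#' depositMBL(1, log(2), 1)$deposited                # 0.5
#' @export
depositAW <- function(w, mua, mut) {
  stopifnot(mua >= 0, mut > 0, mua <= mut)
  d <- w * mua / mut
  list(deposited = d, surviving = w - d)
}

#' @rdname depositAW
#' @export
depositMBL <- function(w, mua, path) {
  stopifnot(mua >= 0, all(path >= 0))
  d <- w * (1 - exp(-mua * path))
  list(deposited = d, surviving = w - d)
}

#' @rdname depositAW
#' @export
arDecide <- function(xi, mua, mut) {
  stopifnot(mua >= 0, mut > 0, mua <= mut)
  xi < mua / mut
}

#' @rdname depositAW
#' @export
rouletteSpin <- function(w, threshold, m, xi) {
  stopifnot(threshold > 0, threshold < 1, m >= 1)
  k <- max(length(w), length(xi))
  w <- rep_len(w, k); xi <- rep_len(xi, k)
  ifelse(w >= threshold, w, ifelse(xi < 1 / m, w * m, 0))
}
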