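#' Filter photon-packet traces by a detector-fiber criterion
#'
#' Keeps the packets whose terminal position lies within the detector core
#' and whose terminal direction passes the numerical-aperture acceptance test
#' (`sin(exit angle) <= na / n_exit`, the exit direction taken after the
#' final boundary transmission). Packets that overflowed the trace capacity
#' or did not escape through the top surface are dropped.
#'
#' @param result an `mc_result` from a trace-enabled [mcSimulate()] run.
#' @param center length-2 detector-fiber center (m); `NULL` accepts any
#'   position.
#' @param core_radius detector core radius (m); `Inf` accepts any position.
#' @param na detector numerical aperture (in air); 1 accepts all directions.
#' @param n_exit refractive index of the medium the terminal direction lives
#'   in (the fiber core when a probe layout collected the packet, otherwise
#'   the surrounding medium).
#' @return logical vector over packets: `TRUE` for retained packets. The
#'   attribute `"terminal_weight"` carries each packet's terminal weight.
#' @export
filterTraces <- function(result, center = c(0, 0), core_radius = Inf,
                         na = 1, n_exit = 1) {
  stopifnot(inherits(result, "mc_result"))
  tr <- result$trace
  if (is.null(tr)) stop("this result holds no trace")
  keep <- tr$fate == 1L & tr$overflowed == 0L
  if (is.finite(core_radius)) {
    keep <- keep & ((tr$term_x - center[1])^2 + (tr$term_y - center[2])^2 <=
                      core_radius^2)
  }
  if (na < 1) {
    sin_exit <- sqrt(tr$term_ux^2 + tr$term_uy^2)
    keep <- keep & (sin_exit <= na / n_exit + 1e-9)
  }
  structure(keep, terminal_weight = tr$term_w)
}

#' Voxelize filtered traces into a sampling volume
#'
#' Transforms a set of filtered packet traces into a voxelated sampling
#' volume: each voxel accumulates the exact path length that the retained
#' packets travelled inside it, multiplied by the packet's terminal weight.
#' The sampling volume is the 3D heat map of where the light collected by a
#' detector actually travelled between source and detector.
#'
#' @param result a trace-enabled `mc_result`.
#' @param keep logical vector from [filterTraces()].
#' @param xlim,ylim,zlim grid extents (m).
#' @param nx,ny,nz voxel counts.
#' @return an `mc_sampling_volume`: 3D array `value` (path length x weight,
#'   m), `in_grid`/`out_grid` totals, grid metadata.
#' @export
computeSamplingVolume <- function(result, keep, xlim, ylim, zlim,
                                  nx, ny, nz) {
  stopifnot(inherits(result, "mc_result"), !is.null(result$trace),
            length(keep) == result$n_packets)
  tr <- result$trace
  grid <- list(x0 = xlim[1], dx = diff(xlim) / nx, nx = as.integer(nx),
               y0 = ylim[1], dy = diff(ylim) / ny, ny = as.integer(ny),
               z0 = zlim[1], dz = diff(zlim) / nz, nz = as.integer(nz))
  out <- cpp_compute_sv(tr$id, tr$x, tr$y, tr$z, as.logical(keep),
                        tr$term_w, grid)
  structure(list(
    value = array(out$sv, c(nx, ny, nz)),
    in_grid = out$in_grid, out_grid = out$out_grid,
    grid = grid, n_kept = sum(keep), n_packets = result$n_packets
  ), class = "mc_sampling_volume")
}

#' @export
print.mc_sampling_volume <- function(x, ...) {
  cat(sprintf(
    "<mc_sampling_volume> %dx%dx%d voxels, %d packet(s) kept, total %g m\n",
    x$grid$nx, x$grid$ny, x$grid$nz, x$n_kept, sum(x$value)))
  invisible(x)
}
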