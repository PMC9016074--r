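#' Serialize and reload simulation results
#'
#' Results are stored as a single JSON document: one section per
#' detector/accumulator holding raw weights and bin edges, plus metadata
#' (launch count N, seed, engine, stepping, RNG and a declarative echo of the
#' detector geometry). Normalized views are recomputed on demand after
#' loading; the raw weights are always the stored quantity.
#'
#' @param result an `mc_result`.
#' @param path output file path (`.json`).
#' @return `saveResult()`: `path` invisibly; `loadResult()`: an `mc_result`
#'   (trace buffers and function-valued config entries are not round-tripped;
#'   totals, accumulators and normalization metadata are).
#' @export
saveResult <- function(result, path) {
  stopifnot(inherits(result, "mc_result"))
  det <- result$config$detectors
  doc <- list(
    container = "turbidmc-result", version = 1L,
    n_packets = result$n_packets, seed = result$seed,
    engine = result$engine, stepping = result$stepping, rng = result$rng,
    totals = list(
      specular = result$specular, reflected = result$reflected,
      transmitted = result$transmitted, absorbed = result$absorbed,
      lateral = result$lateral, layout_absorbed = result$layout_absorbed,
      roulette_killed = result$roulette_killed,
      roulette_boost = result$roulette_boost,
      cutoff_killed = result$cutoff_killed),
    accumulators = list()
  )
  for (side in c("top", "bottom")) {
    nm <- paste0("radial_", side)
    if (!is.null(result[[nm]]))
      doc$accumulators[[nm]] <- list(
        edges = det[[nm]]$edges, raw = result[[nm]]$raw,
        cos_min = det[[nm]]$cos_min,
        discarded = result[[nm]]$discarded, overflow = result[[nm]]$overflow)
    cm <- paste0("cartesian_", side)
    if (!is.null(result[[cm]]))
      doc$accumulators[[cm]] <- c(
        det[[cm]][c("x0", "dx", "nx", "y0", "dy", "ny", "cos_min", "tilt")],
        list(raw = result[[cm]]$raw, discarded = result[[cm]]$discarded,
             overflow = result[[cm]]$overflow))
  }
  if (!is.null(result$fiber_top))
    doc$accumulators$fiber_top <- list(
      cx = det$fiber_top$cx, cy = det$fiber_top$cy,
      core_radius = det$fiber_top$core_radius, na = det$fiber_top$na,
      raw = result$fiber_top$raw, discarded = result$fiber_top$discarded)
  if (!is.null(result$fluence)) {
    g <- result$config$fluence
    doc$accumulators$fluence <- c(
      g[c("x0", "dx", "nx", "y0", "dy", "ny", "z0", "dz", "nz", "mode")],
      list(raw = result$fluence$raw, offgrid = result$fluence$offgrid))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname saveResult
#' @export
loadResult <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$container, "turbidmc-result"))
    stop("not a turbidmc result container: ", path)
  res <- list(
    n_packets = doc$n_packets, seed = doc$seed, engine = doc$engine,
    stepping = doc$stepping, rng = doc$rng,
    specular = doc$totals$specular, reflected = doc$totals$reflected,
    transmitted = doc$totals$transmitted, absorbed = doc$totals$absorbed,
    lateral = doc$totals$lateral %||% 0,
    layout_absorbed = doc$totals$layout_absorbed %||% 0,
    roulette_killed = doc$totals$roulette_killed %||% 0,
    roulette_boost = doc$totals$roulette_boost %||% 0,
    cutoff_killed = doc$totals$cutoff_killed %||% 0)
  det <- list()
  acc <- doc$accumulators
  for (nm in c("radial_top", "radial_bottom")) {
    if (!is.null(acc[[nm]])) {
      res[[nm]] <- list(raw = acc[[nm]]$raw, discarded = acc[[nm]]$discarded,
                        overflow = acc[[nm]]$overflow)
      det[[nm]] <- list(edges = acc[[nm]]$edges, cos_min = acc[[nm]]$cos_min)
    }
  }
  for (nm in c("cartesian_top", "cartesian_bottom")) {
    if (!is.null(acc[[nm]])) {
      res[[nm]] <- list(raw = acc[[nm]]$raw, discarded = acc[[nm]]$discarded,
                        overflow = acc[[nm]]$overflow)
      det[[nm]] <- acc[[nm]][c("x0", "dx", "nx", "y0", "dy", "ny",
                               "cos_min", "tilt")]
    }
  }
  if (!is.null(acc$fiber_top)) {
    res$fiber_top <- list(raw = acc$fiber_top$raw,
                          discarded = acc$fiber_top$discarded)
    det$fiber_top <- acc$fiber_top[c("cx", "cy", "core_radius", "na")]
  }
  cfg <- list(detectors = det)
  if (!is.null(acc$fluence)) {
    res$fluence <- list(raw = acc$fluence$raw, offgrid = acc$fluence$offgrid)
    cfg$fluence <- acc$fluence[c("x0", "dx", "nx", "y0", "dy", "ny",
                                 "z0", "dz", "nz", "mode")]
  }
  res$config <- cfg
  class(res) <- "mc_result"
  res
}

#' Export a 1D profile or spectrum to delimited text
#'
#' @param x a data frame (e.g. from [normalizeRadial()] or [hankelSRR()]).
#' @param path output path.
#' @export
exportTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
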