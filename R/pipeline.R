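#' Decode an ISS image stack end to end
#'
#' Runs the full decoding chain on one (registered) stack: normalization,
#' per-cycle/channel spot detection, signal probability prediction, cross-
#' channel merging, detection-graph construction, min-cost max-flow solving,
#' barcode decoding and quality scoring. When `sigma` is `NULL` the distance
#' penalty weight is calibrated on the decoded reads themselves (on-target vs
#' `UNEXPECTED`), falling back to `fallback_sigma` when only one class is
#' present.
#'
#' @param stack A raw `iss_stack`.
#' @param cb An [codebook()].
#' @param model An `iss_signal_model` (see [train_signal_model()]).
#' @param h,tophat_radius Detection parameters ([detect_candidates()]).
#' @param k,d_th,d_max Graph parameters ([build_detection_graph()]).
#' @param sigma Distance-penalty weight, or `NULL` to calibrate.
#' @param fallback_sigma Used when calibration is impossible or unreliable
#'   (fewer than `min_calibration_reads` reads in either class; an AUC
#'   landscape estimated from a handful of off-target reads is noise).
#' @param min_calibration_reads Minimum reads per class for calibration.
#' @param quality_threshold Passed to [filter_reads()] for the `filtered`
#'   element; the full scored read set is returned too.
#' @param n_patches,norm_seed Normalization sampling parameters.
#' @return An `iss_decode_result` list: `reads` (all scored reads),
#'   `filtered` (quality-filtered, on-target reads), `candidates` (merged
#'   candidate tibble), `graph`, `norm_stats`, `calibration` (or `NULL`) and
#'   the parameters used.
#' @export
decode_stack <- function(stack, cb, model,
                         h = 0.2, tophat_radius = 2,
                         k = 1, d_th = 2, d_max = 3,
                         sigma = NULL, fallback_sigma = 3,
                         min_calibration_reads = 50,
                         quality_threshold = 2,
                         n_patches = 50, norm_seed = 1L) {
  stats <- estimate_normalization(stack, n_patches = n_patches,
                                  patch_size = min(128, stack$dim),
                                  seed = norm_seed)
  norm <- normalize_stack(stack, stats)
  dets <- list()
  for (cyc in seq_len(n_cycles(norm))) {
    for (ch in iss_bases()) {
      dets[[length(dets) + 1L]] <-
        detect_candidates(stack_image(norm, cyc, ch), h = h,
                          tophat_radius = tophat_radius,
                          cycle = cyc, channel = ch)
    }
  }
  cand <- dplyr::bind_rows(dets)
  cand$id <- seq_len(nrow(cand))
  cand <- predict_signal_prob(model, cand, norm)
  merged <- dplyr::bind_rows(purrr::map(
    split(cand, cand$cycle), merge_channels))
  graph <- build_detection_graph(merged, k = k, d_th = d_th, d_max = d_max,
                                 n_cycles = n_cycles(norm))
  paths <- solve_detection_graph(graph)
  reads <- decode_reads(paths, merged, cb)
  calibration <- NULL
  if (nrow(reads) > 0) {
    reads <- score_reads(reads, merged, sigma = fallback_sigma)
    if (is.null(sigma)) {
      lab <- reads$gene != "UNEXPECTED"
      if (min(sum(lab), sum(!lab)) >= min_calibration_reads) {
        calibration <- calibrate_sigma(reads)
        sigma <- calibration$sigma
      } else {
        sigma <- fallback_sigma
      }
    }
    reads$mu <- distance_penalty(reads$max_pair_distance, sigma)
    reads$quality <- reads$mu * reads$base_quality_sum
    filtered <- filter_reads(reads, quality_threshold)
  } else {
    sigma <- if (is.null(sigma)) fallback_sigma else sigma
    filtered <- reads
  }
  structure(list(
    reads = reads, filtered = filtered, candidates = merged, graph = graph,
    norm_stats = stats, calibration = calibration,
    params = list(h = h, tophat_radius = tophat_radius, k = k, d_th = d_th,
                  d_max = d_max, sigma = sigma,
                  quality_threshold = quality_threshold)
  ), class = "iss_decode_result")
}

#' @export
print.iss_decode_result <- function(x, ...) {
  cat(sprintf(
    "<iss_decode_result> %d reads (%d on-target after Q >= %g), sigma = %.3f\n",
    nrow(x$reads), nrow(x$filtered), x$params$quality_threshold,
    x$params$sigma))
  invisible(x)
}

#' Write decoded reads to CSV
#'
#' Per-base qualities are serialized as a semicolon-separated string.
#'
#' @param reads Scored read tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_reads <- function(reads, path) {
  df <- as.data.frame(reads[, setdiff(names(reads), c("path", "per_base_quality"))])
  if ("per_base_quality" %in% names(reads)) {
    df$per_base_quality <- vapply(
      reads$per_base_quality,
      function(q) paste(formatC(q, digits = 6, format = "g"), collapse = ";"),
      character(1))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
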