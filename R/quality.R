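#' Per-base quality of a decoded detection
#'
#' When other detections were merged away in the same cycle with a signal
#' probability above the competitor floor (0.5), the base quality is the
#' detection's intensity-probability product relative to its strongest
#' competitor:
#' `Q_sb = I * p / (I * p + max(I_c * p_c))`;
#' with no such competitor it is simply the detection's probability `p`.
#'
#' @param intensity,p Intensity and signal probability of the decoded
#'   detection (`intensity >= 0`).
#' @param comp_intensity,comp_p Vectors of competitor intensities and
#'   probabilities (already restricted to competitors with `p > 0.5`); may be
#'   empty.
#' @return A quality in \[0, 1\].
#' @export
base_quality <- function(intensity, p, comp_intensity = numeric(0),
                         comp_p = numeric(0)) {
  if (intensity < 0 || any(comp_intensity < 0)) stop("negative intensity")
  stopifnot(length(comp_intensity) == length(comp_p))
  if (length(comp_intensity) == 0) return(p)
  ip <- intensity * p
  ip / (ip + max(comp_intensity * comp_p))
}

#' Distance penalty of a decoded sequence
#'
#' `mu_s = 1 - log(1 + d) / sigma`, clipped to \[0, 1\], where `d` is the
#' maximum distance between the detections forming the sequence. Natural log
#' throughout, consistent with the graph edge weights.
#'
#' @param max_pair_distance Maximum pairwise detection distance in pixels.
#' @param sigma Positive penalty weight.
#' @return A penalty in \[0, 1\]; `mu_s(0) = 1`.
#' @export
distance_penalty <- function(max_pair_distance, sigma) {
  stopifnot(all(max_pair_distance >= 0), sigma > 0)
  pmin(pmax(1 - log1p(max_pair_distance) / sigma, 0), 1)
}

#' Read quality from per-base qualities and the distance penalty
#'
#' `Q_s = mu_s * sum(Q_sb)`, ranging over \[0, n_cycles\].
#'
#' @param base_qualities Numeric vector of per-base qualities.
#' @param mu Distance penalty from [distance_penalty()].
#' @return The read quality.
#' @export
read_quality <- function(base_qualities, mu) {
  mu * sum(base_qualities)
}

#' Attach quality scores to decoded reads
#'
#' For every read and cycle, competitors are the candidates merged away from
#' the path detection in that cycle whose signal probability exceeds
#' `competitor_floor`; the per-base quality, distance penalty and read
#' quality are computed from them. The base-quality sum is stored separately
#' so that re-scoring at a different `sigma` only rescales the penalty.
#'
#' @param reads Read tibble from [decode_reads()].
#' @param candidates The (merged) candidate tibble with a `merged_from`
#'   list-column carrying suppressed candidates with `intensity` and `p`.
#' @param sigma Distance-penalty weight.
#' @param competitor_floor Minimum competitor probability (0.5).
#' @return `reads` with `per_base_quality` (list-column), `base_quality_sum`,
#'   `mu` and `quality` columns.
#' @export
score_reads <- function(reads, candidates, sigma, competitor_floor = 0.5) {
  stopifnot(sigma > 0)
  has_merge <- "merged_from" %in% names(candidates)
  pbq <- purrr::map(reads$path, function(ids) {
    cd <- candidates[match(ids, candidates$id), ]
    cd <- cd[order(cd$cycle), ]
    vapply(seq_len(nrow(cd)), function(b) {
      comp_i <- numeric(0); comp_p <- numeric(0)
      if (has_merge) {
        mf <- cd$merged_from[[b]]
        if (!is.null(mf) && nrow(mf)) {
          keep <- !is.na(mf$p) & mf$p > competitor_floor
          comp_i <- mf$intensity[keep]; comp_p <- mf$p[keep]
        }
      }
      base_quality(cd$intensity[b], cd$p[b], comp_i, comp_p)
    }, numeric(1))
  })
  reads$per_base_quality <- pbq
  reads$base_quality_sum <- vapply(pbq, sum, numeric(1))
  reads$mu <- distance_penalty(reads$max_pair_distance, sigma)
  reads$quality <- reads$mu * reads$base_quality_sum
  reads
}

#' Calibrate the distance-penalty weight by ROC AUC
#'
#' Reads matching the codebook are the positive class and `UNEXPECTED`
#' barcodes the negative class; for every `sigma` on the grid the read
#' qualities are recomputed and their ability to separate the classes is
#' measured by the area under the ROC curve. The `sigma` with maximal AUC is
#' returned (smallest on ties).
#'
#' @param reads Scored reads (from [score_reads()]); must contain both
#'   on-target and `UNEXPECTED` reads.
#' @param sigma_grid Numeric grid of candidate `sigma` values; the default is
#'   20 log-spaced values in \[0.5, 10\].
#' @return An `iss_sigma_calibration` list: `sigma` (the optimum), `auc`, and
#'   `table` (tibble of `sigma`, `auc`).
#' @export
calibrate_sigma <- function(reads,
                            sigma_grid = exp(seq(log(0.5), log(10),
                                                 length.out = 20))) {
  stopifnot(length(sigma_grid) >= 1)
  if (!"base_quality_sum" %in% names(reads)) {
    stop("reads must be scored first (score_reads)")
  }
  lab <- reads$gene != "UNEXPECTED"
  if (length(unique(lab)) < 2) {
    stop("sigma calibration needs both on-target and UNEXPECTED reads")
  }
  aucs <- vapply(sigma_grid, function(s) {
    q <- distance_penalty(reads$max_pair_distance, s) * reads$base_quality_sum
    as.numeric(pROC::auc(pROC::roc(response = lab, predictor = q,
                                   levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE)))
  }, numeric(1))
  best <- which(aucs >= max(aucs) - 1e-12)[1]
  structure(list(sigma = sigma_grid[best], auc = aucs[best],
                 table = tibble::tibble(sigma = sigma_grid, auc = aucs)),
            class = "iss_sigma_calibration")
}

#' @export
print.iss_sigma_calibration <- function(x, ...) {
  cat(sprintf("<iss_sigma_calibration> sigma* = %.3f (AUC %.3f) over %d grid points\n",
              x$sigma, x$auc, nrow(x$table)))
  invisible(x)
}

#' Filter reads by quality and codebook membership
#'
#' Keeps reads with `quality >= quality_threshold` (boundary inclusive) whose
#' barcode matched the codebook.
#'
#' @param reads Scored reads.
#' @param quality_threshold Minimum read quality; the conventional value for
#'   4-5 cycle experiments is 2.
#' @return The filtered read tibble.
#' @export
filter_reads <- function(reads, quality_threshold = 2) {
  if (!"quality" %in% names(reads)) stop("reads must be scored first (score_reads)")
  reads[reads$quality >= quality_threshold & reads$gene != "UNEXPECTED", ]
}

#' Write a QC report as YAML
#'
#' @param reads Scored reads.
#' @param calibration Optional `iss_sigma_calibration`.
#' @param path Output YAML path.
#' @param breaks Quality histogram breakpoints.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(reads, calibration = NULL, path,
                            breaks = seq(0, ceiling(max(reads$quality, 1)), by = 0.5)) {
  h <- graphics::hist(reads$quality, breaks = breaks, plot = FALSE)
  rep <- list(
    n_reads = nrow(reads),
    n_on_target = sum(reads$gene != "UNEXPECTED"),
    n_unexpected = sum(reads$gene == "UNEXPECTED"),
    quality_histogram = list(breaks = as.numeric(h$breaks),
                             counts = as.integer(h$counts))
  )
  if (!is.null(calibration)) {
    rep$sigma <- calibration$sigma
    rep$auc <- calibration$auc
    rep$auc_table <- purrr::pmap(calibration$table, list)
  }
  yaml::write_yaml(rep, path)
  invisible(path)
}
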