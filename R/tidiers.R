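#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL

#' Tidy a decoding result into its read table
#' @param x An `iss_decode_result`.
#' @param filtered Return only quality-filtered on-target reads?
#' @param ... Unused.
#' @return A tibble of reads.
#' @export
tidy.iss_decode_result <- function(x, filtered = FALSE, ...) {
  if (filtered) x$filtered else x$reads
}

#' One-row summary of a decoding result
#' @param x An `iss_decode_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.iss_decode_result <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_reads = nrow(x$reads),
    n_filtered = nrow(x$filtered),
    n_unexpected = sum(x$reads$gene == "UNEXPECTED"),
    sigma = x$params$sigma,
    quality_threshold = x$params$quality_threshold
  )
}

#' Tidy a signal model's coefficients
#' @param x An `iss_signal_model`.
#' @param ... Unused.
#' @return A tibble of `term`, `estimate`.
#' @export
tidy.iss_signal_model <- function(x, ...) {
  terms <- c("(Intercept)", paste0("px", 1:25), "center", "max", "mean", "sd")
  tibble::tibble(term = terms, estimate = as.numeric(x$beta))
}

#' One-row summary of a signal model
#' @param x An `iss_signal_model`.
#' @param ... Unused.
#' @return A one-row tibble with training AUC and sizes.
#' @export
glance.iss_signal_model <- function(x, ...) {
  tibble::tibble(training_auc = x$training_auc, n_examples = x$n_examples,
                 lambda = x$lambda, seed = x$seed)
}

#' Tidy compartment labels
#' @param x An `iss_compartments`.
#' @param ... Unused.
#' @return The labels tibble (`sample`, `patch`, `cluster`).
#' @export
tidy.iss_compartments <- function(x, ...) x$labels

#' One-row summary of a compartment map
#' @param x An `iss_compartments`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.iss_compartments <- function(x, ...) {
  tibble::tibble(n_patches = nrow(x$labels), n_clusters = x$n_clusters,
                 resolution = x$params$resolution, k = x$params$k)
}

#' Tidy a sigma calibration table
#' @param x An `iss_sigma_calibration`.
#' @param ... Unused.
#' @return The (`sigma`, `auc`) tibble.
#' @export
tidy.iss_sigma_calibration <- function(x, ...) x$table

#' Tidy a patch expression matrix into long form
#' @param x An `iss_patch_expr`.
#' @param ... Unused.
#' @return A long tibble (`patch`, `gene`, `count`, and `value` if
#'   normalized).
#' @export
tidy.iss_patch_expr <- function(x, ...) {
  out <- tibble::tibble(
    patch = rep(x$patches$patch, times = ncol(x$counts)),
    gene = rep(x$genes, each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  if (!is.null(x$values)) out$value <- as.numeric(x$values)
  out
}

#' Tidy a KL match table into long pair form
#' @param x An `iss_kl_table`.
#' @param ... Unused.
#' @return A tibble (`iss_gene`, `ref_gene`, `kl`).
#' @export
tidy.iss_kl_table <- function(x, ...) {
  tibble::tibble(
    iss_gene = rep(rownames(x$kl), times = ncol(x$kl)),
    ref_gene = rep(colnames(x$kl), each = nrow(x$kl)),
    kl = as.vector(x$kl)
  )
}
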