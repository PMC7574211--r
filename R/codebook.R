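#' Build a codebook mapping genes to barcodes
#'
#' The codebook maps each targeted gene to a fixed-length barcode over
#' \{A, C, G, T\}; cycle b of the imaging series reads out letter b of the
#' barcode. Gene names and barcodes must both be unique and all barcodes must
#' share one length.
#'
#' @param genes Character vector of gene names.
#' @param barcodes Character vector of barcodes, same length as `genes`.
#' @return A tibble with columns `gene` and `barcode`, class `iss_codebook`.
#' @examples
#' codebook(c("g1", "g2"), c("ACGT", "TGCA"))
#' @export
codebook <- function(genes, barcodes) {
  stopifnot(length(genes) == length(barcodes))
  genes <- as.character(genes); barcodes <- toupper(as.character(barcodes))
  if (anyDuplicated(genes)) stop("gene names must be unique")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  if (length(barcodes)) {
    len <- unique(nchar(barcodes))
    if (length(len) != 1) stop("all barcodes must have the same length")
    if (any(grepl("[^ACGT]", barcodes))) stop("barcodes may only use A, C, G, T")
  }
  out <- tibble::tibble(gene = genes, barcode = barcodes)
  class(out) <- c("iss_codebook", class(out))
  out
}

#' Design a channel-balanced barcode panel
#'
#' Constructs a codebook whose letter usage is as even as possible at every
#' cycle position, the way practical ISS panels are designed: unbalanced
#' panels leave some (cycle, channel) images nearly empty, which starves the
#' percentile-based normalization of signal and degrades detection there.
#' Barcodes are built column-wise from balanced, shuffled letter multisets
#' and reshuffled until all barcodes are unique.
#'
#' @param genes Character vector of gene names (or an integer count, which
#'   generates `gene1..geneN`).
#' @param n_cycles Barcode length.
#' @param seed Integer seed.
#' @return An `iss_codebook` tibble.
#' @export
design_codebook <- function(genes, n_cycles = 4, seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- paste0("gene", seq_len(genes))
  }
  n <- length(genes)
  if (n > 4^n_cycles) stop("more genes than possible barcodes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (attempt in 1:1000) {
    cols <- replicate(n_cycles,
                      sample(rep_len(iss_bases(), n)), simplify = FALSE)
    bcs <- do.call(paste0, cols)
    if (!anyDuplicated(bcs)) return(codebook(genes, bcs))
  }
  stop("could not build a unique balanced panel; try another seed")
}

#' Read a codebook from CSV
#'
#' Expects columns `gene` and `barcode`.
#'
#' @param path CSV file path.
#' @return An `iss_codebook` tibble.
#' @export
read_codebook <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "barcode") %in% names(df))) {
    stop("codebook CSV needs 'gene' and 'barcode' columns")
  }
  codebook(df$gene, df$barcode)
}

#' Write a codebook to CSV
#' @param cb An `iss_codebook`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_codebook <- function(cb, path) {
  utils::write.csv(as.data.frame(cb), path, row.names = FALSE)
  invisible(path)
}

#' Barcode length of a codebook
#' @param cb An `iss_codebook`.
#' @return Integer barcode length (0 for an empty codebook).
#' @export
barcode_length <- function(cb) if (nrow(cb) == 0) 0L else nchar(cb$barcode[[1]])

#' Look up genes for barcodes
#'
#' Barcodes without a codebook entry are labelled `"UNEXPECTED"`; these reads
#' are retained by the decoder because the quality-calibration step uses them
#' as its negative class.
#'
#' @param cb An `iss_codebook`.
#' @param barcodes Character vector of observed barcodes.
#' @return Character vector of gene names or `"UNEXPECTED"`.
#' @export
match_barcodes <- function(cb, barcodes) {
  m <- match(barcodes, cb$barcode)
  out <- cb$gene[m]
  out[is.na(m)] <- "UNEXPECTED"
  out
}
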