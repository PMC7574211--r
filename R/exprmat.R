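#' Side length of a patch window
#'
#' Patches lie on a regular grid with stride `tile_size` and a symmetric
#' overlap margin on each side, so each patch aggregates reads from a window
#' of `tile_size + 2 * overlap` pixels; the conventional 128 px tile with
#' 128 px overlap gives a 384 px window.
#'
#' @param tile_size Tile (stride) size in pixels.
#' @param overlap Overlap margin in pixels.
#' @return The window side length.
#' @export
patch_footprint <- function(tile_size, overlap) {
  stopifnot(tile_size >= 0, overlap >= 0)
  tile_size + 2 * overlap
}

#' Define the patch grid over an image extent
#'
#' @param width,height Image extent in pixels.
#' @param tile_size Tile (stride) size.
#' @param overlap Overlap margin per side.
#' @return A tibble of patches: `patch`, `ix`, `iy` (0-based tile indices),
#'   `x0`, `y0` (window origin, may be negative at the border) and `window`.
#' @export
patch_grid <- function(width, height, tile_size = 128, overlap = 128) {
  win <- patch_footprint(tile_size, overlap)
  nx <- ceiling(width / tile_size); ny <- ceiling(height / tile_size)
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L,
                   KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    patch = seq_len(nrow(g)),
    ix = g$ix, iy = g$iy,
    x0 = g$ix * tile_size - overlap,
    y0 = g$iy * tile_size - overlap,
    window = win
  )
}

#' Build the patch-level gene expression count matrix
#'
#' Each matrix entry is the number of quality-filtered reads of a gene whose
#' position falls inside the patch's window (half-open `[x0, x0 + window)`).
#' With overlapping windows one read contributes to several patches; the
#' per-gene *read* totals (each read counted once) are recorded separately
#' because the gene abundance filter operates on those.
#'
#' @param reads Filtered read tibble (`x`, `y`, `gene`).
#' @param grid A [patch_grid()] tibble (all patches share one `window`).
#' @param gene_panel Character vector of genes forming the columns.
#' @param tile_size,overlap Grid geometry (must match `grid`).
#' @return An `iss_patch_expr` object: integer `counts` (patches x genes),
#'   the `patches` tibble (with per-patch totals), `genes`,
#'   `gene_read_totals`, geometry and a normalization `state` flag (`"raw"`).
#' @export
count_matrix <- function(reads, grid, gene_panel,
                         tile_size = 128, overlap = 128) {
  stopifnot(length(gene_panel) >= 1)
  win <- patch_footprint(tile_size, overlap)
  counts <- matrix(0L, nrow(grid), length(gene_panel),
                   dimnames = list(NULL, gene_panel))
  n_outside <- 0L
  keep <- reads$gene %in% gene_panel
  reads <- reads[keep, ]
  if (nrow(reads) > 0) {
    gi <- match(reads$gene, gene_panel)
    pk <- paste(grid$ix, grid$iy, sep = ",")
    pindex <- stats::setNames(grid$patch, pk)
    for (r in seq_len(nrow(reads))) {
      # tile indices i with i*tile - overlap <= x < i*tile - overlap + window
      ix <- ceiling((reads$x[r] + overlap - win) / tile_size + 1e-9):
        floor((reads$x[r] + overlap) / tile_size)
      iy <- ceiling((reads$y[r] + overlap - win) / tile_size + 1e-9):
        floor((reads$y[r] + overlap) / tile_size)
      hit <- pindex[paste(rep(ix, each = length(iy)), iy, sep = ",")]
      hit <- hit[!is.na(hit)]
      if (!length(hit)) n_outside <- n_outside + 1L else {
        counts[hit, gi[r]] <- counts[hit, gi[r]] + 1L
      }
    }
  }
  if (n_outside > 0) message(n_outside, " reads fell outside all patches")
  patches <- grid
  patches$total <- as.integer(rowSums(counts))
  gene_read_totals <- stats::setNames(
    as.integer(table(factor(reads$gene, levels = gene_panel))), gene_panel)
  structure(list(
    counts = counts, patches = patches, genes = gene_panel,
    gene_read_totals = gene_read_totals,
    tile_size = tile_size, overlap = overlap,
    state = "raw", n_outside = n_outside
  ), class = "iss_patch_expr")
}

#' @export
print.iss_patch_expr <- function(x, ...) {
  cat(sprintf("<iss_patch_expr> %d patches x %d genes [%s]\n",
              nrow(x$counts), ncol(x$counts), x$state))
  invisible(x)
}

#' Filter low-abundance genes and sparse patches
#'
#' Drops genes whose total decoded read count (each read counted once,
#' regardless of patch multiplicity) is below `min_gene_total`, then patches
#' with fewer than `min_patch_reads` counted reads over the remaining genes.
#' Both comparisons are strict (`< threshold` is dropped).
#'
#' @param expr A raw `iss_patch_expr`.
#' @param min_gene_total Minimum per-gene read total (conventional 500).
#' @param min_patch_reads Minimum per-patch count (conventional 10).
#' @return The filtered `iss_patch_expr`; dropped gene names and patch ids
#'   are recorded in `dropped_genes` / `dropped_patches`.
#' @export
filter_matrix <- function(expr, min_gene_total = 500, min_patch_reads = 10) {
  stopifnot(inherits(expr, "iss_patch_expr"))
  if (expr$state != "raw") stop("filter_matrix expects raw counts")
  keep_g <- expr$gene_read_totals >= min_gene_total
  dropped_genes <- expr$genes[!keep_g]
  counts <- expr$counts[, keep_g, drop = FALSE]
  ptot <- rowSums(counts)
  keep_p <- ptot >= min_patch_reads
  dropped_patches <- expr$patches$patch[!keep_p]
  if (!any(keep_g) || !any(keep_p)) {
    stop("filtering removed everything (", sum(!keep_g), " genes, ",
         sum(!keep_p), " patches dropped)")
  }
  out <- expr
  out$counts <- counts[keep_p, , drop = FALSE]
  out$patches <- expr$patches[keep_p, ]
  out$patches$total <- as.integer(ptot[keep_p])
  out$genes <- expr$genes[keep_g]
  out$gene_read_totals <- expr$gene_read_totals[keep_g]
  out$dropped_genes <- dropped_genes
  out$dropped_patches <- dropped_patches
  out
}

#' Variance-stabilize and normalize a patch expression matrix
#'
#' Three steps: (1) the Anscombe transform `2 * sqrt(x + 3/8)` stabilizes the
#' variance of the counts; (2) per gene, an ordinary least-squares regression
#' on the log of the per-patch raw totals removes the dependence on local
#' read density (cell number/size confounds), keeping the residuals; (3) each
#' gene column is scaled to zero mean and unit variance. Re-normalizing an
#' already-normalized matrix is rejected via the state flag.
#'
#' @param expr A filtered, raw `iss_patch_expr`.
#' @return The normalized `iss_patch_expr` (`state == "scaled"`, numeric
#'   `values` matrix alongside the preserved raw `counts`).
#' @export
normalize_matrix <- function(expr) {
  stopifnot(inherits(expr, "iss_patch_expr"))
  if (expr$state != "raw") stop("matrix is already normalized (state: ", expr$state, ")")
  a <- 2 * sqrt(expr$counts + 3 / 8)
  logtot <- log(rowSums(expr$counts) + 1)
  fit <- stats::lm.fit(cbind(1, logtot), a)
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1)
  sds <- apply(res, 2, stats::sd)
  zero <- sds < 1e-12
  if (any(zero)) {
    warning("zero-variance gene(s) after regression set to 0: ",
            paste(expr$genes[zero], collapse = ", "))
    sds[zero] <- 1
  }
  vals <- scale(res, center = TRUE, scale = sds)
  vals[, zero] <- 0
  dimnames(vals) <- dimnames(expr$counts)
  out <- expr
  out$values <- vals
  out$state <- "scaled"
  out
}

#' Subset a patch expression matrix to a marker panel
#'
#' Re-derives the object from the raw counts of the selected genes, so the
#' result can be filtered/normalized afresh.
#'
#' @param expr An `iss_patch_expr` (raw counts must be present).
#' @param marker_genes Genes to keep; all must be in the panel.
#' @return A raw `iss_patch_expr` over `marker_genes`.
#' @export
subset_panel <- function(expr, marker_genes) {
  stopifnot(inherits(expr, "iss_patch_expr"))
  missing <- setdiff(marker_genes, expr$genes)
  if (length(missing)) {
    stop("marker genes not in panel: ", paste(missing, collapse = ", "))
  }
  out <- expr
  out$counts <- expr$counts[, marker_genes, drop = FALSE]
  out$genes <- marker_genes
  out$gene_read_totals <- expr$gene_read_totals[marker_genes]
  out$patches$total <- as.integer(rowSums(out$counts))
  out$values <- NULL
  out$state <- "raw"
  out
}

#' The packaged 18-gene marker panel
#'
#' A minimal panel for defining cortical/hippocampal spatial compartments:
#' 6 inhibitory markers, 6 pan-excitatory markers, 2 neocortical layer
#' markers (Rorb - layer 4, Penk - layer 6) and 4 markers shared between
#' excitatory and inhibitory cells.
#'
#' @return A tibble with columns `gene` and `group`.
#' @export
marker_panel <- function() {
  tibble::tibble(
    gene = c("Pvalb", "Vip", "Cck", "Fam19a1", "Calb1", "Calb2",
             "Rprm", "Crym", "Wfs1", "Pcp4", "Plcxd2", "3110035E14Rik",
             "Rorb", "Penk",
             "Slc24a2", "Bcl11b", "Gda", "Rgs4"),
    group = c(rep("inhibitory", 6), rep("pan-excitatory", 6),
              rep("layer", 2), rep("shared", 4))
  )
}

#' Export a patch expression matrix as MTX + TSVs
#'
#' Writes the raw counts in MatrixMarket coordinate format alongside a genes
#' TSV and a patches TSV (id, window origin, window size, total reads).
#'
#' @param expr An `iss_patch_expr`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_patch_expr <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(expr$counts != 0, arr.ind = TRUE)
  con <- file(file.path(dir, "counts.mtx"), "w")
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(expr$counts), ncol(expr$counts),
                     nrow(nz)), con)
  if (nrow(nz)) {
    writeLines(sprintf("%d %d %d", nz[, 1], nz[, 2],
                       expr$counts[nz]), con)
  }
  close(con)
  utils::write.table(data.frame(gene = expr$genes),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(expr$patches),
                     file.path(dir, "patches.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
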