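#' Simulate patch-level expression for a tissue with planted regions
#'
#' Generates a rectangular patch grid partitioned into `n_regions` vertical
#' bands, each expressing its own disjoint program of marker genes on top of
#' a uniform background, with Poisson counts. This emulates the input of the
#' compartment-analysis stage (spatially coherent regions with distinct gene
#' programs) without running the imaging pipeline; it does not emulate
#' gradual region boundaries, shared programs, or cell-density gradients.
#'
#' @param n_regions Number of planted regions (vertical bands).
#' @param nx,ny Patch grid dimensions.
#' @param program_genes Number of program genes per region (disjoint sets,
#'   drawn from the packaged [marker_panel()] when `genes` is `NULL`).
#' @param n_noise_genes Additional genes expressed uniformly everywhere.
#' @param lambda_program,lambda_background Poisson means for a program gene
#'   inside/outside its region (background also applies to noise genes).
#' @param genes Optional explicit gene panel; the first
#'   `n_regions * program_genes` entries become the programs.
#' @param tile_size,overlap Patch geometry recorded on the result.
#' @param seed Integer seed.
#' @return A list: `expr` (raw `iss_patch_expr`), `truth` (tibble `patch`,
#'   `region`), `programs` (list of gene vectors per region).
#' @export
simulate_patch_expression <- function(n_regions = 3, nx = 18, ny = 18,
                                      program_genes = 6, n_noise_genes = 6,
                                      lambda_program = 20,
                                      lambda_background = 2,
                                      genes = NULL,
                                      tile_size = 128, overlap = 128,
                                      seed = 1L) {
  stopifnot(n_regions >= 1, nx >= n_regions)
  if (is.null(genes)) {
    need <- n_regions * program_genes
    markers <- marker_panel()$gene
    if (need > length(markers)) stop("not enough marker genes for the programs")
    genes <- c(markers[seq_len(need)],
               if (n_noise_genes > 0) paste0("bg", seq_len(n_noise_genes)))
  }
  programs <- split(genes[seq_len(n_regions * program_genes)],
                    rep(seq_len(n_regions), each = program_genes))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  grid <- patch_grid(nx * tile_size, ny * tile_size, tile_size, overlap)
  region <- findInterval(grid$ix, seq(0, nx, length.out = n_regions + 1),
                         rightmost.closed = TRUE)
  counts <- matrix(0L, nrow(grid), length(genes),
                   dimnames = list(NULL, genes))
  for (g in seq_along(genes)) {
    lam <- rep(lambda_background, nrow(grid))
    for (r in seq_len(n_regions)) {
      if (genes[g] %in% programs[[r]]) lam[region == r] <- lambda_program
    }
    counts[, g] <- stats::rpois(nrow(grid), lam)
  }
  patches <- grid
  patches$total <- as.integer(rowSums(counts))
  expr <- structure(list(
    counts = counts, patches = patches, genes = genes,
    gene_read_totals = stats::setNames(as.integer(colSums(counts)), genes),
    tile_size = tile_size, overlap = overlap,
    state = "raw", n_outside = 0L
  ), class = "iss_patch_expr")
  list(expr = expr,
       truth = tibble::tibble(patch = grid$patch, region = region),
       programs = programs)
}
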