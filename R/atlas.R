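#' Spatial expression pattern from decoded reads
#'
#' Rescales the read coordinates of one gene onto a target voxel grid and
#' estimates a Gaussian kernel density there. The kernel covariance is
#' `covariance_factor^2` times the data covariance of the (rescaled) read
#' positions, i.e. the factor scales the per-axis bandwidth relative to the
#' data spread; the resulting density is normalized to total mass 1.
#'
#' @param reads Read tibble of a single gene (`x`, `y`); at least 2 reads.
#' @param grid_shape `c(nrow, ncol)` of the target grid.
#' @param extent `c(xmin, xmax, ymin, ymax)` of the source coordinates;
#'   defaults to the read bounding box.
#' @param covariance_factor Bandwidth scaling factor (conventional 0.05).
#' @param min_bandwidth Per-axis lower bound on the kernel standard
#'   deviation, in grid cells; evaluating a kernel much narrower than the
#'   grid spacing aliases the density, so bandwidths are floored at half a
#'   cell.
#' @param gene Gene name stamped on the pattern.
#' @return An `iss_pattern`: `density` matrix (rows = grid y, cols = grid x)
#'   summing to 1, plus metadata.
#' @export
pattern_from_reads <- function(reads, grid_shape,
                               extent = NULL, covariance_factor = 0.05,
                               min_bandwidth = 0.5,
                               gene = reads$gene[1]) {
  if (nrow(reads) < 2) stop("KDE needs at least 2 reads")
  if (is.null(extent)) extent <- c(range(reads$x), range(reads$y))
  nr <- grid_shape[1]; nc <- grid_shape[2]
  # map source extent onto [0, ncol-1] x [0, nrow-1]
  sx <- (reads$x - extent[1]) / max(extent[2] - extent[1], 1e-12) * (nc - 1)
  sy <- (reads$y - extent[3]) / max(extent[4] - extent[3], 1e-12) * (nr - 1)
  S <- stats::cov(cbind(sx, sy)) * covariance_factor^2
  # floor the per-axis bandwidth at min_bandwidth grid cells and regularize
  # degenerate covariances (e.g. collinear reads)
  S[1, 1] <- max(S[1, 1], min_bandwidth^2)
  S[2, 2] <- max(S[2, 2], min_bandwidth^2)
  if (det(S) < 1e-12) S <- S + diag(1e-6, 2)
  Sinv <- solve(S)
  gx <- 0:(nc - 1); gy <- 0:(nr - 1)
  dens <- matrix(0, nr, nc)
  for (i in seq_along(sx)) {
    dx <- outer(rep(1, nr), gx - sx[i])
    dy <- outer(gy - sy[i], rep(1, nc))
    q <- Sinv[1, 1] * dx^2 + 2 * Sinv[1, 2] * dx * dy + Sinv[2, 2] * dy^2
    dens <- dens + exp(-0.5 * q)
  }
  dens <- dens / sum(dens)
  structure(list(density = dens, gene = gene, provenance = "ISS",
                 grid_shape = grid_shape, covariance_factor = covariance_factor),
            class = "iss_pattern")
}

#' Wrap a reference expression grid as a pattern
#'
#' @param grid Non-negative 2-D matrix (e.g. one coronal level of a voxelized
#'   reference atlas).
#' @param gene Gene name.
#' @return An `iss_pattern` with mass-1 normalized density and provenance
#'   `"reference"`.
#' @export
pattern_from_grid <- function(grid, gene) {
  stopifnot(is.matrix(grid), all(grid >= 0), sum(grid) > 0)
  structure(list(density = grid / sum(grid), gene = gene,
                 provenance = "reference", grid_shape = dim(grid),
                 covariance_factor = NA_real_),
            class = "iss_pattern")
}

#' Kullback-Leibler divergence between two spatial patterns
#'
#' `KL(p || q) = sum p_v log(p_v / q_v)` over the grid, with `q` floored at
#' `eps` so sparse reference grids keep the divergence finite. Non-negative,
#' zero iff the patterns coincide (up to flooring effects), and asymmetric.
#'
#' @param p,q `iss_pattern` objects on the same grid (mass 1).
#' @param eps Floor applied to `q`.
#' @return A non-negative number.
#' @export
kl_divergence <- function(p, q, eps = 1e-12) {
  if (!identical(dim(p$density), dim(q$density))) {
    stop("patterns are on different grids")
  }
  pv <- as.vector(p$density); qv <- pmax(as.vector(q$density), eps)
  nz <- pv > 0
  sum(pv[nz] * log(pv[nz] / qv[nz]))
}

#' Gene-by-gene KL divergence match table
#'
#' Computes the full KL matrix between decoded and reference patterns over
#' their shared genes, scores each gene by
#' `KL(self pair) - min KL(off pairs)` (negative scores mean the gene's own
#' reference pattern is its best match), and sorts rows and columns ascending
#' by score so the best self-matches appear first.
#'
#' @param iss_patterns,ref_patterns Named lists of `iss_pattern` objects over
#'   the same gene names.
#' @return An `iss_kl_table`: sorted `kl` matrix (rows = decoded patterns,
#'   columns = reference), and a `scores` tibble (`gene`, `self_kl`,
#'   `best_other_kl`, `score`) in sorted order.
#' @export
kl_match_table <- function(iss_patterns, ref_patterns) {
  genes <- names(iss_patterns)
  missing <- c(setdiff(genes, names(ref_patterns)),
               setdiff(names(ref_patterns), genes))
  if (length(missing)) {
    stop("genes missing from one set: ", paste(unique(missing), collapse = ", "))
  }
  n <- length(genes)
  kl <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in genes) for (j in genes) {
    kl[i, j] <- kl_divergence(iss_patterns[[i]], ref_patterns[[j]])
  }
  self_kl <- diag(kl)
  best_other <- vapply(seq_len(n), function(i) min(kl[i, -i]), numeric(1))
  score <- self_kl - best_other
  ord <- order(score)
  structure(list(
    kl = kl[ord, ord, drop = FALSE],
    scores = tibble::tibble(gene = genes[ord], self_kl = self_kl[ord],
                            best_other_kl = best_other[ord],
                            score = score[ord])
  ), class = "iss_kl_table")
}

#' Best / worst matching genes of a KL table
#' @param x An `iss_kl_table`.
#' @param k Number of genes.
#' @param worst If `TRUE`, return the k least matching genes instead.
#' @return Character vector of gene names.
#' @export
top_matches <- function(x, k = 10, worst = FALSE) {
  g <- x$scores$gene
  if (worst) utils::tail(g, k) else utils::head(g, k)
}

#' @export
print.iss_kl_table <- function(x, ...) {
  cat(sprintf("<iss_kl_table> %d genes; %d with self-pattern as best match\n",
              nrow(x$kl), sum(x$scores$score <= 0)))
  invisible(x)
}
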