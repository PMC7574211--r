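#' Embed patch expression profiles with UMAP
#'
#' Maps the normalized patch profiles of one or several samples *jointly*
#' into a low-dimensional space: 3 dimensions for RGB visualization (each
#' axis min-max normalized to \[0, 1\]) or 50 dimensions as the substrate for
#' clustering. All samples must share the gene panel and be normalized.
#'
#' @param exprs A normalized `iss_patch_expr` or a (optionally named) list of
#'   them.
#' @param dims Embedding dimensionality, typically 3 or 50.
#' @param seed Integer seed; the embedding is deterministic given it.
#' @param n_neighbors,min_dist UMAP parameters.
#' @return An `iss_embedding`: `coordinates` (patches x dims), `sample` and
#'   `patch` vectors, `dims`, `params`, `seed`.
#' @export
embed_patches <- function(exprs, dims = 50, seed = 1L,
                          n_neighbors = 15, min_dist = 0.1) {
  if (inherits(exprs, "iss_patch_expr")) exprs <- list(sample1 = exprs)
  if (is.null(names(exprs))) names(exprs) <- paste0("sample", seq_along(exprs))
  genes <- exprs[[1]]$genes
  for (e in exprs) {
    if (e$state != "scaled") stop("embed_patches expects normalized matrices")
    if (!identical(e$genes, genes)) stop("gene panels differ between samples")
  }
  X <- do.call(rbind, purrr::map(exprs, "values"))
  sample_id <- rep(names(exprs), purrr::map_int(exprs, ~ nrow(.x$values)))
  patch_id <- unlist(purrr::map(exprs, ~ .x$patches$patch), use.names = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nn <- min(n_neighbors, nrow(X) - 1)
  # spectral initialization is only well-posed for small target dimensions;
  # the high-dimensional clustering embedding starts from random coordinates
  init <- if (dims <= 3) "spectral" else "random"
  coords <- withCallingHandlers(
    uwot::umap(X, n_components = dims, n_neighbors = nn,
               min_dist = min_dist, init = init,
               n_threads = 1, n_sgd_threads = 1),
    warning = function(w) {
      # expected whenever the embedding dimension exceeds the gene panel
      if (grepl("n_components > number of columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (dims == 3) {
    rng <- apply(coords, 2, range)
    span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
    coords <- sweep(sweep(coords, 2, rng[1, ]), 2, span, "/")
  }
  structure(list(
    coordinates = coords, sample = sample_id, patch = patch_id, dims = dims,
    params = list(n_neighbors = nn, min_dist = min_dist), seed = seed
  ), class = "iss_embedding")
}

#' Cluster embedded patches into spatial compartments
#'
#' Builds a k-nearest-neighbour graph on the embedding coordinates and runs
#' Leiden community detection on it. Patches of all samples are clustered
#' together so labels are comparable across samples.
#'
#' @param embedding An `iss_embedding` (typically 50-dimensional).
#' @param k Number of nearest neighbours for the graph (20, the customary
#'   neighbourhood size for expression kNN graphs; smaller values can leave
#'   sparse subgraphs that modularity then splits).
#' @param resolution Leiden resolution parameter (modularity objective).
#'   The default favours coarse, anatomically sized compartments; raise it to
#'   split finer structure.
#' @param seed Integer seed.
#' @return An `iss_compartments`: `labels` tibble (`sample`, `patch`,
#'   `cluster`) and `n_clusters`.
#' @export
cluster_patches <- function(embedding, k = 20, resolution = 0.5, seed = 1L) {
  X <- embedding$coordinates
  n <- nrow(X)
  if (n <= k) stop("fewer patches (", n, ") than k + 1 neighbours")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn_idx <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nn_idx)))
  el <- t(apply(el, 1, sort))
  el <- unique(el)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  labels <- igraph::membership(cl)
  structure(list(
    labels = tibble::tibble(sample = embedding$sample,
                            patch = embedding$patch,
                            cluster = as.integer(labels)),
    n_clusters = length(unique(labels)),
    params = list(k = k, resolution = resolution, seed = seed)
  ), class = "iss_compartments")
}

#' @export
print.iss_compartments <- function(x, ...) {
  cat(sprintf("<iss_compartments> %d patches in %d clusters\n",
              nrow(x$labels), x$n_clusters))
  invisible(x)
}

#' Per-cluster gene expression profiles
#'
#' For each cluster of one sample, sums the raw gene counts over its member
#' patches, divides by the number of patches (cluster area), and scales to
#' unit total over genes.
#'
#' @param expr The *raw* `iss_patch_expr` of one sample.
#' @param compartments An `iss_compartments`.
#' @param sample Sample name to select from `compartments` (default: the
#'   only/first one).
#' @return A matrix (clusters x genes) whose rows sum to 1.
#' @export
cluster_profiles <- function(expr, compartments,
                             sample = compartments$labels$sample[1]) {
  lab <- compartments$labels[compartments$labels$sample == sample, ]
  m <- match(lab$patch, expr$patches$patch)
  if (anyNA(m)) stop("labels cover patches missing from the matrix")
  cl <- sort(unique(lab$cluster))
  prof <- matrix(0, length(cl), ncol(expr$counts),
                 dimnames = list(cl, expr$genes))
  for (i in seq_along(cl)) {
    rows <- m[lab$cluster == cl[i]]
    if (!length(rows)) stop("cluster ", cl[i], " has no member patches")
    p <- colSums(expr$counts[rows, , drop = FALSE]) / length(rows)
    if (sum(p) == 0) stop("cluster ", cl[i], " has an all-zero profile")
    prof[i, ] <- p / sum(p)
  }
  prof
}

#' Match compartments across samples by profile correlation
#'
#' Stacks the cluster profiles of several samples and hierarchically clusters
#' them (average linkage) on `1 - Pearson correlation`, giving a
#' correspondence tree whose lowest merges pair the most similar
#' compartments across samples. Cutting the tree at a chosen group count
#' (e.g. the top 20 distinct compartments) yields a flat correspondence.
#'
#' @param profiles_by_sample Named list of profile matrices from
#'   [cluster_profiles()] (at least 2 samples).
#' @param n_groups Number of flat groups to cut the tree into (capped at the
#'   number of profiles).
#' @return An `iss_cluster_tree`: the `hclust` object, profile `labels`
#'   (`sample:cluster`), and `groups` (tibble of label, group).
#' @export
match_clusters <- function(profiles_by_sample, n_groups = 20) {
  stopifnot(length(profiles_by_sample) >= 2)
  if (is.null(names(profiles_by_sample))) {
    names(profiles_by_sample) <- paste0("sample", seq_along(profiles_by_sample))
  }
  labs <- unname(unlist(purrr::imap(profiles_by_sample,
                                    ~ paste(.y, rownames(.x), sep = ":"))))
  P <- do.call(rbind, profiles_by_sample)
  rownames(P) <- labs
  sds <- apply(P, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant profile (correlation undefined): ",
         paste(labs[sds == 0], collapse = ", "))
  }
  D <- stats::as.dist(1 - stats::cor(t(P)))
  hc <- stats::hclust(D, method = "average")
  ng <- min(n_groups, length(labs))
  grp <- stats::cutree(hc, k = ng)
  structure(list(
    tree = hc, labels = labs,
    groups = tibble::tibble(label = labs, group = as.integer(grp[labs]))
  ), class = "iss_cluster_tree")
}

#' Export a correspondence tree as a Newick string
#'
#' Tip labels are sanitized (`:`, `;`, commas, parentheses and spaces become
#' `_`) because Newick reserves those characters.
#'
#' @param x An `iss_cluster_tree`.
#' @return A Newick string.
#' @export
tree_newick <- function(x) {
  phy <- ape::as.phylo(x$tree)
  phy$tip.label <- gsub("[:;,() ]", "_", phy$tip.label)
  ape::write.tree(phy)
}

#' Differential expression between compartments
#'
#' For every compartment (with at least `min_patches` member patches), each
#' gene is tested compartment-vs-rest with a two-sided Wilcoxon rank-sum test
#' on raw patch counts; p-values are Benjamini-Hochberg adjusted per
#' compartment and the natural-log fold change of means (with a 1e-9
#' pseudo-mean) is reported. Rows are sorted by adjusted p within
#' compartment.
#'
#' @param expr An `iss_patch_expr` with raw counts (typically restricted to
#'   genes outside the clustering panel, so the test is unbiased by the
#'   clustering itself).
#' @param compartments An `iss_compartments`.
#' @param sample Sample to test.
#' @param min_patches Minimum patches per compartment (smaller ones are
#'   skipped with a warning).
#' @return A tibble: `cluster`, `gene`, `statistic`, `p`, `q`, `lfc`.
#' @export
differential_expression <- function(expr, compartments,
                                    sample = compartments$labels$sample[1],
                                    min_patches = 3) {
  lab <- compartments$labels[compartments$labels$sample == sample, ]
  m <- match(lab$patch, expr$patches$patch)
  if (anyNA(m)) stop("labels cover patches missing from the matrix")
  counts <- expr$counts[m, , drop = FALSE]
  cls <- sort(unique(lab$cluster))
  if (length(cls) < 2) stop("need at least 2 compartments")
  out <- list()
  for (cl in cls) {
    inside <- lab$cluster == cl
    if (sum(inside) < min_patches) {
      warning("cluster ", cl, " has fewer than ", min_patches,
              " patches; skipped")
      next
    }
    res <- purrr::map(expr$genes, function(g) {
      xi <- counts[inside, g]; xo <- counts[!inside, g]
      wt <- suppressWarnings(stats::wilcox.test(xi, xo, exact = FALSE))
      tibble::tibble(
        cluster = cl, gene = g,
        statistic = unname(wt$statistic), p = wt$p.value,
        lfc = log((mean(xi) + 1e-9) / (mean(xo) + 1e-9))
      )
    })
    res <- dplyr::bind_rows(res)
    res$q <- stats::p.adjust(res$p, method = "BH")
    out[[length(out) + 1L]] <- res[order(res$q, res$p), ]
  }
  dplyr::bind_rows(out)[, c("cluster", "gene", "statistic", "p", "q", "lfc")]
}
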