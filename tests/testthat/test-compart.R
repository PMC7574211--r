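planted_tissue <- function(seed = 5L) {
  with_cache(paste0("tissue", seed), {
    ts <- simulate_patch_expression(seed = seed)
    list(ts = ts, norm = normalize_matrix(filter_matrix(ts$expr)))
  })
}

test_that("3-d embeddings are unit-cube RGB coordinates and deterministic", {
  tt <- planted_tissue()
  e3 <- embed_patches(tt$norm, dims = 3, seed = 2)
  expect_true(all(e3$coordinates >= 0 & e3$coordinates <= 1))
  expect_equal(ncol(e3$coordinates), 3)
  e3b <- embed_patches(tt$norm, dims = 3, seed = 2)
  expect_identical(e3$coordinates, e3b$coordinates)
  # mismatched gene panels are rejected
  other <- simulate_patch_expression(n_noise_genes = 2, seed = 3L)
  other <- normalize_matrix(filter_matrix(other$expr))
  expect_error(embed_patches(list(a = tt$norm, b = other), seed = 1),
               "gene panels differ")
  # unnormalized input is rejected
  expect_error(embed_patches(filter_matrix(planted_tissue()$ts$expr)),
               "normalized")
})

test_that("distinct expression programs separate in the embedding", {
  tt <- planted_tissue()
  e <- embed_patches(tt$norm, dims = 3, seed = 4)
  truth <- tt$ts$truth$region[match(e$patch, tt$ts$truth$patch)]
  D <- as.matrix(dist(e$coordinates))
  same <- outer(truth, truth, "==")
  diag(same) <- NA
  expect_gt(mean(D[!same], na.rm = TRUE), mean(D[same], na.rm = TRUE))
})

test_that("RGB maps are smooth within regions relative to region borders", {
  tt <- planted_tissue()
  e3 <- embed_patches(tt$norm, dims = 3, seed = 6)
  patches <- tt$norm$patches
  region <- tt$ts$truth$region[match(e3$patch, tt$ts$truth$patch)]
  col <- e3$coordinates
  # grid-adjacent patch pairs, split by whether they cross a region border
  within_d <- c(); across_d <- c()
  for (i in seq_len(nrow(patches))) {
    j <- which(patches$ix == patches$ix[i] + 1 & patches$iy == patches$iy[i])
    if (length(j) == 1) {
      d <- sqrt(sum((col[i, ] - col[j, ])^2))
      if (region[i] == region[j]) within_d <- c(within_d, d)
      else across_d <- c(across_d, d)
    }
  }
  expect_gt(mean(across_d), mean(within_d))
})

test_that("Leiden clustering recovers planted regions and is deterministic", {
  tt <- planted_tissue()
  em <- embed_patches(tt$norm, dims = 50, seed = 1)
  cl <- cluster_patches(em, seed = 1)
  truth <- tt$ts$truth$region[match(cl$labels$patch, tt$ts$truth$patch)]
  expect_gte(mclust::adjustedRandIndex(cl$labels$cluster, truth), 0.9)
  cl2 <- cluster_patches(em, seed = 1)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_patches(em, k = nrow(em$coordinates)), "fewer patches")
})

test_that("identical patches collapse to a single cluster", {
  em <- structure(list(
    coordinates = matrix(1, 40, 5), sample = rep("s", 40), patch = 1:40,
    dims = 5, params = list(), seed = 1
  ), class = "iss_embedding")
  cl <- cluster_patches(em, k = 5, seed = 1)
  expect_equal(cl$n_clusters, 1)
})

test_that("cluster profiles are area-normalized unit-mass vectors", {
  tt <- planted_tissue()
  em <- embed_patches(tt$norm, dims = 50, seed = 1)
  cl <- cluster_patches(em, seed = 1)
  prof <- cluster_profiles(tt$norm, cl)
  expect_true(all(abs(rowSums(prof) - 1) < 1e-12))
  # a cluster of identical patches has the single-patch profile
  counts <- matrix(c(3L, 1L, 3L, 1L), 2, 2, byrow = TRUE,
                   dimnames = list(NULL, c("a", "b")))
  expr <- structure(list(
    counts = counts,
    patches = tibble::tibble(patch = 1:2, ix = 0:1, iy = 0, x0 = 0, y0 = 0,
                             window = 384, total = c(4L, 4L)),
    genes = c("a", "b"), gene_read_totals = c(a = 6L, b = 2L),
    tile_size = 128, overlap = 128, state = "raw", n_outside = 0L
  ), class = "iss_patch_expr")
  cmp <- structure(list(labels = tibble::tibble(sample = "s", patch = 1:2,
                                                cluster = 1L),
                        n_clusters = 1L, params = list()),
                   class = "iss_compartments")
  expect_equal(unname(cluster_profiles(expr, cmp)[1, ]), c(0.75, 0.25))
  # region expressing mostly one program concentrates its profile there
  profs <- cluster_profiles(tt$ts$expr, cl)
  top <- colnames(profs)[apply(profs, 1, which.max)]
  expect_true(all(top %in% unlist(tt$ts$programs)))
})

test_that("cross-sample matching pairs identical profiles first", {
  p1 <- matrix(c(0.7, 0.2, 0.1,
                 0.1, 0.2, 0.7), 2, byrow = TRUE,
               dimnames = list(c("1", "2"), c("a", "b", "c")))
  p2 <- p1[2:1, ]; rownames(p2) <- c("1", "2")
  tree <- match_clusters(list(s1 = p1, s2 = p2), n_groups = 2)
  expect_equal(sort(tree$labels),
               sort(c("s1:1", "s1:2", "s2:1", "s2:2")))
  grp <- tree$groups
  g <- function(l) grp$group[grp$label == l]
  expect_equal(g("s1:1"), g("s2:2"))   # identical profiles grouped
  expect_equal(g("s1:2"), g("s2:1"))
  expect_false(g("s1:1") == g("s1:2")) # orthogonal ones apart
  # first merge joins a zero-distance pair
  expect_equal(min(tree$tree$height), 0, tolerance = 1e-12)
  # Newick export is a parseable tree over all labels
  nwk <- tree_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, gsub("[:;,() ]", "_", tree$labels))
  # constant profiles error by name
  bad <- rbind(p1, c(1, 1, 1) / 3)
  rownames(bad) <- c("1", "2", "3")
  expect_error(match_clusters(list(s1 = bad, s2 = p2)), "constant profile")
})

test_that("planted regions pair across independently simulated samples", {
  a <- simulate_patch_expression(seed = 21L)
  b <- simulate_patch_expression(seed = 22L)
  ca <- structure(list(labels = tibble::tibble(sample = "a",
                                               patch = a$truth$patch,
                                               cluster = a$truth$region),
                       n_clusters = 3L, params = list()),
                  class = "iss_compartments")
  cbm <- structure(list(labels = tibble::tibble(sample = "b",
                                                patch = b$truth$patch,
                                                cluster = b$truth$region),
                        n_clusters = 3L, params = list()),
                   class = "iss_compartments")
  tree <- match_clusters(list(a = cluster_profiles(a$expr, ca),
                              b = cluster_profiles(b$expr, cbm)),
                         n_groups = 3)
  grp <- tree$groups
  for (r in 1:3) {
    expect_equal(grp$group[grp$label == paste0("a:", r)],
                 grp$group[grp$label == paste0("b:", r)])
  }
})

test_that("differential expression flags planted program genes", {
  ts <- simulate_patch_expression(nx = 12, ny = 6, seed = 31L)
  cmp <- structure(list(labels = tibble::tibble(sample = "s",
                                                patch = ts$truth$patch,
                                                cluster = ts$truth$region),
                        n_clusters = 3L, params = list()),
                   class = "iss_compartments")
  de <- differential_expression(ts$expr, cmp)
  for (r in 1:3) {
    top <- de[de$cluster == r, ][1:6, ]
    expect_true(all(top$gene %in% ts$programs[[r]]))
    expect_true(all(top$q < 0.05))
    expect_true(all(top$lfc > 0))
  }
  # a compartment with too few patches is skipped with a warning
  small <- cmp
  small$labels$cluster[1:2] <- 9L
  expect_warning(differential_expression(ts$expr, small), "fewer than")
})

test_that("label permutation yields uniform DE p-values", {
  set.seed(41)
  n_genes <- 1000
  counts <- matrix(rpois(120 * n_genes, 5), 120, n_genes,
                   dimnames = list(NULL, paste0("g", seq_len(n_genes))))
  expr <- structure(list(
    counts = counts,
    patches = tibble::tibble(patch = 1:120, ix = 0, iy = 0, x0 = 0, y0 = 0,
                             window = 384, total = rowSums(counts)),
    genes = colnames(counts),
    gene_read_totals = colSums(counts),
    tile_size = 128, overlap = 128, state = "raw", n_outside = 0L
  ), class = "iss_patch_expr")
  cmp <- structure(list(labels = tibble::tibble(
    sample = "s", patch = 1:120, cluster = sample(rep(1:2, 60))),
    n_clusters = 2L, params = list()), class = "iss_compartments")
  de <- differential_expression(expr, cmp)
  ks <- suppressWarnings(stats::ks.test(de$p[de$cluster == 1], "punif"))
  expect_gt(ks$p.value, 0.01)
  # identical distributions: log fold-changes hover near zero
  expect_lt(mean(abs(de$lfc)), 0.1)
})
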