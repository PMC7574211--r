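test_that("patch windows combine tile size and symmetric overlap", {
  expect_equal(patch_footprint(128, 128), 384)
  expect_equal(patch_footprint(128, 0), 128)
  expect_equal(patch_footprint(100, 50), 200)
})

test_that("a read lands in every overlapping patch window", {
  grid <- patch_grid(5 * 128, 5 * 128)
  # read at the centre of the middle tile -> 3x3 block of windows
  reads <- tibble::tibble(x = 2 * 128 + 64, y = 2 * 128 + 64, gene = "g1")
  expr <- count_matrix(reads, grid, "g1")
  expect_equal(sum(expr$counts), 9)
  hit <- grid[expr$counts[, "g1"] > 0, ]
  expect_setequal(hit$ix, 1:3)
  expect_setequal(hit$iy, 1:3)
  # no reads: all-zero matrix
  expr0 <- count_matrix(reads[0, ], grid, "g1")
  expect_true(all(expr0$counts == 0))
})

test_that("total matrix mass equals summed coverage multiplicity", {
  set.seed(12)
  grid <- patch_grid(6 * 128, 6 * 128)
  reads <- tibble::tibble(x = runif(200, 0, 6 * 128 - 1),
                          y = runif(200, 0, 6 * 128 - 1),
                          gene = sample(c("g1", "g2"), 200, replace = TRUE))
  expr <- count_matrix(reads, grid, c("g1", "g2"))
  mult <- vapply(seq_len(nrow(reads)), function(r) {
    sum(reads$x[r] >= grid$x0 & reads$x[r] < grid$x0 + grid$window &
        reads$y[r] >= grid$y0 & reads$y[r] < grid$y0 + grid$window)
  }, numeric(1))
  expect_equal(sum(expr$counts), sum(mult))
  # per-gene read totals count each read once
  expect_equal(unname(expr$gene_read_totals),
               unname(as.integer(table(factor(reads$gene, c("g1", "g2"))))))
})

test_that("gene and patch filters apply strict thresholds in order", {
  counts <- matrix(0L, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  counts[, 1] <- c(100L, 200L, 100L, 99L)
  counts[, 2] <- c(200L, 200L, 50L, 50L)
  counts[, 3] <- c(5L, 4L, 0L, 1L)
  grid <- patch_grid(4 * 128, 128)
  expr <- structure(list(
    counts = counts, patches = within(as.data.frame(grid), total <- rowSums(counts)),
    genes = c("a", "b", "c"),
    gene_read_totals = c(a = 499L, b = 500L, c = 600L),
    tile_size = 128, overlap = 128, state = "raw", n_outside = 0L
  ), class = "iss_patch_expr")
  expr$patches <- tibble::as_tibble(expr$patches)
  filt <- filter_matrix(expr, min_gene_total = 500, min_patch_reads = 10)
  expect_equal(filt$genes, c("b", "c"))          # 499 dropped, 500 kept
  expect_equal(filt$dropped_genes, "a")
  # patch totals after the gene drop: 205, 204, 50, 51 -> all kept at 10
  expect_equal(nrow(filt$counts), 4)
  filt2 <- filter_matrix(expr, min_gene_total = 500, min_patch_reads = 52)
  expect_equal(nrow(filt2$counts), 2)            # 50 and 51 dropped
  # abundant everything: identity
  ok <- expr; ok$gene_read_totals[] <- 1000L
  same <- filter_matrix(ok, min_patch_reads = 0)
  expect_equal(same$counts, expr$counts)
  # everything removed errors
  expect_error(filter_matrix(expr, min_gene_total = 1e6), "removed everything")
})

test_that("normalization stabilizes, regresses out totals and scales", {
  expect_equal(2 * sqrt(0 + 3 / 8), 1.224745, tolerance = 1e-6)
  ts <- simulate_patch_expression(seed = 8L)
  expr <- filter_matrix(ts$expr)
  norm <- normalize_matrix(expr)
  expect_equal(norm$state, "scaled")
  logtot <- log(rowSums(expr$counts) + 1)
  for (g in seq_len(ncol(norm$values))) {
    expect_lt(abs(cor(norm$values[, g], logtot) *
                    sd(norm$values[, g])), 1e-10)
    expect_lt(abs(mean(norm$values[, g])), 1e-10)
    expect_equal(sd(norm$values[, g]), 1, tolerance = 1e-10)
  }
  # re-normalizing is rejected via the state flag
  expect_error(normalize_matrix(norm), "already normalized")
  # zero-variance gene handled with a warning
  degen <- expr
  degen$counts[, 1] <- 5L
  expect_warning(nd <- normalize_matrix(degen), "zero-variance")
  expect_true(all(nd$values[, 1] == 0))
})

test_that("panel subsetting re-derives raw counts and validates names", {
  ts <- simulate_patch_expression(seed = 9L)
  sub <- subset_panel(ts$expr, c("Pvalb", "Vip"))
  expect_equal(sub$genes, c("Pvalb", "Vip"))
  expect_equal(sub$counts, ts$expr$counts[, c("Pvalb", "Vip")])
  expect_equal(sub$state, "raw")
  expect_error(subset_panel(ts$expr, c("Pvalb", "NotAGene")), "NotAGene")
  # subsetting to the full panel is the identity on raw counts
  full <- subset_panel(ts$expr, ts$expr$genes)
  expect_equal(full$counts, ts$expr$counts)
})

test_that("the packaged marker panel has its four groups and 18 genes", {
  panel <- marker_panel()
  expect_equal(nrow(panel), 18)
  expect_equal(sum(panel$group == "inhibitory"), 6)
  expect_equal(sum(panel$group == "pan-excitatory"), 6)
  expect_equal(sum(panel$group == "layer"), 2)
  expect_equal(sum(panel$group == "shared"), 4)
  expect_true(all(c("Pvalb", "Rorb", "Penk", "Rgs4") %in% panel$gene))
})

test_that("matrices export to MTX with genes and patch annotations", {
  ts <- simulate_patch_expression(nx = 4, ny = 4, seed = 10L)
  dir <- withr::local_tempdir()
  write_patch_expr(ts$expr, dir)
  mtx <- readLines(file.path(dir, "counts.mtx"))
  expect_match(mtx[1], "MatrixMarket")
  dims <- as.integer(strsplit(mtx[2], " ")[[1]])
  expect_equal(dims[1:2], dim(ts$expr$counts))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  expect_equal(genes$gene, ts$expr$genes)
})
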