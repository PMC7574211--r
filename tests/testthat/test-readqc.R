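test_that("per-base quality follows the competitor formula", {
  expect_equal(base_quality(1, 0.9), 0.9)                 # no competitors
  expect_equal(base_quality(1, 0.8, 1, 0.8), 0.5)         # identical rival
  expect_equal(base_quality(1, 0.8, c(0.5, 0.4), c(0.6, 0.9)),
               0.8 / (0.8 + 0.36), tolerance = 1e-12)     # 0.6897
  expect_error(base_quality(-1, 0.5), "negative intensity")
})

test_that("distance penalty is clipped and anchored at its closed forms", {
  expect_equal(distance_penalty(0, 2), 1)
  expect_equal(distance_penalty(exp(2) - 1, 2), 0)
  expect_equal(distance_penalty(exp(3), 2), 0)            # beyond the clip
  expect_equal(distance_penalty(3, 2), 1 - log(4) / 2, tolerance = 1e-12)
})

test_that("read quality combines penalty and base qualities", {
  expect_equal(read_quality(rep(1, 4), 1), 4)
  expect_equal(read_quality(c(0.9, 0.8, 0.7, 0.6), 0), 0)
  expect_equal(read_quality(c(0.9, 0.8, 0.7, 0.6), 0.5), 1.5)
})

test_that("quality formulas match direct evaluation on random inputs", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(3:6, 1)
    I <- runif(1, 0, 3); p <- runif(1)
    k <- sample(0:3, 1)
    ci <- runif(k, 0, 3); cp <- runif(k, 0.5, 1)
    qsb <- base_quality(I, p, ci, cp)
    want <- if (k == 0) p else (I * p) / (I * p + max(ci * cp))
    expect_equal(qsb, want, tolerance = 1e-12)
    expect_true(qsb >= 0 && qsb <= 1)
    d <- runif(1, 0, 30); sg <- runif(1, 0.3, 8)
    mu <- distance_penalty(d, sg)
    expect_equal(mu, min(max(1 - log(1 + d) / sg, 0), 1), tolerance = 1e-12)
    qs <- read_quality(runif(n), mu)
    expect_true(qs >= 0 && qs <= n)
  }
  # monotone non-increasing in distance at fixed base qualities
  ds <- seq(0, 20, by = 0.5)
  qs <- vapply(ds, function(d) read_quality(rep(0.8, 4),
                                            distance_penalty(d, 3)), numeric(1))
  expect_true(all(diff(qs) <= 0))
})

test_that("scored reads resolve competitors from merged candidates", {
  cand <- tibble::tibble(
    id = 1:2, cycle = 1:2, channel = c("A", "C"),
    x = c(0, 0.5), y = 0, intensity = c(1, 1), p = c(0.8, 0.9),
    merged_from = list(
      tibble::tibble(id = 3L, channel = "C", x = 0, y = 0,
                     intensity = 0.5, p = 0.6),
      tibble::tibble(id = integer(), channel = character(), x = numeric(),
                     y = numeric(), intensity = numeric(), p = numeric())))
  reads <- decode_reads(list(1:2), cand, codebook("g", "AC"))
  scored <- score_reads(reads, cand, sigma = 2)
  expect_equal(scored$per_base_quality[[1]],
               c(0.8 / (0.8 + 0.3), 0.9), tolerance = 1e-12)
  expect_equal(scored$mu, distance_penalty(0.5, 2))
  expect_equal(scored$quality,
               distance_penalty(0.5, 2) * (0.8 / 1.1 + 0.9), tolerance = 1e-12)
  # competitors below the probability floor are ignored
  cand$merged_from[[1]]$p <- 0.4
  scored2 <- score_reads(reads, cand, sigma = 2)
  expect_equal(scored2$per_base_quality[[1]][1], 0.8)
})

test_that("sigma calibration maximizes the ROC AUC over the grid", {
  # perfect separation at any sigma
  reads <- tibble::tibble(
    gene = rep(c("g1", "UNEXPECTED"), each = 20),
    max_pair_distance = rep(c(0, 0), each = 20),
    base_quality_sum = rep(c(4, 0), each = 20))
  cal <- calibrate_sigma(reads)
  expect_equal(cal$auc, 1)
  expect_equal(cal$sigma, min(cal$table$sigma))   # smallest sigma on ties

  # off-target reads systematically farther apart: finite sigma* beats the
  # extremes of the grid
  set.seed(55)
  n <- 150
  on <- tibble::tibble(gene = "g1",
                       max_pair_distance = runif(n, 0, 1.2),
                       base_quality_sum = runif(n, 2.2, 4))
  off <- tibble::tibble(gene = "UNEXPECTED",
                        max_pair_distance = runif(n, 1.5, 6),
                        base_quality_sum = runif(n, 1.8, 4))
  reads <- dplyr::bind_rows(on, off)
  cal <- calibrate_sigma(reads)
  expect_gte(cal$auc, 0.9)
  expect_gt(cal$auc, utils::tail(cal$table$auc, 1))
  expect_gte(cal$auc, cal$table$auc[1])
  # single class errors
  expect_error(calibrate_sigma(on), "both on-target and UNEXPECTED")
})

test_that("calibration AUC agrees with pairwise concordance to 1e-9", {
  set.seed(66)
  n <- 1000
  reads <- tibble::tibble(
    gene = sample(c("g1", "UNEXPECTED"), n, replace = TRUE),
    max_pair_distance = runif(n, 0, 5),
    base_quality_sum = runif(n, 0, 4))
  cal <- calibrate_sigma(reads, sigma_grid = 3)
  q <- distance_penalty(reads$max_pair_distance, 3) * reads$base_quality_sum
  expect_equal(cal$auc, auc_pairwise(reads$gene != "UNEXPECTED", q),
               tolerance = 1e-9)
})

test_that("permuted labels give chance-level calibration AUC", {
  set.seed(77)
  base <- tibble::tibble(
    gene = rep(c("g1", "UNEXPECTED"), each = 100),
    max_pair_distance = c(runif(100, 0, 1), runif(100, 2, 5)),
    base_quality_sum = c(runif(100, 3, 4), runif(100, 0, 1)))
  aucs <- vapply(1:50, function(i) {
    perm <- base
    perm$gene <- sample(base$gene)
    calibrate_sigma(perm, sigma_grid = 3)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("read filtering applies an inclusive threshold and drops UNEXPECTED", {
  reads <- tibble::tibble(
    gene = c("g1", "g2", "g3", "UNEXPECTED"),
    quality = c(1.9, 2.0, 2.5, 3.9))
  expect_equal(filter_reads(reads, 2)$gene, c("g2", "g3"))
  expect_equal(nrow(filter_reads(reads, 0)), 3)   # all codebook matches kept
  only_bad <- reads[4, ]
  expect_equal(nrow(filter_reads(only_bad, 0)), 0)
})
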