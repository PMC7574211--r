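test_that("edge and node weights follow their closed forms", {
  cand <- tibble::tibble(
    id = 1:2, cycle = 1:2, channel = c("A", "C"),
    x = c(0, 1), y = c(0, 0), intensity = 1, p = c(0.5, 1))
  g <- build_detection_graph(cand, k = 1, d_th = 2, d_max = 3, n_cycles = 2)
  expect_equal(g$edges$weight, log(2))            # d = 1, k = 1
  # zero distance costs nothing for any k
  cand0 <- cand; cand0$x <- c(0, 0)
  g0 <- build_detection_graph(cand0, k = 7, d_th = 2, d_max = 3, n_cycles = 2)
  expect_equal(g0$edges$weight, 0)
  # node weight -log(p): check through a solved path cost
  expect_equal(path_cost(g0, c(1, 2)), -log(0.5) - log(1))
})

test_that("probabilities must be valid before building the graph", {
  cand <- tibble::tibble(id = 1L, cycle = 1L, channel = "A",
                         x = 0, y = 0, intensity = 1, p = 1.2)
  expect_error(build_detection_graph(cand, n_cycles = 1), "lie in \\(0, 1\\]")
  cand$p <- NA_real_
  expect_error(build_detection_graph(cand, n_cycles = 1), "probabilities")
  # empty input yields an empty graph and no paths
  g <- build_detection_graph(cand[0, ], n_cycles = 2)
  expect_equal(nrow(g$candidates), 0)
  expect_equal(solve_detection_graph(g), list())
})

test_that("the worked-example fixture decodes to its published topology", {
  fx <- worked_example_fixture()
  expect_equal(nrow(fx$detections), 14)
  expect_equal(sort(unique(fx$detections$cycle)), 1:4)
  g <- build_detection_graph(fx$detections, k = 1, d_th = 2, d_max = 3,
                             n_cycles = 4)
  expect_equal(length(unique(g$candidates$component)),
               fx$expected_components)
  # forced (dash-dotted) connections exist alongside direct ones
  expect_true(all(c("direct", "forced") %in% g$edges$type))
  paths <- solve_detection_graph(g)
  labels <- purrr::map(paths, ~ fx$detections$label[match(.x, fx$detections$id)])
  expect_equal(length(paths), 3)
  expect_setequal(purrr::map_chr(labels, paste, collapse = ","),
                  purrr::map_chr(fx$expected_paths, paste, collapse = ","))
  cb <- codebook(c("g1", "g2", "g3"), c("TAGT", "GCAC", "GCAG"))
  reads <- decode_reads(paths, fx$detections, cb)
  expect_setequal(reads$barcode, fx$expected_sequences)
  expect_setequal(reads$gene, c("g1", "g2", "g3"))
})

test_that("a single chain decodes to exactly that path", {
  cand <- tibble::tibble(
    id = 1:4, cycle = 1:4, channel = c("A", "C", "G", "T"),
    x = c(0, 0.3, 0.1, 0.2), y = 0, intensity = 1, p = 0.9)
  g <- build_detection_graph(cand, n_cycles = 4)
  paths <- solve_detection_graph(g)
  expect_equal(paths, list(1:4))
})

test_that("solver equals exhaustive enumeration on random graphs", {
  for (s in 1:60) {
    cand <- random_candidates(s)
    g <- build_detection_graph(cand, k = 1, d_th = 2, d_max = 3,
                               n_cycles = max(cand$cycle))
    sol <- solve_detection_graph(g)
    want <- best_disjoint_path_set_all(g)
    expect_equal(length(sol), want$flow, info = paste("seed", s))
    expect_equal(solution_cost(g, sol), want$cost, tolerance = 1e-9,
                 info = paste("seed", s))
    # node-disjointness
    used <- unlist(sol)
    expect_equal(anyDuplicated(used), 0)
    # conservation: per component, reads <= min per-cycle candidate count
    for (comp in unique(g$candidates$component)) {
      rows <- g$candidates[g$candidates$component == comp, ]
      npaths <- sum(vapply(sol, function(p) p[1] %in% rows$id, logical(1)))
      if (all(seq_len(g$params$n_cycles) %in% rows$cycle)) {
        expect_lte(npaths, min(table(factor(rows$cycle,
                                            seq_len(g$params$n_cycles)))))
      } else {
        expect_equal(npaths, 0)
      }
    }
  }
})

test_that("graph construction links components before pruning to consecutive cycles", {
  # cycles 1 and 3 nearby (non-consecutive); cycle 2 reachable only via d_max
  cand <- tibble::tibble(
    id = 1:3, cycle = c(1L, 3L, 2L), channel = c("A", "G", "C"),
    x = c(0, 0.5, 2.4), y = 0, intensity = 1, p = 0.9)
  g <- build_detection_graph(cand, k = 1, d_th = 2, d_max = 3, n_cycles = 3)
  # all one component (1-3 within d_th)
  expect_equal(length(unique(g$candidates$component)), 1)
  # every surviving edge joins consecutive cycles only
  cyc <- cand$cycle[match(c(g$edges$from, g$edges$to), cand$id)]
  m <- matrix(cyc, ncol = 2)
  expect_true(all(abs(m[, 1] - m[, 2]) == 1))
  expect_equal(solve_detection_graph(g), list(c(1L, 3L, 2L)))
})

test_that("reads carry barcode, centroid position and codebook match", {
  cand <- tibble::tibble(
    id = 1:4, cycle = 1:4, channel = c("A", "C", "G", "T"),
    x = c(0, 2, 0, 2), y = c(0, 0, 2, 2), intensity = 1, p = 0.9)
  reads <- decode_reads(list(1:4), cand, codebook(character(), character()))
  expect_equal(reads$barcode, "ACGT")
  expect_equal(reads$gene, "UNEXPECTED")
  expect_equal(c(reads$x, reads$y), c(1, 1))
  expect_equal(reads$max_pair_distance, 2 * sqrt(2))
  # wrong path length errors
  expect_error(decode_reads(list(1:3), cand, codebook("g", "ACGT")),
               "one candidate per cycle")
})
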