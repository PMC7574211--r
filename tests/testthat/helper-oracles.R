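# Independent oracles and shared fixtures for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# deterministic codebook over all length-4 barcodes
test_codebook <- function(n = 24, n_cycles = 4, seed = 42) {
  bases <- c("A", "C", "G", "T")
  all_bc <- do.call(expand.grid, rep(list(bases), n_cycles))
  all_bc <- apply(all_bc, 1, paste, collapse = "")
  withr::with_seed(seed, codebook(paste0("g", seq_len(n)), sample(all_bc, n)))
}

# signal models trained on independent simulations, cached per session.
# The percentile normalization makes intensity scales density-dependent, so
# each model is trained at the field size it will score.
trained_model_at <- function(image_size, n_rolonies, seed) {
  with_cache(paste0("model", image_size), {
    cb <- test_codebook()
    tr <- simulate_iss(sim_config(image_size = image_size,
                                  n_rolonies = n_rolonies, seed = seed), cb)
    stats <- estimate_normalization(tr$stack,
                                    patch_size = min(128, image_size),
                                    seed = 1)
    norm <- normalize_stack(tr$stack, stats)
    train_signal_model(training_windows(tr, norm, seed = 2), seed = 3)
  })
}

trained_model <- function() trained_model_at(256, 150, 990L)
trained_model_small <- function() trained_model_at(128, 50, 991L)

# --- oracle: grayscale reconstruction by sequential raster scans -----------
# (independent of the package's parallel-dilation implementation)
naive_reconstruct <- function(marker, mask) {
  nr <- nrow(marker); nc <- ncol(marker)
  v <- pmin(marker, mask)
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {          # forward
      best <- v[r, cc]
      for (dr in -1:0) for (dc in -1:1) {
        if (dr == 0 && dc >= 0) next
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && c2 >= 1 && c2 <= nc) best <- max(best, v[rr, c2])
      }
      nv <- min(best, mask[r, cc])
      if (nv != v[r, cc]) { v[r, cc] <- nv; changed <- TRUE }
    }
    for (r in rev(seq_len(nr))) for (cc in rev(seq_len(nc))) { # backward
      best <- v[r, cc]
      for (dr in 0:1) for (dc in -1:1) {
        if (dr == 0 && dc <= 0) next
        rr <- r + dr; c2 <- cc + dc
        if (rr <= nr && c2 >= 1 && c2 <= nc) best <- max(best, v[rr, c2])
      }
      nv <- min(best, mask[r, cc])
      if (nv != v[r, cc]) { v[r, cc] <- nv; changed <- TRUE }
    }
    if (!changed) break
  }
  v
}

# --- oracle: exhaustive node-disjoint path-set enumeration -----------------
# total cost of one candidate-id path under a detection graph
path_cost <- function(graph, ids) {
  cand <- graph$candidates
  cost <- sum(-log(cand$p[match(ids, cand$id)]))
  for (b in seq_len(length(ids) - 1L)) {
    e <- graph$edges[(graph$edges$from == ids[b] & graph$edges$to == ids[b + 1]) |
                     (graph$edges$from == ids[b + 1] & graph$edges$to == ids[b]), ]
    if (nrow(e) == 0) stop("path uses a non-existent edge")
    cost <- cost + e$weight[1]
  }
  cost
}

# all complete source-sink paths (one candidate per cycle, consecutive edges)
enumerate_paths <- function(graph) {
  cand <- graph$candidates
  ncyc <- graph$params$n_cycles
  adj <- split(graph$edges$to, graph$edges$from)
  paths <- lapply(cand$id[cand$cycle == 1L], function(i) i)
  for (cyc in seq_len(ncyc - 1L)) {
    nxt <- list()
    for (p in paths) {
      last <- p[length(p)]
      for (j in adj[[as.character(last)]]) {
        if (cand$cycle[match(j, cand$id)] == cyc + 1L) {
          nxt[[length(nxt) + 1L]] <- c(p, j)
        }
      }
    }
    paths <- nxt
    if (!length(paths)) return(list())
  }
  paths
}

# best (max cardinality, then min cost) node-disjoint subset of paths,
# by branch-and-bound over the path list
best_disjoint_path_set <- function(graph) {
  paths <- enumerate_paths(graph)
  if (!length(paths)) return(list(flow = 0L, cost = 0))
  costs <- vapply(paths, function(p) path_cost(graph, p), numeric(1))
  best_flow <- 0L; best_cost <- Inf
  n <- length(paths)
  recurse <- function(i, used, flow, cost) {
    if (flow > best_flow || (flow == best_flow && cost < best_cost)) {
      best_flow <<- flow; best_cost <<- cost
    }
    if (i > n) return()
    if (flow + (n - i + 1L) < best_flow) return()   # cannot catch up
    p <- paths[[i]]
    if (!any(p %in% used)) recurse(i + 1L, c(used, p), flow + 1L, cost + costs[i])
    recurse(i + 1L, used, flow, cost)
  }
  recurse(1L, integer(0), 0L, 0)
  list(flow = best_flow, cost = best_cost)
}

# a random small candidate set for solver stress tests
random_candidates <- function(seed, max_n = 12, n_cycles = sample(3:4, 1)) {
  withr::with_seed(seed, {
    ncyc <- n_cycles
    n <- sample(ncyc:max_n, 1)
    cycles <- c(seq_len(ncyc), sample(seq_len(ncyc), n - ncyc, replace = TRUE))
    tibble::tibble(
      id = seq_len(n),
      cycle = as.integer(sort(cycles)),
      channel = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      x = round(stats::runif(n, 0, 7), 2),
      y = round(stats::runif(n, 0, 7), 2),
      intensity = stats::runif(n, 0.2, 2),
      p = stats::runif(n, 0.05, 1)
    )
  })
}

# total cost of a solver result
solution_cost <- function(graph, paths) {
  if (!length(paths)) return(0)
  sum(vapply(paths, function(p) path_cost(graph, p), numeric(1)))
}

# --- oracle: ROC AUC as pairwise concordance -------------------------------
auc_pairwise <- function(labels, scores) {
  pos <- scores[labels]; neg <- scores[!labels]
  gr <- outer(pos, neg, ">"); eq <- outer(pos, neg, "==")
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# oracle over a whole (possibly multi-component) graph
best_disjoint_path_set_all <- function(graph) {
  cand <- graph$candidates
  flow <- 0L; cost <- 0
  for (comp in unique(cand$component)) {
    rows <- cand[cand$component == comp, ]
    sub <- graph
    sub$candidates <- rows
    sub$edges <- graph$edges[graph$edges$from %in% rows$id &
                               graph$edges$to %in% rows$id, ]
    r <- best_disjoint_path_set(sub)
    flow <- flow + r$flow; cost <- cost + r$cost
  }
  list(flow = flow, cost = cost)
}
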