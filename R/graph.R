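#' Build the detection graph across sequencing cycles
#'
#' Each candidate becomes a split D-node: an in/out node pair joined by an
#' edge of weight `-log(p)`, so that routing a unit of flow through a
#' detection pays its improbability. Candidates of *different* cycles closer
#' than `d_th` are linked first and the resulting connected components are
#' the decoding units; within each component, "forced" edges are then added
#' between unconnected candidates of *consecutive* cycles closer than
#' `d_max`; finally all links between non-consecutive cycles are dropped.
#' Inter-cycle edges cost `-log(1 / (1 + k * d))`, i.e. `log(1 + k * d)` for
#' Euclidean pixel distance `d`. A source feeds every first-cycle node and
#' every last-cycle node drains to a sink, both at zero cost.
#'
#' @param candidates Candidate tibble with columns `id`, `cycle`, `channel`,
#'   `x`, `y`, `intensity`, `p` (probabilities in (0, 1\]).
#' @param k Distance weighting of inter-cycle edge costs.
#' @param d_th Direct-connection distance in pixels.
#' @param d_max Forced-connection distance (`d_max >= d_th`).
#' @param n_cycles Number of sequencing cycles.
#' @return An `iss_detection_graph`: the candidates (with a `component`
#'   column), an edge tibble (`from`, `to`, `d`, `weight`, `type`), and the
#'   parameters.
#' @export
build_detection_graph <- function(candidates, k = 1, d_th = 2, d_max = 3,
                                  n_cycles = max(candidates$cycle)) {
  stopifnot(d_th > 0, d_max >= d_th, k > 0)
  candidates <- tibble::as_tibble(candidates)
  n <- nrow(candidates)
  if (n > 0) {
    if (!"p" %in% names(candidates) || any(is.na(candidates$p)) ||
        any(candidates$p <= 0 | candidates$p > 1)) {
      stop("all candidate probabilities must be set and lie in (0, 1]")
    }
    if (is.null(candidates$id)) candidates$id <- seq_len(n)
  }
  empty_edges <- tibble::tibble(from = integer(), to = integer(),
                                d = numeric(), weight = numeric(),
                                type = character())
  if (n == 0) {
    candidates$component <- integer(0)
    return(structure(list(candidates = candidates, edges = empty_edges,
                          params = list(k = k, d_th = d_th, d_max = d_max,
                                        n_cycles = n_cycles)),
                     class = "iss_detection_graph"))
  }
  # neighbour search on a coarse grid of cell size d_max
  cell <- d_max
  cx <- floor(candidates$x / cell); cy <- floor(candidates$y / cell)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  key <- paste(cx, cy, sep = ",")
  for (i in seq_len(n)) buckets[[key[i]]] <- c(buckets[[key[i]]], i)
  pairs_from <- integer(0); pairs_to <- integer(0); pairs_d <- numeric(0)
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      js <- buckets[[paste(cx[i] + dx, cy[i] + dy, sep = ",")]]
      js <- js[js > i & candidates$cycle[js] != candidates$cycle[i]]
      if (!length(js)) next
      d <- sqrt((candidates$x[js] - candidates$x[i])^2 +
                (candidates$y[js] - candidates$y[i])^2)
      ok <- d < d_max
      if (any(ok)) {
        pairs_from <- c(pairs_from, rep.int(i, sum(ok)))
        pairs_to <- c(pairs_to, js[ok])
        pairs_d <- c(pairs_d, d[ok])
      }
    }
  }
  direct <- pairs_d < d_th
  # connected components on direct links (any cycle pair)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(direct)) {
    g <- igraph::add_edges(g, rbind(pairs_from[direct], pairs_to[direct]))
  }
  comp <- igraph::components(g)$membership
  candidates$component <- as.integer(comp)

  consec <- abs(candidates$cycle[pairs_from] - candidates$cycle[pairs_to]) == 1L
  same_comp <- comp[pairs_from] == comp[pairs_to]
  keep_direct <- direct & consec
  keep_forced <- !direct & consec & same_comp
  keep <- keep_direct | keep_forced
  edges <- tibble::tibble(
    from = candidates$id[pairs_from[keep]],
    to = candidates$id[pairs_to[keep]],
    d = pairs_d[keep],
    weight = log1p(k * pairs_d[keep]),
    type = ifelse(keep_direct[keep], "direct", "forced")
  )
  # orient from the earlier cycle to the later one
  swap <- candidates$cycle[match(edges$from, candidates$id)] >
    candidates$cycle[match(edges$to, candidates$id)]
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  structure(list(candidates = candidates, edges = edges,
                 params = list(k = k, d_th = d_th, d_max = d_max,
                               n_cycles = n_cycles)),
            class = "iss_detection_graph")
}

#' @export
print.iss_detection_graph <- function(x, ...) {
  cat(sprintf("<iss_detection_graph> %d candidates, %d edges, %d components\n",
              nrow(x$candidates), nrow(x$edges),
              length(unique(x$candidates$component))))
  invisible(x)
}

# min-cost max-flow on one component by successive shortest paths.
# cand: rows of the candidate tibble; edges: rows of the edge tibble
# restricted to this component. Returns list of candidate-id paths.
mcmf_component <- function(cand, edges, n_cycles) {
  m <- nrow(cand)
  if (!all(seq_len(n_cycles) %in% cand$cycle)) return(list())
  S <- 2L * m + 1L; T <- 2L * m + 2L
  nv <- 2L * m + 2L
  ef <- integer(0); et <- integer(0); ecap <- numeric(0); ecost <- numeric(0)
  add_edge <- function(a, b, cap, cost) {
    # forward edge at odd position, residual at the following even position
    ef <<- c(ef, a, b); et <<- c(et, b, a)
    ecap <<- c(ecap, cap, 0); ecost <<- c(ecost, cost, -cost)
  }
  idx <- stats::setNames(seq_len(m), cand$id)
  for (i in seq_len(m)) {
    add_edge(i, m + i, 1, -log(cand$p[i]))
    if (cand$cycle[i] == 1L) add_edge(S, i, 1, 0)
    if (cand$cycle[i] == n_cycles) add_edge(m + i, T, 1, 0)
  }
  for (e in seq_len(nrow(edges))) {
    a <- idx[[as.character(edges$from[e])]]
    b <- idx[[as.character(edges$to[e])]]
    add_edge(m + a, b, 1, edges$weight[e])
  }
  ne <- length(ef)
  adj <- vector("list", nv)
  for (e in seq_len(ne)) adj[[ef[e]]] <- c(adj[[ef[e]]], e)
  orig_cap <- ecap
  eps <- 1e-12
  repeat {
    # Bellman-Ford over the residual network (residual arcs carry negative
    # costs, so Dijkstra does not apply without potentials)
    dist <- rep(Inf, nv); dist[S] <- 0
    pred_edge <- integer(nv)
    for (pass in seq_len(nv)) {
      changed <- FALSE
      for (e in seq_len(ne)) {
        if (ecap[e] <= 0) next
        nd <- dist[ef[e]] + ecost[e]
        if (nd < dist[et[e]] - eps) {
          dist[et[e]] <- nd; pred_edge[et[e]] <- e; changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[T])) break
    v <- T
    while (v != S) {
      e <- pred_edge[v]
      ecap[e] <- ecap[e] - 1
      r <- if (e %% 2L == 1L) e + 1L else e - 1L
      ecap[r] <- ecap[r] + 1
      v <- ef[e]
    }
  }
  flow <- orig_cap - ecap
  paths <- list()
  for (e in seq_len(ne)) {
    if (ef[e] == S && flow[e] > 0) {
      path <- integer(0)
      v <- et[e]                       # an in-node of cycle 1
      repeat {
        path <- c(path, cand$id[v])
        out_v <- v + m
        nxt <- NA_integer_
        for (e2 in adj[[out_v]]) {
          if (e2 %% 2L == 1L && flow[e2] > 0 && et[e2] != out_v) {
            nxt <- et[e2]
            flow[e2] <- 0              # consume so shared nodes cannot repeat
            break
          }
        }
        if (is.na(nxt) || nxt == T) break
        v <- nxt
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  paths
}

#' Solve a detection graph by maximum flow of minimum cost
#'
#' Every detection and every inter-cycle link has unit capacity, so the
#' maximum flow equals the largest number of node-disjoint source-to-sink
#' paths, and among all maximum flows the one of least total cost (summed
#' detection and distance weights) is found by successive shortest-path
#' augmentation. Each component is solved independently; a component that
#' does not span all cycles yields no path (a complete barcode needs one
#' base per cycle).
#'
#' @param graph An `iss_detection_graph`.
#' @return A list of integer vectors of candidate ids, each ordered by cycle.
#' @export
solve_detection_graph <- function(graph) {
  cand <- graph$candidates
  if (nrow(cand) == 0) return(list())
  out <- list()
  for (comp in sort(unique(cand$component))) {
    rows <- cand[cand$component == comp, ]
    ed <- graph$edges[graph$edges$from %in% rows$id & graph$edges$to %in% rows$id, ]
    paths <- mcmf_component(rows, ed, graph$params$n_cycles)
    out <- c(out, paths)
  }
  out
}

#' Decode candidate paths into gene reads
#'
#' Concatenates the channel letters along each path in cycle order into a
#' barcode, looks it up in the codebook (unmatched barcodes are labelled
#' `UNEXPECTED` and retained for quality calibration), and places the read at
#' the centroid of its detections. The maximum pairwise distance between the
#' path's detections is recorded for the distance penalty of the quality
#' score.
#'
#' @param paths List of candidate-id vectors from [solve_detection_graph()].
#' @param candidates The candidate tibble used to build the graph.
#' @param cb An [codebook()].
#' @return A tibble of reads: `read_id`, `x`, `y`, `barcode`, `gene`,
#'   `max_pair_distance`, `path` (list-column of candidate ids).
#' @export
decode_reads <- function(paths, candidates, cb) {
  nc <- if (nrow(cb) > 0) barcode_length(cb) else
    length(unique(candidates$cycle))
  rows <- purrr::map(paths, function(p) {
    cd <- candidates[match(p, candidates$id), ]
    if (nrow(cd) != nc || anyNA(cd$id) ||
        !identical(sort(cd$cycle), seq_len(nc))) {
      stop("path must have exactly one candidate per cycle")
    }
    cd <- cd[order(cd$cycle), ]
    dmat <- as.matrix(stats::dist(cbind(cd$x, cd$y)))
    tibble::tibble(
      x = mean(cd$x), y = mean(cd$y),
      barcode = paste(cd$channel, collapse = ""),
      max_pair_distance = max(dmat),
      path = list(cd$id)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(read_id = integer(), x = numeric(), y = numeric(),
                          barcode = character(), gene = character(),
                          max_pair_distance = numeric(), path = list()))
  }
  out$gene <- match_barcodes(cb, out$barcode)
  out$read_id <- seq_len(nrow(out))
  out[, c("read_id", "x", "y", "barcode", "gene", "max_pair_distance", "path")]
}
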