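# 3x3 maximum filter with -Inf outside the border (so dilation never imports
# values across the image edge)
max_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)])
  }
  out
}

#' Grayscale morphological reconstruction by dilation
#'
#' Iteratively dilates `marker` (8-connected, 3x3 structuring element) while
#' clamping it under `mask`, until stable. Used to compute the h-maxima
#' transform; exposed for testing.
#'
#' @param marker Numeric matrix, elementwise `<= mask`.
#' @param mask Numeric matrix of the same dimensions.
#' @return The reconstructed matrix.
#' @export
reconstruct_dilation <- function(marker, mask) {
  stopifnot(identical(dim(marker), dim(mask)), all(marker <= mask))
  cur <- marker
  limit <- sum(dim(mask)) + 2L
  for (i in seq_len(limit)) {
    nxt <- pmin(max_filter3(cur), mask)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

#' h-maxima transform
#'
#' Suppresses all regional maxima whose height above their surroundings
#' (dynamic) is below `h`: the reconstruction by dilation of `image - h`
#' under `image`.
#'
#' @param image Numeric matrix.
#' @param h Positive height threshold.
#' @return Matrix of the same dimensions.
#' @export
h_maxima <- function(image, h) {
  stopifnot(h > 0)
  reconstruct_dilation(image - h, image)
}

# label 8-connected components of a logical mask; returns integer matrix
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  nxt <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start; lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L; c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || cc < 1L || rr > nr || cc > ncol(mask)) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) { lab[j] <- nxt; queue <- c(queue, j) }
      }
    }
  }
  lab
}

#' Detect signal candidates in one normalized image
#'
#' Applies a white top-hat filter (disk structuring element of radius
#' `tophat_radius`) to enhance diffraction-limited spots, then keeps every
#' regional maximum whose dynamic exceeds `h` via the h-maxima transform.
#' A candidate's position is the centroid of its maximum plateau (0-based
#' pixel coordinates, `x` = column, `y` = row) and its intensity the filtered
#' value there.
#'
#' Positions are refined to sub-pixel precision by an intensity-weighted
#' centroid over the 3x3 neighbourhood of the plateau, the standard
#' refinement for diffraction-limited spots; without it, pixel quantization
#' would inflate the inter-cycle distances the decoder depends on.
#'
#' @param image Numeric matrix of normalized intensities.
#' @param h Positive h-maxima threshold; a generous (low) value relative to
#'   spot intensities is intended, with residual noise removed downstream by
#'   the signal probability model. Under the percentile normalization spot
#'   peaks land at roughly 1-3, so the default keeps a >5x margin below the
#'   faintest spots while staying above the noise floor.
#' @param tophat_radius Disk radius of the top-hat structuring element.
#' @param cycle,channel Metadata stamped on the returned candidates.
#' @return A tibble of candidates: `cycle`, `channel`, `x`, `y`, `intensity`.
#' @export
detect_candidates <- function(image, h = 0.2, tophat_radius = 2,
                              cycle = 1L, channel = "A") {
  stopifnot(h > 0, tophat_radius >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(tophat_radius) + 1L, shape = "disc")
  f <- as.matrix(EBImage::whiteTopHat(image, brush))
  H <- h_maxima(f, h)
  mask <- (f - H) >= h - 1e-9 & f > min(f)
  lab <- label_components8(mask)
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(cycle = integer(), channel = character(),
                          x = numeric(), y = numeric(), intensity = numeric()))
  }
  idx <- which(lab > 0L)
  comp <- lab[idx]
  nr <- nrow(image)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  x <- as.numeric(tapply(cols - 1L, comp, mean))
  y <- as.numeric(tapply(rows - 1L, comp, mean))
  inten <- as.numeric(tapply(f[idx], comp, max))
  # sub-pixel refinement: intensity-weighted centroid on the 5x5 window
  # around the plateau centroid (covers most of a diffraction-limited PSF)
  nc_img <- ncol(image)
  for (i in seq_along(x)) {
    r0 <- min(max(floor(y[i] + 0.5) + 1L, 3L), nr - 2L)
    c0 <- min(max(floor(x[i] + 0.5) + 1L, 3L), nc_img - 2L)
    rr <- (r0 - 2L):(r0 + 2L); cc <- (c0 - 2L):(c0 + 2L)
    w <- pmax(f[rr, cc], 0)
    sw <- sum(w)
    if (sw > 0) {
      y[i] <- sum((rr - 1L) * rowSums(w)) / sw
      x[i] <- sum((cc - 1L) * colSums(w)) / sw
    }
  }
  out <- tibble::tibble(
    cycle = as.integer(cycle), channel = channel,
    x = x, y = y, intensity = inten
  )
  out[order(out$y, out$x), ]
}

#' Merge duplicate detections across channels within one cycle
#'
#' A rolony fluoresces in a single base channel per cycle, so detections of
#' the same spot appearing in several channels (e.g. through spectral
#' bleed-through) are duplicates. Candidates from *different* channels whose
#' rounded pixel positions coincide or are 4-adjacent are grouped
#' transitively; each group keeps its highest-intensity member and records
#' the suppressed candidates in the `merged_from` list-column (these later
#' act as competitors in per-base quality scoring). Intensity ties keep the
#' candidate with lexicographically smallest (channel, x, y).
#'
#' @param candidates Tibble of candidates from a single cycle, with columns
#'   `id`, `cycle`, `channel`, `x`, `y`, `intensity` (and optionally `p`).
#' @return The kept candidates with a `merged_from` list-column of the
#'   suppressed candidates' rows.
#' @export
merge_channels <- function(candidates) {
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0) {
    candidates$merged_from <- list()
    return(candidates)
  }
  if (length(unique(candidates$cycle)) != 1) {
    stop("merge_channels expects candidates from a single cycle")
  }
  if (is.null(candidates$id)) candidates$id <- seq_len(nrow(candidates))
  n <- nrow(candidates)
  # round-half-up to the pixel grid for adjacency tests
  px <- floor(candidates$x + 0.5); py <- floor(candidates$y + 0.5)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  # hashed pixel buckets: coincident or 4-adjacent pairs only
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  keys <- paste(px, py, sep = ",")
  for (i in seq_len(n)) {
    b <- buckets[[keys[i]]]
    buckets[[keys[i]]] <- c(b, i)
  }
  neigh_keys <- function(i) c(
    keys[i],
    paste(px[i] + 1L, py[i], sep = ","),
    paste(px[i], py[i] + 1L, sep = ",")
  )
  for (i in seq_len(n)) {
    for (k in neigh_keys(i)) {
      for (j in buckets[[k]]) {
        if (j > i && candidates$channel[i] != candidates$channel[j]) link(i, j)
        if (j < i && k != keys[i] && candidates$channel[i] != candidates$channel[j]) link(i, j)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep_rows <- integer(0); merged <- list()
  for (g in unique(root)) {
    members <- which(root == g)
    ord <- members[order(-candidates$intensity[members],
                         candidates$channel[members],
                         candidates$x[members], candidates$y[members])]
    keep_rows <- c(keep_rows, ord[1])
    merged[[length(merged) + 1L]] <- candidates[setdiff(members, ord[1]), , drop = FALSE]
  }
  out <- candidates[keep_rows, ]
  out$merged_from <- merged
  out[order(out$id), ]
}
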