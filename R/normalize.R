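#' Estimate per-channel normalization statistics
#'
#' For every sequencing cycle and every anchor/base channel, samples
#' `n_patches` random square patches and derives a robust background and
#' signal level: the background is the mean of the per-patch intensity modes,
#' and the signal is the 99th percentile of the per-patch 98th intensity
#' percentiles. The nuclei channel is not part of decoding and is skipped.
#'
#' The patch mode is taken on binned intensities: bin width 1 for integer
#' images, otherwise 256 equal bins over the patch range (a mode is undefined
#' for continuous data).
#'
#' @param stack An `iss_stack` of raw registered images.
#' @param n_patches Number of random patches per channel.
#' @param patch_size Patch side length in pixels; must fit in the image.
#' @param seed Integer seed for patch sampling.
#' @return A tibble with columns `cycle`, `channel`, `background`, `signal`,
#'   carrying `n_patches`, `patch_size` and `seed` as attributes; class
#'   `iss_norm_stats`.
#' @export
estimate_normalization <- function(stack, n_patches = 50, patch_size = 128,
                                   seed = 1L) {
  stopifnot(n_patches >= 1)
  nr <- stack$dim[1]; nc <- stack$dim[2]
  patch_size <- min(patch_size, nr, nc)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  chans <- c("anchor", iss_bases())
  rows <- list()
  for (cyc in seq_len(n_cycles(stack))) {
    for (ch in chans) {
      im <- stack_image(stack, cyc, ch)
      r0 <- sample.int(nr - patch_size + 1L, n_patches, replace = TRUE)
      c0 <- sample.int(nc - patch_size + 1L, n_patches, replace = TRUE)
      modes <- numeric(n_patches); p98 <- numeric(n_patches)
      for (i in seq_len(n_patches)) {
        p <- im[r0[i]:(r0[i] + patch_size - 1L), c0[i]:(c0[i] + patch_size - 1L)]
        modes[i] <- patch_mode(p)
        p98[i] <- stats::quantile(p, 0.98, names = FALSE)
      }
      bg <- mean(modes)
      sig <- stats::quantile(p98, 0.99, names = FALSE)
      if (!(sig > bg)) {
        stop("degenerate channel (signal <= background): cycle ", cyc,
             ", channel ", ch)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cycle = cyc, channel = ch, background = bg, signal = sig
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_patches") <- n_patches
  attr(out, "patch_size") <- patch_size
  attr(out, "seed") <- seed
  class(out) <- c("iss_norm_stats", class(out))
  out
}

# histogram mode of one patch: bin width 1 for integer-valued data,
# 256 equal-width bins otherwise; ties resolved to the lowest bin
patch_mode <- function(p) {
  v <- as.vector(p)
  if (all(v == round(v))) {
    tab <- tabulate(v - min(v) + 1L)
    return(min(v) + which.max(tab) - 1L)
  }
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257L)
  counts <- findInterval(v, br, rightmost.closed = TRUE)
  k <- which.max(tabulate(counts, nbins = 256L))
  (br[k] + br[k + 1L]) / 2
}

#' Normalize a stack using estimated statistics
#'
#' Rescales each anchor/base image linearly so the estimated background maps
#' to 0 and the estimated signal level to 1. Values below 0 are clipped;
#' values above 1 are retained (bright spots may exceed the robust signal
#' estimate). The nuclei channel is passed through unchanged.
#'
#' @param stack An `iss_stack` of raw images.
#' @param stats An `iss_norm_stats` tibble from [estimate_normalization()]
#'   covering every cycle and anchor/base channel of `stack`.
#' @return A normalized `iss_stack`.
#' @export
normalize_stack <- function(stack, stats) {
  chans <- c("anchor", iss_bases())
  imgs <- stack$images
  for (cyc in seq_len(n_cycles(stack))) {
    for (ch in chans) {
      row <- stats[stats$cycle == cyc & stats$channel == ch, ]
      if (nrow(row) != 1) {
        stop("no normalization stats for cycle ", cyc, ", channel ", ch)
      }
      im <- (imgs[[cyc]][[ch]] - row$background) / (row$signal - row$background)
      imgs[[cyc]][[ch]] <- pmax(im, 0)
    }
  }
  channel_stack(imgs, pixel_size = stack$pixel_size)
}

# integer circular-free shift with zero padding; s = c(dy, dx) applied so the
# content moves by +dy rows, +dx columns
shift_image <- function(im, dy, dx) {
  out <- matrix(0, nrow(im), ncol(im))
  nr <- nrow(im); nc <- ncol(im)
  src_r <- max(1, 1 - dy):min(nr, nr - dy)
  src_c <- max(1, 1 - dx):min(nc, nc - dx)
  if (!length(src_r) || !length(src_c)) return(out)
  out[src_r + dy, src_c + dx] <- im[src_r, src_c]
  out
}

# translation between two images by FFT cross-correlation of mean-centred
# intensities; returns c(dy, dx) moving `im` onto `ref`, with parabolic
# sub-pixel refinement
estimate_shift <- function(ref, im) {
  a <- ref - mean(ref); b <- im - mean(im)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(c(0, 0))
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  k <- which.max(cc)
  nr <- nrow(cc); nc <- ncol(cc)
  r <- (k - 1) %% nr + 1; c <- (k - 1) %/% nr + 1
  refine <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
  }
  rm1 <- cc[(r - 2) %% nr + 1, c]; rp1 <- cc[r %% nr + 1, c]
  cm1 <- cc[r, (c - 2) %% nc + 1]; cp1 <- cc[r, c %% nc + 1]
  dy <- (r - 1) + refine(rm1, cc[r, c], rp1)
  dx <- (c - 1) + refine(cm1, cc[r, c], cp1)
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dy, dx)
}

#' Refine inter-cycle alignment of a tile
#'
#' Estimates, for every cycle, the translation that best aligns its anchor
#' image to the reference cycle's anchor (FFT cross-correlation with
#' parabolic sub-pixel refinement) and applies the rounded shift to all
#' channels of that cycle. Intended as a local touch-up after whole-slide
#' registration, which is assumed done upstream.
#'
#' @param stack An `iss_stack` (typically one tile).
#' @param reference_cycle Cycle whose anchor is the alignment target.
#' @return The shifted `iss_stack`, with a `shifts` attribute: a tibble of
#'   per-cycle estimated (`dy`, `dx`). A flat anchor yields a zero shift with
#'   a warning.
#' @export
refine_alignment <- function(stack, reference_cycle = 1L) {
  ref <- stack_image(stack, reference_cycle, "anchor")
  imgs <- stack$images
  shifts <- tibble::tibble(cycle = seq_len(n_cycles(stack)), dy = 0, dx = 0)
  for (cyc in seq_len(n_cycles(stack))) {
    if (cyc == reference_cycle) next
    anc <- stack_image(stack, cyc, "anchor")
    if (stats::sd(anc) == 0) {
      warning("flat anchor in cycle ", cyc, "; applying zero shift")
      next
    }
    s <- estimate_shift(ref, anc)
    shifts$dy[cyc] <- s[1]; shifts$dx[cyc] <- s[2]
    di <- round(s)
    if (any(di != 0)) {
      imgs[[cyc]] <- purrr::map(imgs[[cyc]], shift_image, dy = di[1], dx = di[2])
    }
  }
  out <- channel_stack(imgs, pixel_size = stack$pixel_size)
  attr(out, "shifts") <- shifts
  out
}

#' Serialize normalization statistics to YAML
#' @param stats An `iss_norm_stats` tibble.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_norm_stats <- function(stats, path) {
  yaml::write_yaml(list(
    n_patches = attr(stats, "n_patches"),
    patch_size = attr(stats, "patch_size"),
    seed = attr(stats, "seed"),
    channels = purrr::pmap(
      as.data.frame(stats)[c("cycle", "channel", "background", "signal")], list)
  ), path)
  invisible(path)
}

#' Read normalization statistics from YAML
#' @param path YAML path written by [write_norm_stats()].
#' @return An `iss_norm_stats` tibble.
#' @export
read_norm_stats <- function(path) {
  y <- yaml::read_yaml(path)
  out <- dplyr::bind_rows(purrr::map(y$channels, tibble::as_tibble))
  out$cycle <- as.integer(out$cycle)
  attr(out, "n_patches") <- y$n_patches
  attr(out, "patch_size") <- y$patch_size
  attr(out, "seed") <- y$seed
  class(out) <- c("iss_norm_stats", class(out))
  out
}
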