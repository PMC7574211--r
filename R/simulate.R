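#' Configuration for the synthetic ISS image generator
#'
#' Bundles the physical parameters of a simulated in situ sequencing
#' experiment. Defaults emulate a sparse-to-moderate rolony field imaged at
#' x20 on an epifluorescence microscope: diffraction-limited spots of
#' Gaussian profile, an autofluorescent background pedestal, additive sensor
#' noise, a fixed-fraction spectral bleed-through into one neighbouring base
#' channel, and sub-pixel registration jitter between cycles.
#'
#' @param image_size Image side length in pixels.
#' @param n_cycles Number of sequencing cycles (barcode length), at least 2.
#' @param n_rolonies Number of rolonies to place.
#' @param psf_sigma Gaussian point-spread sd in pixels.
#' @param background_level Constant background intensity.
#' @param noise_sd Additive Gaussian noise sd.
#' @param bleedthrough_fraction Fraction of each spot copied into the next
#'   base channel (cyclic A->C->G->T->A); must be in [0, 1).
#' @param jitter_sd Per-cycle positional jitter sd in pixels.
#' @param false_spot_rate Expected number of spurious spots per base-channel
#'   image (Poisson).
#' @param amplitude_meanlog,amplitude_sdlog Log-normal peak-amplitude
#'   parameters for rolony spots.
#' @param margin Minimum distance of rolony centres from the image border.
#' @param min_separation Minimum centre-to-centre distance between rolonies
#'   in pixels; rolling-circle products are ~1 um solid DNA balls, so their
#'   centres cannot coincide (rejection-sampled).
#' @param seed Integer seed; identical configurations produce bit-identical
#'   output.
#' @return A list of class `iss_sim_config`.
#' @export
sim_config <- function(image_size = 256, n_cycles = 4, n_rolonies = 200,
                       psf_sigma = 1.5, background_level = 100,
                       noise_sd = 10, bleedthrough_fraction = 0.1,
                       jitter_sd = 0.5, false_spot_rate = 10,
                       amplitude_meanlog = log(900), amplitude_sdlog = 0.25,
                       margin = 6, min_separation = 4, seed = 1L) {
  stopifnot(
    image_size >= 16, n_cycles >= 2, n_rolonies >= 0,
    psf_sigma > 0, background_level >= 0, noise_sd >= 0,
    bleedthrough_fraction >= 0, bleedthrough_fraction < 1,
    jitter_sd >= 0, false_spot_rate >= 0
  )
  structure(as.list(environment()), class = "iss_sim_config")
}

# add a Gaussian spot in place over a local window; im is a matrix,
# (x, y) are 0-based continuous coordinates (x = column, y = row)
add_spot <- function(im, x, y, amplitude, sigma) {
  n <- nrow(im); m <- ncol(im)
  r <- ceiling(4 * sigma)
  rows <- max(1, floor(y + 1 - r)):min(n, ceiling(y + 1 + r))
  cols <- max(1, floor(x + 1 - r)):min(m, ceiling(x + 1 + r))
  if (!length(rows) || !length(cols)) return(im)
  dy <- (rows - 1) - y
  dx <- (cols - 1) - x
  g <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))
  im[rows, cols] <- im[rows, cols] + amplitude * g
  im
}

bleed_partner <- function(channel) {
  c(A = "C", C = "G", G = "T", T = "A")[[channel]]
}

#' Simulate an ISS image series with known ground truth
#'
#' Generates one six-channel image per cycle. Each rolony emits a Gaussian
#' spot in the base channel of its barcode letter for that cycle and in the
#' anchor channel every cycle; a `bleedthrough_fraction` copy of every base
#' spot lands in the next base channel; per-cycle positions are perturbed by
#' Gaussian jitter; spurious spots are added per base-channel image at rate
#' `false_spot_rate`; finally a constant background and Gaussian noise are
#' applied (intensities clipped at zero).
#'
#' @param config An [sim_config()] object.
#' @param cb An [codebook()]; barcode length must equal `config$n_cycles`.
#' @param rolonies Optional tibble with columns `x`, `y`, `gene` (and
#'   optionally `amplitude`) fixing the ground truth instead of sampling it.
#'   Positions must lie inside the image and genes must be in the codebook.
#' @return A list with elements `stack` (an `iss_stack`), `truth`
#'   (tibble: `id`, `x`, `y`, `gene`, `barcode`, `amplitude`) and
#'   `false_spots` (tibble of the spurious spots injected per cycle and
#'   channel).
#' @export
simulate_iss <- function(config, cb, rolonies = NULL) {
  stopifnot(inherits(config, "iss_sim_config"), inherits(cb, "iss_codebook"))
  if (nrow(cb) == 0 && (config$n_rolonies > 0 || !is.null(rolonies))) {
    stop("cannot place rolonies with an empty codebook")
  }
  if (nrow(cb) > 0 && barcode_length(cb) != config$n_cycles) {
    stop("codebook barcode length must equal config$n_cycles")
  }
  sz <- config$image_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  if (is.null(rolonies)) {
    n <- config$n_rolonies
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n && tries < 200L * max(n, 1L)) {
      tries <- tries + 1L
      px <- stats::runif(1, config$margin, sz - 1 - config$margin)
      py <- stats::runif(1, config$margin, sz - 1 - config$margin)
      if (!length(xs) ||
          min((xs - px)^2 + (ys - py)^2) >= config$min_separation^2) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    if (length(xs) < n) stop("could not place ", n, " rolonies at min_separation ",
                             config$min_separation, " in a ", sz, " px image")
    truth <- tibble::tibble(
      id = seq_len(n),
      x = xs, y = ys,
      gene = if (n) sample(cb$gene, n, replace = TRUE) else character(),
      amplitude = stats::rlnorm(n, config$amplitude_meanlog, config$amplitude_sdlog)
    )
  } else {
    truth <- tibble::as_tibble(rolonies)
    if (!all(c("x", "y", "gene") %in% names(truth))) {
      stop("rolonies need columns x, y, gene")
    }
    if (any(truth$x < 0 | truth$x > sz - 1 | truth$y < 0 | truth$y > sz - 1)) {
      stop("rolony position outside the image")
    }
    if (!all(truth$gene %in% cb$gene)) stop("rolony gene missing from codebook")
    if (is.null(truth$amplitude)) {
      truth$amplitude <- stats::rlnorm(nrow(truth), config$amplitude_meanlog,
                                       config$amplitude_sdlog)
    }
    truth$id <- seq_len(nrow(truth))
  }
  truth$barcode <- cb$barcode[match(truth$gene, cb$gene)]
  if (nrow(truth) && any(grepl("[^ACGT]", truth$barcode))) {
    stop("barcode letters outside {A,C,G,T}")
  }

  images <- vector("list", config$n_cycles)
  false_spots <- list()
  # static nuclei texture: a few broad dim blobs, identical across cycles
  nuc <- matrix(0, sz, sz)
  n_nuc <- max(3L, round(sz^2 / 2500))
  nx <- stats::runif(n_nuc, 0, sz - 1); ny <- stats::runif(n_nuc, 0, sz - 1)
  na_ <- stats::runif(n_nuc, 100, 300)
  for (i in seq_len(n_nuc)) nuc <- add_spot(nuc, nx[i], ny[i], na_[i], 4)

  for (cyc in seq_len(config$n_cycles)) {
    base_imgs <- stats::setNames(
      replicate(4, matrix(0, sz, sz), simplify = FALSE), iss_bases())
    anchor <- matrix(0, sz, sz)
    if (nrow(truth)) {
      jx <- stats::rnorm(nrow(truth), 0, config$jitter_sd)
      jy <- stats::rnorm(nrow(truth), 0, config$jitter_sd)
      for (i in seq_len(nrow(truth))) {
        ch <- substr(truth$barcode[i], cyc, cyc)
        px <- min(max(truth$x[i] + jx[i], 0), sz - 1)
        py <- min(max(truth$y[i] + jy[i], 0), sz - 1)
        base_imgs[[ch]] <- add_spot(base_imgs[[ch]], px, py,
                                    truth$amplitude[i], config$psf_sigma)
        anchor <- add_spot(anchor, px, py, truth$amplitude[i], config$psf_sigma)
      }
    }
    # spectral bleed-through: fixed-fraction copy into the partner channel
    if (config$bleedthrough_fraction > 0) {
      clean <- base_imgs
      for (ch in iss_bases()) {
        tgt <- bleed_partner(ch)
        base_imgs[[tgt]] <- base_imgs[[tgt]] + config$bleedthrough_fraction * clean[[ch]]
      }
    }
    for (ch in iss_bases()) {
      n_false <- stats::rpois(1, config$false_spot_rate)
      if (n_false > 0) {
        fx <- stats::runif(n_false, 0, sz - 1)
        fy <- stats::runif(n_false, 0, sz - 1)
        fa <- stats::rlnorm(n_false, config$amplitude_meanlog - 1, 0.4)
        for (i in seq_len(n_false)) {
          base_imgs[[ch]] <- add_spot(base_imgs[[ch]], fx[i], fy[i], fa[i],
                                      config$psf_sigma)
        }
        false_spots[[length(false_spots) + 1L]] <- tibble::tibble(
          cycle = cyc, channel = ch, x = fx, y = fy, amplitude = fa)
      }
    }
    all_imgs <- c(list(nuclei = nuc + 50, anchor = anchor), base_imgs)
    all_imgs <- purrr::map(all_imgs, function(im) {
      im <- im + config$background_level
      if (config$noise_sd > 0) {
        im <- im + matrix(stats::rnorm(sz * sz, 0, config$noise_sd), sz, sz)
      }
      pmax(im, 0)
    })
    images[[cyc]] <- all_imgs
  }
  list(
    stack = channel_stack(images),
    truth = truth[, c("id", "x", "y", "gene", "barcode", "amplitude")],
    false_spots = if (length(false_spots)) dplyr::bind_rows(false_spots) else
      tibble::tibble(cycle = integer(), channel = character(),
                     x = numeric(), y = numeric(), amplitude = numeric())
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write simulated ground truth to CSV
#' @param truth Truth tibble from [simulate_iss()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' Score decoded reads against simulated ground truth
#'
#' Matches reads to ground-truth rolonies one-to-one: candidate pairs are
#' reads and rolonies with equal barcode within `match_radius` pixels,
#' accepted greedily by increasing distance. Recall is matched over truth,
#' precision matched over reads. With no truth (or no reads) the respective
#' rate is undefined and reported as `NA`, which is distinct from 0.
#'
#' @param truth Ground-truth tibble (`x`, `y`, `barcode`).
#' @param reads Decoded reads tibble (`x`, `y`, `barcode`).
#' @param match_radius Maximum centre distance in pixels for a match.
#' @return A one-row tibble: `recall`, `precision`, `n_matched`, `n_truth`,
#'   `n_reads`.
#' @export
score_decoding <- function(truth, reads, match_radius = 2) {
  stopifnot(match_radius > 0)
  n_truth <- nrow(truth); n_reads <- nrow(reads)
  n_matched <- 0L
  if (n_truth > 0 && n_reads > 0) {
    pairs <- tidyr::crossing(ti = seq_len(n_truth), ri = seq_len(n_reads))
    pairs$d <- sqrt((truth$x[pairs$ti] - reads$x[pairs$ri])^2 +
                    (truth$y[pairs$ti] - reads$y[pairs$ri])^2)
    pairs <- pairs[pairs$d <= match_radius &
                     truth$barcode[pairs$ti] == reads$barcode[pairs$ri], ]
    pairs <- pairs[order(pairs$d, pairs$ti, pairs$ri), ]
    used_t <- logical(n_truth); used_r <- logical(n_reads)
    for (i in seq_len(nrow(pairs))) {
      ti <- pairs$ti[i]; ri <- pairs$ri[i]
      if (!used_t[ti] && !used_r[ri]) {
        used_t[ti] <- TRUE; used_r[ri] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  tibble::tibble(
    recall = if (n_truth == 0) NA_real_ else n_matched / n_truth,
    precision = if (n_reads == 0) NA_real_ else n_matched / n_reads,
    n_matched = n_matched, n_truth = n_truth, n_reads = n_reads
  )
}
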