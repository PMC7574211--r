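#' Multi-cycle, multi-channel image stack
#'
#' A `channel_stack` holds the registered 2-D images of one in situ sequencing
#' tile or slide, indexed by sequencing cycle and channel role. Each cycle
#' carries six channels: a nuclei stain, a general ("anchor") stain present for
#' every rolony in every cycle, and one channel per base (A, C, G, T).
#'
#' @param images A list with one element per cycle; each element is a named
#'   list of numeric matrices, all of identical dimensions, whose names are
#'   the channel roles.
#' @param pixel_size Optional physical pixel size in microns per pixel.
#'
#' @return An object of class `iss_stack`.
#' @export
channel_stack <- function(images, pixel_size = NULL) {
  stopifnot(is.list(images), length(images) >= 1)
  roles <- names(images[[1]])
  dims <- dim(images[[1]][[1]])
  for (cyc in seq_along(images)) {
    cy <- images[[cyc]]
    if (!identical(sort(names(cy)), sort(roles))) {
      stop("cycle ", cyc, " does not carry the same channel roles as cycle 1")
    }
    for (ch in names(cy)) {
      if (!is.matrix(cy[[ch]]) || !identical(dim(cy[[ch]]), dims)) {
        stop("image (cycle ", cyc, ", channel ", ch, ") has mismatched dimensions")
      }
    }
  }
  if (sum(roles == "anchor") != 1L || sum(roles == "nuclei") != 1L) {
    stop("stack needs exactly one 'anchor' and one 'nuclei' channel per cycle")
  }
  if (!setequal(setdiff(roles, c("anchor", "nuclei")), c("A", "C", "G", "T"))) {
    stop("base channels must be exactly A, C, G, T")
  }
  structure(
    list(images = images, dim = dims, pixel_size = pixel_size),
    class = "iss_stack"
  )
}

#' @export
print.iss_stack <- function(x, ...) {
  cat(sprintf(
    "<iss_stack> %d cycles x %d channels, %d x %d px\n",
    n_cycles(x), length(channel_roles(x)), x$dim[1], x$dim[2]
  ))
  invisible(x)
}

#' Number of sequencing cycles in a stack
#' @param stack An `iss_stack`.
#' @return Integer cycle count.
#' @export
n_cycles <- function(stack) length(stack$images)

#' Channel roles of a stack
#' @param stack An `iss_stack`.
#' @return Character vector of roles (e.g. `"nuclei"`, `"anchor"`, `"A"`, ...).
#' @export
channel_roles <- function(stack) names(stack$images[[1]])

#' Base channel names in canonical order
#' @keywords internal
iss_bases <- function() c("A", "C", "G", "T")

#' Extract one image from a stack
#' @param stack An `iss_stack`.
#' @param cycle 1-based cycle index.
#' @param channel Channel role.
#' @return A numeric matrix.
#' @export
stack_image <- function(stack, cycle, channel) {
  img <- stack$images[[cycle]][[channel]]
  if (is.null(img)) stop("no image for cycle ", cycle, ", channel ", channel)
  img
}

#' Split a stack into non-overlapping tiles
#'
#' Tiles the stack into square blocks of side `tile_size`; tiles at the right
#' and bottom edge may be smaller. Together the tiles partition the image, so
#' reassembling them reproduces it exactly.
#'
#' @param stack An `iss_stack`.
#' @param tile_size Tile side length in pixels.
#' @return A tibble with columns `tile` (id), `x0`, `y0` (0-based global
#'   origin of the tile) and `stack` (list-column of `iss_stack` tiles).
#' @export
tile_stack <- function(stack, tile_size) {
  stopifnot(tile_size >= 1)
  nr <- stack$dim[1]; nc <- stack$dim[2]
  row0 <- seq(1L, nr, by = tile_size)
  col0 <- seq(1L, nc, by = tile_size)
  grid <- expand.grid(r = row0, c = col0, KEEP.OUT.ATTRS = FALSE)
  tiles <- purrr::pmap(grid, function(r, c) {
    rr <- r:min(r + tile_size - 1L, nr)
    cc <- c:min(c + tile_size - 1L, nc)
    imgs <- purrr::map(stack$images, function(cy) purrr::map(cy, function(im) im[rr, cc, drop = FALSE]))
    channel_stack(imgs, pixel_size = stack$pixel_size)
  })
  tibble::tibble(
    tile = seq_len(nrow(grid)),
    x0 = grid$c - 1L,
    y0 = grid$r - 1L,
    stack = tiles
  )
}

#' Reassemble tiles into one stack
#'
#' Inverse of [tile_stack()]: places each tile back at its origin.
#'
#' @param tiles Tibble as returned by [tile_stack()].
#' @return An `iss_stack`.
#' @export
untile_stack <- function(tiles) {
  nr <- max(tiles$y0 + purrr::map_int(tiles$stack, ~ .x$dim[1]))
  nc <- max(tiles$x0 + purrr::map_int(tiles$stack, ~ .x$dim[2]))
  tmpl <- tiles$stack[[1]]
  imgs <- purrr::map(seq_len(n_cycles(tmpl)), function(cyc) {
    purrr::map(stats::setNames(nm = channel_roles(tmpl)), function(ch) {
      out <- matrix(0, nr, nc)
      for (i in seq_len(nrow(tiles))) {
        t <- tiles$stack[[i]]
        out[tiles$y0[i] + seq_len(t$dim[1]), tiles$x0[i] + seq_len(t$dim[2])] <-
          t$images[[cyc]][[ch]]
      }
      out
    })
  })
  channel_stack(imgs, pixel_size = tmpl$pixel_size)
}

#' Write a stack as one multi-page TIFF per cycle
#'
#' Pages are ordered nuclei, anchor, A, C, G, T. Images are written as
#' 16-bit TIFF with intensities rounded to integer gray levels (the native
#' representation of scientific camera data); values are clipped to
#' \[0, 65535\].
#'
#' @param stack An `iss_stack`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix; files are `<prefix>_cycle<i>.tif`.
#' @return Invisibly, the written file paths.
#' @export
write_stack <- function(stack, dir, prefix = "iss") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  order <- c("nuclei", "anchor", iss_bases())
  paths <- character(n_cycles(stack))
  for (cyc in seq_len(n_cycles(stack))) {
    pages <- purrr::map(order,
                        ~ pmin(pmax(round(stack$images[[cyc]][[.x]]), 0), 65535) / 65535)
    paths[cyc] <- file.path(dir, sprintf("%s_cycle%d.tif", prefix, cyc))
    tiff::writeTIFF(pages, paths[cyc], bits.per.sample = 16L)
  }
  invisible(paths)
}

#' Read a stack written by [write_stack()]
#'
#' @param dir Directory holding `<prefix>_cycle<i>.tif` files.
#' @param prefix File name prefix.
#' @return An `iss_stack`.
#' @export
read_stack <- function(dir, prefix = "iss") {
  files <- sort(list.files(dir, sprintf("^%s_cycle[0-9]+\\.tif$", prefix), full.names = TRUE))
  if (length(files) == 0) stop("no stack TIFFs with prefix '", prefix, "' in ", dir)
  idx <- as.integer(sub(".*_cycle([0-9]+)\\.tif$", "\\1", files))
  files <- files[order(idx)]
  order <- c("nuclei", "anchor", iss_bases())
  imgs <- purrr::map(files, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    stats::setNames(purrr::map(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      p * 65535
    }), order)
  })
  channel_stack(imgs)
}
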