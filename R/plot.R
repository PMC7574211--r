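#' Plot decoded reads in tissue coordinates
#'
#' @param reads Read tibble.
#' @param colour_by Column to colour by (default `gene`).
#' @return A ggplot object.
#' @export
plot_reads <- function(reads, colour_by = "gene") {
  ggplot2::ggplot(reads, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' RGB map of a 3-dimensional embedding
#'
#' Renders each patch as a tile coloured by its position in the unit-cube
#' embedding, a compact visualization of local gene expression variation.
#'
#' @param embedding A 3-D `iss_embedding`.
#' @param expr The `iss_patch_expr` (or list matching the embedding samples)
#'   supplying patch tile coordinates.
#' @return A ggplot object (facetted by sample if several).
#' @export
plot_rgb_map <- function(embedding, expr) {
  stopifnot(embedding$dims == 3)
  if (inherits(expr, "iss_patch_expr")) expr <- list(sample1 = expr)
  if (is.null(names(expr))) names(expr) <- paste0("sample", seq_along(expr))
  co <- embedding$coordinates
  df <- tibble::tibble(
    sample = embedding$sample, patch = embedding$patch,
    colour = grDevices::rgb(co[, 1], co[, 2], co[, 3])
  )
  pos <- dplyr::bind_rows(purrr::imap(
    expr, ~ tibble::tibble(sample = .y, patch = .x$patches$patch,
                           ix = .x$patches$ix, iy = .x$patches$iy)))
  df <- dplyr::inner_join(df, pos, by = c("sample", "patch"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ix, y = .data$iy,
                                   fill = .data$colour)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::theme_void()
}

#' Plot compartment labels on the patch grid
#'
#' @param compartments An `iss_compartments`.
#' @param expr An `iss_patch_expr` or list of them supplying tile indices.
#' @return A ggplot object.
#' @export
plot_compartments <- function(compartments, expr) {
  if (inherits(expr, "iss_patch_expr")) expr <- list(sample1 = expr)
  if (is.null(names(expr))) names(expr) <- paste0("sample", seq_along(expr))
  pos <- dplyr::bind_rows(purrr::imap(
    expr, ~ tibble::tibble(sample = .y, patch = .x$patches$patch,
                           ix = .x$patches$ix, iy = .x$patches$iy)))
  df <- dplyr::inner_join(compartments$labels, pos, by = c("sample", "patch"))
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ix, y = .data$iy,
                                   fill = .data$cluster)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.iss_pattern <- function(object, ...) {
  d <- object$density
  df <- tibble::tibble(
    x = rep(seq_len(ncol(d)) - 1L, each = nrow(d)),
    y = rep(seq_len(nrow(d)) - 1L, times = ncol(d)),
    density = as.vector(d)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0(object$gene, " (", object$provenance, ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iss_sigma_calibration <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$sigma, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$sigma, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(sigma), y = "ROC AUC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iss_patch_expr <- function(object, ...) {
  df <- object$patches
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ix, y = .data$iy,
                                   fill = .data$total)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "reads") +
    ggplot2::theme_minimal()
}
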