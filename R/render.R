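#' Plot a contact scene with ggplot2
#'
#' Draws the primitives computed by [build_figure()]: track polygons first,
#' then heatmap cells, then contact points, on a fixed square canvas with
#' residue index `i` on x and `j` on y, origin at (1, 1). Colours are taken
#' verbatim from the scene; the legend lists one entry per (layer or track,
#' label) pair.
#'
#' @param object A `contact_scene` (or a `figure_spec`, built on the fly).
#' @param point_size Dot size for contact points.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.contact_scene <- function(object, point_size = 0.6, ...) {
  scene <- object
  trk <- scene$legend[scene$legend$kind == "track", ]
  breaks <- trk$colour[!duplicated(trk$colour)]
  labels <- vapply(breaks, function(cl) {
    paste(unique(paste0(trk$name[trk$colour == cl], ": ",
                        trk$label[trk$colour == cl])), collapse = ", ")
  }, character(1))

  p <- ggplot2::ggplot()
  if (nrow(scene$tracks)) {
    p <- p + ggplot2::geom_polygon(
      data = scene$tracks,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$colour),
      colour = NA)
  }
  if (nrow(scene$cells)) {
    p <- p + ggplot2::geom_tile(
      data = scene$cells,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$colour))
  }
  if (nrow(scene$tracks) || nrow(scene$cells)) {
    p <- p + ggplot2::scale_fill_identity(
      guide = if (nrow(scene$tracks)) "legend" else "none",
      name = NULL, breaks = breaks, labels = labels)
  }
  if (nrow(scene$points)) {
    p <- p + ggplot2::geom_point(
      data = scene$points,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$colour),
      size = point_size) +
      ggplot2::scale_colour_identity(
        guide = "legend", name = NULL,
        breaks = unique(scene$points$colour),
        labels = vapply(unique(scene$points$colour), function(cl) {
          paste(unique(scene$points$layer[scene$points$colour == cl]),
                collapse = ", ")
        }, character(1)))
  }
  p +
    ggplot2::coord_fixed(xlim = c(0.5, scene$seq_length + 0.5),
                         ylim = c(0.5, scene$seq_length + 0.5),
                         expand = FALSE) +
    ggplot2::labs(x = "residue i", y = "residue j") +
    ggplot2::theme_bw() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @rdname autoplot.contact_scene
#' @exportS3Method ggplot2::autoplot
autoplot.figure_spec <- function(object, ...) {
  autoplot.contact_scene(build_figure(object), ...)
}

#' @export
plot.contact_scene <- function(x, ...) print(autoplot.contact_scene(x, ...))

#' @export
plot.figure_spec <- function(x, ...) print(autoplot.figure_spec(x, ...))

#' Render a figure to an image file
#'
#' Writes PNG (cairo raster) or SVG (cairo vector). SVG output is
#' byte-for-byte deterministic for a fixed scene and package version, which
#' makes golden-file tests possible.
#'
#' @param x A `contact_scene` or `figure_spec`.
#' @param path Output file path; the extension picks the format when
#'   `format` is omitted.
#' @param format `"png"` or `"svg"`.
#' @param dpi Resolution for PNG output.
#' @param width,height Figure size in inches.
#' @param ... Passed to [autoplot.contact_scene()].
#' @return `path`, invisibly.
#' @export
render_figure <- function(x, path, format = NULL, dpi = 150,
                          width = 7, height = 7, ...) {
  if (inherits(x, "figure_spec")) x <- build_figure(x)
  stopifnot(inherits(x, "contact_scene"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("png", "svg")) {
    cmap_abort(sprintf("unknown format '%s' (supported: png, svg)", format))
  }
  p <- autoplot.contact_scene(x, ...)
  opened <- FALSE
  tryCatch({
    if (format == "png") {
      grDevices::png(path, width = width, height = height, units = "in",
                     res = dpi, type = "cairo")
    } else {
      grDevices::svg(path, width = width, height = height)
    }
    opened <- TRUE
    print(p)  # cairo opens the file lazily, so I/O errors surface here
  },
  error = function(e) {
    cmap_abort(sprintf("cannot open '%s' for writing: %s",
                       path, conditionMessage(e)))
  },
  finally = if (opened) grDevices::dev.off())
  invisible(path)
}
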