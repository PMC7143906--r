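# Choropleth maps of pressure classes.

#' Colour palette for pressure classes
#'
#' A fixed sequential ramp (light to dark blue), so class `k` always maps to
#' the same colour across runs and figures.
#'
#' @param k number of classes.
#' @return character vector of `k` hex colours, named `"1"..."k"`.
#' @export
class_palette <- function(k = 4) {
  cols <- grDevices::colorRampPalette(c("#DEEBF7", "#9ECAE1", "#4292C6", "#08306B"))(k)
  stats::setNames(cols, as.character(seq_len(k)))
}

# flatten block geometries for geom_polygon (subgroup handles holes)
blocks_to_df <- function(blocks) {
  dplyr::bind_rows(lapply(seq_len(nrow(blocks)), function(i) {
    rings <- blocks$geometry[[i]]
    dplyr::bind_rows(lapply(seq_along(rings), function(j) {
      tibble(block_id = blocks$block_id[i], ring = j,
             x = rings[[j]]$x, y = rings[[j]]$y)
    }))
  }))
}

#' Choropleth of block pressure classes
#'
#' Draws the block tessellation filled by pressure class (four colour
#' intensities by default) with an optional overlay of suggested well
#' locations.
#'
#' @param object a `pressure_report` from [run_pipeline()].
#' @param show_wells overlay suggested well sites if the allocation carries
#'   them.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pressure_report <- function(object, show_wells = TRUE, ...) {
  plot_pressure_map(object$blocks, object$allocation,
                    scheme = object$config$scheme, show_wells = show_wells)
}

#' @rdname autoplot.pressure_report
#' @param blocks a `gw_blocks` tessellation.
#' @param allocation a `gw_allocation` with `pressure_class` (and optionally
#'   a `wells` list-column).
#' @param scheme the [class_scheme()] (fixes the palette length).
#' @export
plot_pressure_map <- function(blocks, allocation, scheme = class_scheme(),
                              show_wells = TRUE) {
  if (is.null(blocks) || nrow(blocks) == 0) {
    abort("no blocks to draw", class = "gwp_validation_error")
  }
  df <- blocks_to_df(blocks) |>
    dplyr::left_join(as_tibble(allocation)[, c("block_id", "pressure_class")],
                     by = "block_id") |>
    dplyr::mutate(pressure_class = factor(.data$pressure_class,
                                          levels = seq_len(scheme$n_classes)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$block_id,
                                        subgroup = .data$ring)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$pressure_class),
                          colour = "grey25", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = class_palette(scheme$n_classes),
                               name = "pressure class", drop = FALSE,
                               na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
  if (show_wells && "wells" %in% names(allocation)) {
    wdf <- dplyr::bind_rows(lapply(seq_len(nrow(allocation)), function(i) {
      w <- allocation$wells[[i]]
      if (is.null(w) || nrow(w) == 0) return(NULL)
      tibble(x = w$x, y = w$y)
    }))
    if (!is.null(wdf) && nrow(wdf) > 0) {
      p <- p + ggplot2::geom_point(data = wdf,
                                   ggplot2::aes(x = .data$x, y = .data$y),
                                   inherit.aes = FALSE,
                                   shape = 21, fill = "white", colour = "black",
                                   size = 1.6, stroke = 0.4)
    }
  }
  p
}

#' Render the pressure-class map to an image file
#'
#' @param report a `pressure_report` (or a list with `blocks`, `allocation`
#'   and `config`).
#' @param path output image path (`.png` or `.svg`, decided by extension).
#' @param width,height,dpi device settings passed to [ggplot2::ggsave()].
#' @param ... passed to [autoplot.pressure_report()].
#' @return `path`, invisibly.
#' @export
render_map <- function(report, path, width = 7, height = 6, dpi = 150, ...) {
  p <- autoplot(report, ...)
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = dpi)
  invisible(path)
}
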