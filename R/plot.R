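#' Triangle plot of hybrid index against interclass heterozygosity
#'
#' Scatters each individual's estimates on the unit square with the HWE
#' boundary overlaid: solid lines `y = 2x` and `y = -2x + 2`, and the
#' dashed curve `y = 2x(1 - x)` below which individuals cannot occur
#' under HWE. Points are drawn exactly at their table coordinates (no
#' jitter unless requested); rows with undefined estimates are skipped
#' with a message.
#'
#' @param table A triangle table from [build_triangle_table()] or
#'   [read_triangle_table()].
#' @param color_by `"pop"` for discrete population colors (colorblind-safe
#'   palette) or `"perc_missing"` for a continuous missing-data scale.
#' @param show_boundary Draw the HWE boundary (default `TRUE`).
#' @param overlay_expectations Add the canonical class-expectation points
#'   from [class_expectations()].
#' @param overlay_space Optional data frame from [enumerate_space()] to
#'   draw as small black points.
#' @param jitter Cosmetic jitter width (default 0 = off); seed it
#'   upstream if used, the underlying values are never changed.
#' @return A ggplot object.
#' @export
triangle_plot <- function(table, color_by = c("pop", "perc_missing"),
                          show_boundary = TRUE,
                          overlay_expectations = FALSE,
                          overlay_space = NULL, jitter = 0) {
  color_by <- match.arg(color_by)
  ok <- !is.na(table$hybrid_index) & !is.na(table$heterozygosity)
  if (!any(ok)) {
    stop("no individuals with defined estimates to plot", call. = FALSE)
  }
  if (any(!ok)) {
    message(sum(!ok), " individual(s) with undefined estimates skipped")
  }
  d <- as.data.frame(table[ok, ])

  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$hybrid_index, y = .data$heterozygosity)
  )
  if (!is.null(overlay_space)) {
    p <- p + ggplot2::geom_point(
      data = overlay_space, ggplot2::aes(x = .data$hi, y = .data$het),
      inherit.aes = FALSE, size = 0.4, colour = "black"
    )
  }
  if (show_boundary) {
    curve <- data.frame(x = seq(0, 1, length.out = 201))
    curve$y <- 2 * curve$x * (1 - curve$x)
    lines <- data.frame(x = c(0, 0.5), xend = c(0.5, 1),
                        y = c(0, 1), yend = c(1, 0))
    p <- p +
      ggplot2::geom_segment(
        data = lines,
        ggplot2::aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
        inherit.aes = FALSE, colour = "black"
      ) +
      ggplot2::geom_line(
        data = curve, ggplot2::aes(x = .data$x, y = .data$y),
        inherit.aes = FALSE, colour = "black", linetype = "dashed"
      )
  }
  pos <- if (jitter > 0) ggplot2::position_jitter(width = jitter,
                                                  height = jitter)
         else "identity"
  if (color_by == "pop") {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(colour = .data$pop), size = 2,
                          position = pos) +
      ggplot2::scale_colour_manual(values = okabe_ito(length(unique(d$pop))),
                                   name = "Population")
  } else {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(colour = .data$perc_missing),
                          size = 2, position = pos) +
      ggplot2::scale_colour_viridis_c(name = "% missing",
                                      limits = c(0, 100))
  }
  if (overlay_expectations) {
    ce <- class_expectations()
    p <- p + ggplot2::geom_point(
      data = ce, ggplot2::aes(x = .data$hi, y = .data$het),
      inherit.aes = FALSE, shape = 21, size = 3, fill = "white"
    ) + ggplot2::geom_text(
      data = ce, ggplot2::aes(x = .data$hi, y = .data$het,
                              label = .data$class),
      inherit.aes = FALSE, vjust = -1, size = 2.8
    )
  }
  p +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Hybrid index", y = "Interclass heterozygosity") +
    ggplot2::theme_classic()
}

# Okabe-Ito palette, recycled if more groups than colors are present.
okabe_ito <- function(n) {
  pal <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
           "#0072B2", "#D55E00", "#CC79A7", "#999999")
  rep_len(pal, max(n, 1))
}

#' Save a triangle plot to file
#'
#' @param plot A ggplot object from [triangle_plot()].
#' @param path Output path; format taken from the extension (`.png`,
#'   `.pdf` or `.svg`) unless `format` is given.
#' @param format Optional explicit format.
#' @param width,height Device size in inches.
#' @return Invisibly, `path`.
#' @export
save_triangle_plot <- function(plot, path, format = NULL,
                               width = 6, height = 5) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  if (!format %in% c("png", "pdf", "svg")) {
    stop("unsupported format '", format, "' (use png, pdf or svg)",
         call. = FALSE)
  }
  ggplot2::ggsave(path, plot, device = format, width = width,
                  height = height, dpi = 300)
  invisible(path)
}
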