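#' Plot a windowed ED scan
#'
#' Manhattan-style plot of the fourth-power windowed ED statistic along
#' the genome, faceted by chromosome, with an optional significance
#' threshold line and called regions shaded.
#'
#' @param object A `window_profile` from [windowed_statistic()].
#' @param threshold Optional scalar threshold to draw.
#' @param regions Optional `qtl_regions` to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_profile <- function(object, threshold = NULL,
                                    regions = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$mid_pos / 1e6,
                                    y = .data$w_stat)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "(cumulative ED)^4") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "grey85")
  }
  p <- p + ggplot2::geom_point(size = 0.3, colour = "steelblue")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a cell-length profile with its logistic fit
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  prof <- object$profile
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$distance,
                                          y = .data$length)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::labs(x = "distance from quiescent center (µm)",
                  y = "cell length (µm)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(
      distance = seq(min(prof$distance), max(prof$distance), length.out = 200))
    grid$length <- object$l_min + (object$l_max - object$l_min) /
      (1 + exp(-object$k * (grid$distance - object$x0)))
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot seasonal FTSW trajectories
#'
#' Daily FTSW for one or more seasons with the stress-onset line; if a
#' classification table is supplied the seasons are coloured by stress
#' pattern.
#'
#' @param object An `ftsw_series` tibble (or several row-bound ones).
#' @param labels Optional tibble with `season` and `label` columns.
#' @param onset Stress-onset FTSW drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ftsw_series <- function(object, labels = NULL, onset = 0.3, ...) {
  df <- object
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels, by = "season")
    aes <- ggplot2::aes(x = .data$day, y = .data$ftsw,
                        group = .data$season, colour = .data$label)
  } else {
    aes <- ggplot2::aes(x = .data$day, y = .data$ftsw,
                        group = .data$season)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = onset, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "days after season start",
                  y = "fraction of transpirable soil water") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
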