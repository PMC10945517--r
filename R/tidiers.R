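#' Tidy a logistic cell-length fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("l_min", "l_max", "k", "x0"),
                 estimate = c(x$l_min, x$l_max, x$k, x$x0))
}

#' One-row summary of a logistic cell-length fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_cells = x$n_cells, converged = x$converged)
}

#' Tidy variance components
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @return One row per component: `term`, `estimate`.
#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(term = c("var_line", "var_res"),
                 estimate = c(x$var_line, x$var_res))
}

#' One-row summary of a variance-component fit
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(h2 = x$h2, n_lines = x$n_lines,
                 n_plant_per_line = x$n_plant_per_line,
                 method = x$method, truncated = x$truncated,
                 degenerate = x$degenerate)
}

#' Tidy a kinematics result
#'
#' @param x A `kinematics_result`.
#' @param ... Unused.
#' @export
tidy.kinematics_result <- function(x, ...) {
  tibble::tibble(term = c("elongation_rate", "max_cell_length",
                          "cell_production"),
                 estimate = c(x$elongation_rate, x$max_cell_length,
                              x$cell_production))
}

#' Tidy a stress classification
#'
#' @param x A `stress_classification`.
#' @param ... Unused.
#' @export
tidy.stress_classification <- function(x, ...) {
  tibble::tibble(label = as.character(x$label), onset_day = x$onset_day)
}
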