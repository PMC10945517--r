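#' Variance components of a line-replicated trait
#'
#' Fits the one-way random-effects model
#' `value = mu + line + residual` and estimates `Var(line)` and
#' `Var(res)`. The default estimator is method-of-moments from the
#' expected mean squares of the unbalanced one-way ANOVA:
#' `Var(res) = MS_within` and
#' `Var(line) = (MS_between - MS_within) / n0` with
#' `n0 = (N - sum(n_i^2) / N) / (k - 1)`. A negative moment estimate of
#' `Var(line)` is truncated to 0 and flagged. `method = "reml"` fits the
#' same model with `lme4::lmer` instead.
#'
#' @param table Phenotype table with columns `line`, `trait`, `value`
#'   (e.g. from [simulate_panel_phenotypes()]).
#' @param trait Trait name to analyse (default: the only trait present).
#' @param method `"mom"` (default) or `"reml"`.
#' @return A list of class `variance_components` with `var_line`,
#'   `var_res`, `n_plant_per_line` (average plants per line), `n_lines`,
#'   `h2` (from [broad_sense_heritability()]), `truncated` and
#'   `degenerate` flags, and `method`.
#'
#' @examples
#' panel <- simulate_panel_phenotypes(n_lines = 30, var_line = 2,
#'                                    var_res = 1, seed = 4)
#' variance_components(panel)
#' @export
variance_components <- function(table, trait = NULL, method = c("mom", "reml")) {
  method <- match.arg(method)
  stopifnot(all(c("line", "value") %in% names(table)))
  if (!is.null(trait)) {
    stopifnot("trait" %in% names(table))
    table <- table[table$trait == trait, ]
  }
  if (nrow(table) == 0) abort("no records for the requested trait")
  if (any(!is.finite(table$value))) abort("trait values must be finite")
  counts <- table(table$line)
  k <- length(counts)
  if (k < 2) abort("need at least two lines")
  if (max(counts) < 2) {
    abort("residual variance is inestimable: every line is a singleton")
  }
  n_total <- sum(counts)
  n_bar <- n_total / k

  if (method == "reml") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      abort("method = \"reml\" requires the lme4 package")
    }
    fit <- lme4::lmer(value ~ 1 + (1 | line), data = table)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_line <- vc$vcov[vc$grp == "line"]
    var_res <- vc$vcov[vc$grp == "Residual"]
    truncated <- FALSE
  } else {
    grand <- mean(table$value)
    by_line <- table |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(n = dplyr::n(), m = mean(.data$value),
                       ss = sum((.data$value - mean(.data$value))^2),
                       .groups = "drop")
    ss_within <- sum(by_line$ss)
    ms_within <- ss_within / (n_total - k)
    ss_between <- sum(by_line$n * (by_line$m - grand)^2)
    ms_between <- ss_between / (k - 1)
    n0 <- (n_total - sum(by_line$n^2) / n_total) / (k - 1)
    var_line <- (ms_between - ms_within) / n0
    var_res <- ms_within
    truncated <- var_line < 0
    if (truncated) {
      warn("negative moment estimate of Var(line); truncated to 0")
      var_line <- 0
    }
  }
  out <- structure(
    list(var_line = var_line, var_res = var_res,
         n_plant_per_line = n_bar, n_lines = k,
         truncated = truncated,
         degenerate = var_line == 0 && var_res == 0,
         method = method, h2 = NA_real_),
    class = "variance_components")
  out$h2 <- broad_sense_heritability(out)
  out
}

#' Broad-sense heritability of line means
#'
#' `H2 = Var(line) / (Var(line) + Var(res) / n_plant_per_line)`, the
#' proportion of the variance of line means attributable to line
#' (genetic) variance, with `n_plant_per_line` the average number of
#' plants measured per line. When both components are zero the ratio is
#' undefined and 0 is returned (the object carries a `degenerate` flag).
#'
#' @param vc A `variance_components` object (or any list with
#'   `var_line`, `var_res`, `n_plant_per_line`).
#' @return Heritability in `[0, 1]`.
#' @export
broad_sense_heritability <- function(vc) {
  stopifnot(vc$var_line >= 0, vc$var_res >= 0, vc$n_plant_per_line > 0)
  denom <- vc$var_line + vc$var_res / vc$n_plant_per_line
  if (denom == 0) return(0)
  vc$var_line / denom
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s): Var(line) = %.4g, Var(res) = %.4g\n",
    x$method, x$var_line, x$var_res))
  cat(sprintf("  %d lines, %.2f plants/line on average; H2 = %.3f\n",
              x$n_lines, x$n_plant_per_line, x$h2))
  if (x$truncated) cat("  (negative Var(line) estimate truncated to 0)\n")
  invisible(x)
}

#' Adjusted (least-squares) line means
#'
#' Fits the fixed-effects model `value ~ line + year:block` by ordinary
#' least squares (treatment coding) and reports, per line, the model
#' prediction averaged with equal weight over the year-by-block cells
#' observed in the data -- the least-squares mean for an unbalanced
#' multi-environment design. Lines absent from every cell of a year are
#' still estimable through the remaining cells; combinations the model
#' cannot estimate are dropped with a warning.
#'
#' @param table Phenotype table with columns `line`, `year`, `block`,
#'   `value` (and optionally `trait`).
#' @param trait Trait to analyse when a `trait` column is present.
#' @return Tibble with `line` and `adjusted_mean`.
#' @export
adjusted_line_means <- function(table, trait = NULL) {
  stopifnot(all(c("line", "year", "block", "value") %in% names(table)))
  if (!is.null(trait) && "trait" %in% names(table)) {
    table <- table[table$trait == trait, ]
  }
  df <- data.frame(line = factor(table$line),
                   cell = factor(paste(table$year, table$block, sep = ":")),
                   value = table$value)
  form <- if (nlevels(df$cell) > 1) value ~ line + cell else value ~ line
  fit <- lm(form, data = df)
  grid <- expand.grid(line = levels(df$line), cell = levels(df$cell))
  mform <- if (nlevels(df$cell) > 1) ~ line + cell else ~ line
  beta <- coef(fit)
  mm <- model.matrix(mform, data = grid)
  if (anyNA(beta)) {
    est <- !is.na(beta)
    inest <- rowSums(mm[, !est, drop = FALSE] != 0) > 0
    if (any(inest)) {
      warn(sprintf("%d line-by-cell combination(s) inestimable; dropped",
                   sum(inest)))
      grid <- grid[!inest, , drop = FALSE]
      mm <- mm[!inest, , drop = FALSE]
    }
    pred <- drop(mm[, est, drop = FALSE] %*% beta[est])
  } else {
    pred <- drop(mm %*% beta)
  }
  tibble::tibble(line = grid$line, pred = pred) |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(adjusted_mean = mean(.data$pred), .groups = "drop") |>
    dplyr::mutate(line = as.character(.data$line))
}

#' Correlation between two per-line trait summaries
#'
#' Pearson correlation on pairwise-complete lines, e.g. between
#' lab-measured root length and a field drought-tolerance indicator.
#'
#' @param means_a,means_b Data frames with columns `line` and a single
#'   value column each (such as the output of [adjusted_line_means()]),
#'   or named numeric vectors keyed by line.
#' @return A list with `r` (Pearson coefficient), `n` (lines used) and
#'   `p_value` (two-sided test). Zero variance in either trait gives
#'   `r = NA` with a warning.
#' @export
correlate_traits <- function(means_a, means_b) {
  as_named <- function(x) {
    if (is.data.frame(x)) {
      valcol <- setdiff(names(x), "line")[1]
      setNames(x[[valcol]], x$line)
    } else x
  }
  a <- as_named(means_a); b <- as_named(means_b)
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) abort("need at least 3 paired lines")
  if (sd(a) == 0 || sd(b) == 0) {
    warn("zero variance in a trait; correlation undefined")
    return(list(r = NA_real_, n = length(a), p_value = NA_real_))
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), n = length(a), p_value = ct$p.value)
}
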