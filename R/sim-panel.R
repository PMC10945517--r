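#' Simulate a line-replicated phenotype panel
#'
#' Generates records `value = mu + line + year + block(year) + residual`
#' for a panel of inbred lines, emulating a growth-chamber or field
#' phenotyping design: line effects are `N(0, var_line)`, residuals
#' `N(0, var_res)`, and the number of plants per line is Poisson around
#' `plants_per_line_mean` (minimum 1). Year and block-within-year effect
#' standard deviations default to zero so the default panel follows the
#' one-way random-effects model used for heritability; set them to
#' positive values to exercise the adjusted-means machinery.
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param plants_per_line_mean Mean plants measured per line.
#' @param var_line,var_res Line and residual variance components
#'   (trait units squared).
#' @param n_years,n_blocks Numbers of years and blocks per year.
#' @param sd_year,sd_block Standard deviations of the year and
#'   block-within-year effects (default 0).
#' @param mu Overall trait mean.
#' @param trait Trait name recorded in the table.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `line`, `year`, `block`, `plant`,
#'   `trait`, `value`. The generating effects are attached as attribute
#'   `"truth"` (a list with `line_effects`, `var_line`, `var_res`).
#'
#' @examples
#' panel <- simulate_panel_phenotypes(n_lines = 10, seed = 1)
#' dplyr::count(panel, line)
#' @export
simulate_panel_phenotypes <- function(n_lines = 122,
                                      plants_per_line_mean = 7,
                                      var_line = 1, var_res = 1,
                                      n_years = 1, n_blocks = 1,
                                      sd_year = 0, sd_block = 0,
                                      mu = 0, trait = "root_length",
                                      seed) {
  stopifnot(n_lines >= 2, plants_per_line_mean > 0,
            var_line >= 0, var_res >= 0,
            n_years >= 1, n_blocks >= 1, sd_year >= 0, sd_block >= 0)
  set.seed(as.integer(seed))
  lines <- sprintf("L%03d", seq_len(n_lines))
  line_eff <- rnorm(n_lines, 0, sqrt(var_line))
  year_eff <- rnorm(n_years, 0, sd_year)
  block_eff <- matrix(rnorm(n_years * n_blocks, 0, sd_block),
                      nrow = n_years)
  grid <- tidyr::expand_grid(
    line_idx = seq_len(n_lines),
    year = seq_len(n_years),
    block = seq_len(n_blocks)
  )
  grid$n_plants <- pmax(1L, rpois(nrow(grid), plants_per_line_mean))
  out <- tidyr::uncount(grid, .data$n_plants, .id = "plant")
  out$value <- mu + line_eff[out$line_idx] + year_eff[out$year] +
    block_eff[cbind(out$year, out$block)] +
    rnorm(nrow(out), 0, sqrt(var_res))
  out <- tibble::tibble(
    line = lines[out$line_idx],
    year = out$year, block = out$block, plant = out$plant,
    trait = trait, value = out$value
  )
  attr(out, "truth") <- list(line_effects = setNames(line_eff, lines),
                             var_line = var_line, var_res = var_res)
  out
}
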