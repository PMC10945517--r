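#' Simulate a root-tip cell-length profile
#'
#' Emulates the axial cell-length pattern of a root tip: short
#' meristematic cells near the quiescent center that elongate through
#' the elongation zone to a mature maximum, following the logistic curve
#' `l(x) = l_min + (l_max - l_min) / (1 + exp(-k (x - x0)))`. Cells are
#' laid end to end from the quiescent center: each cell's recorded
#' distance is the cumulative length of the cells before it, its length
#' is the logistic curve at that distance plus Gaussian noise, truncated
#' below at 1 um.
#'
#' @param l_min,l_max Minimum (meristematic) and maximum (mature) cell
#'   length, um; `l_max > l_min > 0`.
#' @param k Logistic steepness, 1/um (> 0).
#' @param x0 Distance of the inflection point from the quiescent center,
#'   um.
#' @param n_cells Number of consecutive cells; the default (300) spans
#'   both shoulders of the default curve. With a closer, steeper
#'   transition (e.g. `k = 0.01`, `x0 = 600`) 60 cells suffice.
#' @param noise_sd Standard deviation of the length noise, um.
#' @param seed Integer seed.
#' @param sample_id Identifier recorded in the profile.
#'
#' @return A tibble of class `cell_profile` with columns `sample`,
#'   `cell`, `distance` (um from the quiescent center) and `length`
#'   (um).
#'
#' @examples
#' simulate_cell_profile(n_cells = 20, noise_sd = 0, seed = 1)
#' @export
simulate_cell_profile <- function(l_min = 10, l_max = 200, k = 0.005,
                                  x0 = 3000, n_cells = 300, noise_sd = 0,
                                  seed = 1, sample_id = "sim") {
  stopifnot(l_max > l_min, l_min > 0, k > 0, n_cells >= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  distance <- numeric(n_cells)
  len <- numeric(n_cells)
  x <- 0
  for (i in seq_len(n_cells)) {
    distance[i] <- x
    l <- l_min + (l_max - l_min) / (1 + exp(-k * (x - x0)))
    if (noise_sd > 0) l <- l + rnorm(1, 0, noise_sd)
    len[i] <- max(1, l)
    x <- x + len[i]
  }
  out <- tibble::tibble(sample = sample_id, cell = seq_len(n_cells),
                        distance = distance, length = len)
  class(out) <- c("cell_profile", class(out))
  out
}
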