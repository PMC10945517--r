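#' Detect cell walls in a 1-D intensity profile
#'
#' Finds cell-wall positions along a line traced from the quiescent
#' center as local maxima of the (cell-wall stain) intensity profile,
#' keeping peaks with topographic prominence at least `min_prominence`
#' and enforcing a minimum pairwise separation: when two candidate
#' walls are closer than `min_separation`, the higher one is kept.
#' Plateau maxima resolve to their leftmost sample.
#'
#' @param intensity Numeric intensity values sampled at regular spacing.
#' @param spacing Sample spacing in um (> 0).
#' @param min_prominence Minimum peak prominence, intensity units.
#' @param min_separation Minimum distance between retained walls, um.
#' @return Numeric vector of wall positions in um from the first sample
#'   (possibly empty, e.g. for a flat profile).
#'
#' @examples
#' x <- rep(0, 50); x[c(10, 25, 40)] <- 5
#' detect_cell_walls(x, spacing = 1, min_prominence = 1,
#'                   min_separation = 5)
#' @export
detect_cell_walls <- function(intensity, spacing, min_prominence = 0,
                              min_separation = 0) {
  stopifnot(length(intensity) >= 3, spacing > 0,
            min_prominence >= 0, min_separation >= 0)
  n <- length(intensity)
  # leftmost sample of every strict local maximum (plateau-aware)
  cand <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (intensity[i] > intensity[i - 1L]) {
      j <- i
      while (j < n && intensity[j + 1L] == intensity[j]) j <- j + 1L
      if (j < n && intensity[j + 1L] < intensity[j]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0) return(numeric(0))
  prom <- purrr::map_dbl(cand, function(p) peak_prominence(intensity, p))
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(numeric(0))
  # enforce separation: greedy from the highest peak down
  ord <- cand[order(-intensity[cand], cand)]
  kept <- integer()
  for (p in ord) {
    if (all(abs(p - kept) * spacing >= min_separation)) kept <- c(kept, p)
  }
  sort((kept - 1L)) * spacing
}

# topographic prominence: height above the higher of the two key saddles
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- x[seq_len(p - 1L)]
  right <- x[seq.int(p + 1L, length(x))]
  higher_l <- which(left >= h)
  col_l <- if (length(higher_l) == 0) min(left) else {
    min(left[seq.int(max(higher_l), length(left))])
  }
  higher_r <- which(right >= h)
  col_r <- if (length(higher_r) == 0) min(right) else {
    min(right[seq_len(min(higher_r))])
  }
  h - max(col_l, col_r)
}

#' Cell lengths from detected wall positions
#'
#' Consecutive wall positions delimit cells: the cell length is the
#' difference between neighbouring walls and the cell's distance
#' coordinate is the midpoint between its walls, measured from the
#' first wall (taken as the quiescent-center origin).
#'
#' @param walls Numeric wall positions in um, at least two, distinct.
#' @param sample_id Identifier recorded in the profile.
#' @return A `cell_profile` tibble with `sample`, `cell`, `distance`,
#'   `length`.
#' @export
cell_lengths_from_walls <- function(walls, sample_id = "sample") {
  stopifnot(length(walls) >= 2)
  if (anyDuplicated(walls)) abort("wall positions must be distinct")
  walls <- sort(walls)
  len <- diff(walls)
  mid <- (head(walls, -1) + tail(walls, -1)) / 2 - walls[1]
  out <- tibble::tibble(sample = sample_id, cell = seq_along(len),
                        distance = mid, length = len)
  class(out) <- c("cell_profile", class(out))
  out
}

#' Fit a logistic curve to a cell-length profile
#'
#' Least-squares fit of
#' `l(x) = l_min + (l_max - l_min) / (1 + exp(-k (x - x0)))` to cell
#' length versus distance from the quiescent center, the standard
#' description of the meristem-to-elongation-zone transition.
#' Initialization is data-driven (5th/95th length percentiles for the
#' asymptotes, distance at half-range for `x0`, central slope for `k`)
#' and the fit is bounded with `l_min >= 0.1` um and `k > 0`. Set
#' `three_parameter = TRUE` to pin `l_min` at its floor. A fit that
#' fails or hits a degenerate profile returns `converged = FALSE`
#' rather than erroring.
#'
#' @param profile A `cell_profile` (columns `distance`, `length`).
#' @param three_parameter Drop the lower asymptote (default `FALSE`).
#' @return A list of class `logistic_fit` with elements `l_min`,
#'   `l_max`, `k`, `x0`, `rss`, `converged`, `n_cells`, and the data
#'   used (`profile`).
#'
#' @examples
#' prof <- simulate_cell_profile(noise_sd = 0, seed = 1)
#' fit_logistic(prof)
#' @export
fit_logistic <- function(profile, three_parameter = FALSE) {
  stopifnot(all(c("distance", "length") %in% names(profile)))
  x <- profile$distance
  y <- profile$length
  n <- length(y)
  failed <- function() {
    structure(list(l_min = min(y), l_max = max(y), k = NA_real_,
                   x0 = NA_real_, rss = NA_real_, converged = FALSE,
                   n_cells = n, profile = profile),
              class = "logistic_fit")
  }
  if (n < 4 || diff(range(y)) < 1e-8) return(failed())
  # positivity floor: 0.1 um for um-scale data, scaled down if the data
  # are in larger units so the bound never binds on a valid profile
  floor_l <- max(min(0.1, 0.9 * min(y)), 1e-9)
  l_min0 <- max(floor_l, unname(quantile(y, 0.05)))
  l_max0 <- unname(quantile(y, 0.95))
  half <- l_min0 + (l_max0 - l_min0) / 2
  x00 <- x[which.min(abs(y - half))]
  # central slope of the sigmoid is k * (l_max - l_min) / 4
  mid <- abs(y - half) <= (l_max0 - l_min0) / 4
  slope <- if (sum(mid) >= 2) {
    abs(coef(lm(y[mid] ~ x[mid]))[2])
  } else {
    (l_max0 - l_min0) / max(diff(range(x)), 1e-8)
  }
  k0 <- max(4 * slope / max(l_max0 - l_min0, 1e-8), 1e-6)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (three_parameter) {
      minpack.lm::nlsLM(
        y ~ floor_l + (l_max - floor_l) / (1 + exp(-k * (x - x0))),
        data = dat, start = list(l_max = l_max0, k = k0, x0 = x00),
        lower = c(l_max = floor_l, k = 1e-9, x0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ l_min + (l_max - l_min) / (1 + exp(-k * (x - x0))),
        data = dat,
        start = list(l_min = l_min0, l_max = l_max0, k = k0, x0 = x00),
        lower = c(l_min = floor_l, l_max = floor_l, k = 1e-9, x0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- coef(fit)
  l_min_hat <- if (three_parameter) floor_l else unname(cf["l_min"])
  l_max_hat <- unname(cf["l_max"])
  conv <- isTRUE(fit$convInfo$isConv) && l_max_hat > l_min_hat &&
    diff(range(y)) > 1e-6
  structure(list(l_min = l_min_hat, l_max = l_max_hat,
                 k = unname(cf["k"]), x0 = unname(cf["x0"]),
                 rss = sum(resid(fit)^2), converged = conv,
                 n_cells = n, profile = profile),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic cell-length fit (%d cells)%s\n", x$n_cells,
    if (x$converged) "" else " [NOT converged]"))
  cat(sprintf("  l_min = %.3g um, l_max = %.3g um, k = %.3g /um, x0 = %.3g um\n",
              x$l_min, x$l_max, x$k, x$x0))
  invisible(x)
}

#' Elongation and cell-production rates
#'
#' Under steady-state growth the number of cells leaving the meristem
#' per day is the root elongation rate divided by the mature
#' (maximum) cell length: `production = elongation_rate / l_max`.
#' `l_max` is the fitted logistic asymptote; for an unconverged fit the
#' default is to error, or with `fallback = "observed"` the 95th
#' percentile of the observed cell lengths is used instead.
#'
#' @param fit A `logistic_fit`.
#' @param elongation_rate Externally measured root elongation rate,
#'   um/day (> 0).
#' @param fallback `"error"` (default) or `"observed"` behaviour for
#'   unconverged fits.
#' @return A list of class `kinematics_result` with `elongation_rate`
#'   (um/day), `max_cell_length` (um) and `cell_production`
#'   (cells/day).
#' @export
kinematic_rates <- function(fit, elongation_rate,
                            fallback = c("error", "observed")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(fit, "logistic_fit"), elongation_rate > 0)
  if (!fit$converged) {
    if (fallback == "error") {
      abort(paste("logistic fit did not converge; rerun with",
                  "fallback = \"observed\" to use the 95th percentile",
                  "of observed cell lengths"))
    }
    l_max <- unname(quantile(fit$profile$length, 0.95))
  } else {
    l_max <- fit$l_max
  }
  structure(list(elongation_rate = elongation_rate,
                 max_cell_length = l_max,
                 cell_production = elongation_rate / l_max),
            class = "kinematics_result")
}
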