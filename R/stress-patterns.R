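#' Sowing day from the soil water store
#'
#' The sowing date is the first day on which the actual transpirable
#' soil water reaches the significant-rain threshold (>= 10 mm by
#' default), counting from the opening of the soil water balance.
#'
#' @param atsw Daily actual transpirable soil water, mm.
#' @param threshold Minimum ATSW, mm (inclusive).
#' @return 1-based day index, or `NA_integer_` if never reached.
#' @export
sowing_day <- function(atsw, threshold = 10) {
  if (length(atsw) == 0) abort("ATSW series is empty")
  hit <- which(atsw >= threshold)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Gap between the first two significant rainfall events
#'
#' Number of days strictly between the first and second day with
#' rainfall above the significance threshold (> 10 mm by default) --
#' the early-season rain pause that puts seedlings at risk.
#'
#' @param rain Daily rainfall, mm.
#' @param significant Threshold, mm (strict).
#' @return Gap length in days (0 for consecutive events), or
#'   `NA_integer_` with fewer than two events.
#' @export
rain_gap <- function(rain, significant = 10) {
  events <- which(rain > significant)
  if (length(events) < 2) return(NA_integer_)
  as.integer(events[2] - events[1] - 1L)
}

#' Dynamic time warping distance between two daily series
#'
#' Classic dynamic-programming DTW with the symmetric step pattern
#' (match, insertion, deletion), absolute-difference local cost and no
#' warping window. The distance is non-negative, symmetric, and zero
#' exactly when one series is a warped copy of the other.
#'
#' @param a,b Numeric series (non-empty).
#' @return The accumulated alignment cost.
#'
#' @examples
#' dtw_distance(c(0, 0, 0), c(1, 1, 1))
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("series must be non-empty")
  n <- length(a); m <- length(b)
  cost <- abs(outer(a, b, "-"))
  acc <- matrix(Inf, n + 1, m + 1)
  acc[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc[i + 1, j + 1] <- cost[i, j] +
        min(acc[i, j], acc[i, j + 1], acc[i + 1, j])
    }
  }
  acc[n + 1, m + 1]
}

#' Cluster seasonal FTSW trajectories
#'
#' Average-linkage hierarchical clustering on the pairwise DTW distance
#' matrix of the seasons' daily FTSW series (aligned by days after
#' sowing). With `k = "auto"` the number of clusters in 2..6 maximizing
#' the mean silhouette width on the DTW distances is chosen; if all
#' pairwise distances are zero the silhouette is undefined and a single
#' degenerate cluster is returned.
#'
#' @param series Named list of numeric FTSW series (one per season), or
#'   a tibble with columns `season`, `day`, `ftsw`.
#' @param k Number of clusters, or `"auto"` (default).
#' @return A tibble with `season` and `cluster`, with attributes `k`,
#'   `degenerate`, `distance_matrix` and `silhouette` (mean widths by
#'   candidate k, when auto).
#' @export
cluster_seasons <- function(series, k = "auto") {
  if (is.data.frame(series)) {
    stopifnot(all(c("season", "day", "ftsw") %in% names(series)))
    series <- series |>
      dplyr::arrange(.data$season, .data$day) |>
      (\(df) split(df$ftsw, df$season))()
  }
  n <- length(series)
  if (n < 3) abort("need at least 3 seasons to cluster")
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k > n) abort("more clusters requested than seasons")
  }
  ids <- names(series) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- dtw_distance(series[[i]], series[[j]])
    }
  }
  degenerate <- all(d == 0)
  sil <- NULL
  if (degenerate) {
    cl <- rep(1L, n)
    k_used <- 1L
  } else {
    hc <- hclust(as.dist(d), method = "average")
    if (identical(k, "auto")) {
      ks <- 2:min(6, n - 1)
      sil <- purrr::map_dbl(ks, function(kk) {
        mean(cluster::silhouette(cutree(hc, kk), dmatrix = d)[, "sil_width"])
      })
      names(sil) <- ks
      k_used <- ks[which.max(sil)]
    } else {
      k_used <- k
    }
    cl <- cutree(hc, k_used)
  }
  out <- tibble::tibble(season = ids, cluster = unname(cl))
  attr(out, "k") <- k_used
  attr(out, "degenerate") <- degenerate
  attr(out, "distance_matrix") <- d
  attr(out, "silhouette") <- sil
  out
}

#' Classify a season's stress pattern
#'
#' A season is `early_stress` when FTSW falls below the onset threshold
#' on any day before panicle initiation; otherwise `late_stress` when it
#' does so between flowering and maturity; otherwise `no_stress`.
#' Stress in the window between panicle initiation and flowering is
#' counted as early by default (`mid_window = "early"`), the documented
#' convention for this rule.
#'
#' @param ftsw Daily FTSW values, days after sowing.
#' @param phenology List or vector with `panicle_initiation_day`,
#'   `flowering_day`, `maturity_day` (days after sowing, ordered).
#' @param onset Stress onset threshold (default 0.3; stress is FTSW
#'   strictly below it).
#' @param mid_window `"early"` (default) or `"none"`: whether stress
#'   confined to the panicle-initiation-to-flowering window labels the
#'   season early_stress.
#' @return A list of class `stress_classification` with `label`
#'   (factor: early_stress / late_stress / no_stress) and `onset_day`
#'   (first day below the threshold, `NA` if none).
#' @export
classify_stress <- function(ftsw, phenology, onset = 0.3,
                            mid_window = c("early", "none")) {
  mid_window <- match.arg(mid_window)
  req <- c("panicle_initiation_day", "flowering_day", "maturity_day")
  if (is.null(phenology) || !all(req %in% names(phenology))) {
    abort(paste("phenology must provide", paste(req, collapse = ", ")))
  }
  pi_day <- phenology[["panicle_initiation_day"]]
  fl_day <- phenology[["flowering_day"]]
  mat_day <- phenology[["maturity_day"]]
  stopifnot(pi_day <= fl_day, fl_day <= mat_day,
            mat_day <= length(ftsw) + 0L)
  stress_days <- which(ftsw < onset)
  onset_day <- if (length(stress_days) == 0) NA_integer_ else stress_days[1]
  early_end <- if (mid_window == "early") fl_day - 1L else pi_day - 1L
  label <- if (any(stress_days <= early_end)) {
    "early_stress"
  } else if (any(stress_days >= fl_day & stress_days <= mat_day)) {
    "late_stress"
  } else {
    "no_stress"
  }
  structure(
    list(label = factor(label, levels = c("early_stress", "late_stress",
                                          "no_stress")),
         onset_day = onset_day,
         phenology = list(panicle_initiation_day = pi_day,
                          flowering_day = fl_day, maturity_day = mat_day)),
    class = "stress_classification")
}

#' Stress-pattern frequencies and yield/biomass penalties
#'
#' Summarizes a set of classified seasons: the share of seasons per
#' stress label and, relative to the no-stress baseline, the mean
#' relative yield (and biomass) penalty
#' `100 * (mean_no_stress - mean_label) / mean_no_stress`.
#'
#' @param seasons Tibble with columns `season`, `label`, `yield` and
#'   optionally `biomass`.
#' @return A tibble with one row per label: `label`, `n_seasons`,
#'   `frequency_pct`, `yield_penalty_pct` and (when biomass is present)
#'   `biomass_penalty_pct`. The baseline rows carry penalty 0.
#' @export
stress_impact <- function(seasons) {
  stopifnot(all(c("season", "label", "yield") %in% names(seasons)))
  base <- seasons[seasons$label == "no_stress", ]
  if (nrow(base) == 0 || all(is.na(base$yield))) {
    abort("no no_stress season with a yield: baseline undefined")
  }
  base_yield <- mean(base$yield, na.rm = TRUE)
  has_biomass <- "biomass" %in% names(seasons)
  base_biomass <- if (has_biomass) mean(base$biomass, na.rm = TRUE) else NA
  out <- seasons |>
    dplyr::group_by(label = as.character(.data$label)) |>
    dplyr::summarise(
      n_seasons = dplyr::n(),
      mean_yield = mean(.data$yield, na.rm = TRUE),
      mean_biomass = if (has_biomass) {
        mean(.data$biomass, na.rm = TRUE)
      } else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      frequency_pct = 100 * .data$n_seasons / sum(.data$n_seasons),
      yield_penalty_pct = 100 * (base_yield - .data$mean_yield) / base_yield)
  if (has_biomass) {
    out$biomass_penalty_pct <-
      100 * (base_biomass - out$mean_biomass) / base_biomass
  }
  dplyr::select(out, -"mean_yield", -"mean_biomass")
}
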