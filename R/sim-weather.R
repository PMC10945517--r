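#' Soil water bucket parameters
#'
#' Parameters of the single-layer "bucket" soil water balance used to
#' turn daily rainfall into a fraction-of-transpirable-soil-water (FTSW)
#' trajectory. Transpiration proceeds at full demand while FTSW is at or
#' above the stress onset and declines linearly with FTSW below it.
#'
#' @param ttsw Total transpirable soil water of the (fully rooted)
#'   profile, mm (> 0). The sowing-time rooted capacity can be smaller;
#'   see the `ttsw0` argument of [simulate_ftsw()].
#' @param initial_fill Initial fraction of the starting capacity present
#'   (default 0.05): the balance opens in the dry season with the
#'   transpirable store nearly empty, so sowing waits for real rain.
#' @param daily_demand Water demand on the store (crop transpiration
#'   plus soil evaporation), mm/day.
#' @param stress_onset_ftsw FTSW below which transpiration is restricted
#'   (default 0.3).
#' @param season_start_doy Day of year at which the balance starts
#'   (default 100, i.e. around April 10).
#' @return A list of class `bucket_params`.
#' @export
bucket_params <- function(ttsw = 100, initial_fill = 0.05,
                          daily_demand = 4, stress_onset_ftsw = 0.3,
                          season_start_doy = 100) {
  stopifnot(ttsw > 0, initial_fill >= 0, initial_fill <= 1,
            daily_demand >= 0,
            stress_onset_ftsw > 0, stress_onset_ftsw < 1)
  structure(list(ttsw = ttsw, initial_fill = initial_fill,
                 daily_demand = daily_demand,
                 stress_onset_ftsw = stress_onset_ftsw,
                 season_start_doy = season_start_doy),
            class = "bucket_params")
}

#' Run the soil-water bucket over a rainfall series
#'
#' Daily recurrence: transpiration
#' `T_t = min(demand * min(1, FTSW_t / onset), ATSW_t + rain_t)`,
#' then `ATSW_{t+1} = clamp(ATSW_t + rain_t - T_t, 0, ttsw)` with the
#' excess counted as drainage/runoff. `FTSW_t = ATSW_t / ttsw`. The
#' reported series gives, for each day, the state after that day's rain
#' and transpiration.
#'
#' Optionally the rooted capacity deepens after crop establishment, as
#' in crop models: from `ttsw0` at `growth_start_day` (typically the
#' sowing day, found with a first constant-capacity pass) the capacity
#' grows linearly to `ttsw` over `root_growth_days`. Rain exceeding the
#' current capacity infiltrates into the not-yet-rooted profile (an
#' internal reserve, capped at the remaining capacity) and becomes
#' available pro rata as roots reach it; only water beyond the full
#' profile drains. FTSW is the store over the *current* capacity. With
#' `root_growth_days = 0` (default) this reduces exactly to the
#' constant-capacity recurrence above.
#'
#' @param soil A [bucket_params()].
#' @param rain Numeric vector of daily rainfall, mm (>= 0).
#' @param season_id Identifier recorded in the series.
#' @param ttsw0 Rooted capacity before root growth, mm (default:
#'   `soil$ttsw`, i.e. constant capacity).
#' @param root_growth_days Days over which the capacity grows from
#'   `ttsw0` to `soil$ttsw` (0 disables growth).
#' @param growth_start_day Day the capacity starts growing.
#' @return A tibble of class `ftsw_series` with columns `season`, `day`,
#'   `rain`, `transpiration`, `overflow`, `atsw`, `ftsw` (`atsw` and
#'   `ftsw` are relative to the current rooted capacity; `overflow` is
#'   deep drainage past the full profile plus unrooted-reserve spill).
#'   The initial store is attached as attribute `"atsw0"` and the final
#'   unrooted reserve as attribute `"reserve_end"`.
#'
#' @examples
#' simulate_ftsw(bucket_params(initial_fill = 1), rain = rep(0, 30))
#' @export
simulate_ftsw <- function(soil, rain, season_id = "season1",
                          ttsw0 = NULL, root_growth_days = 0,
                          growth_start_day = 1) {
  stopifnot(inherits(soil, "bucket_params"), root_growth_days >= 0,
            growth_start_day >= 1)
  if (length(rain) == 0) abort("rain series is empty")
  if (any(rain < 0)) abort("rain must be non-negative")
  n <- length(rain)
  ttsw0 <- ttsw0 %||% soil$ttsw
  stopifnot(ttsw0 > 0, ttsw0 <= soil$ttsw)
  atsw <- transp <- over <- numeric(n)
  cap_prev <- ttsw0
  store <- soil$initial_fill * ttsw0
  reserve <- 0
  for (t in seq_len(n)) {
    cap <- if (root_growth_days > 0 && t >= growth_start_day) {
      min(soil$ttsw,
          ttsw0 + (soil$ttsw - ttsw0) *
            (t - growth_start_day) / root_growth_days)
    } else {
      ttsw0
    }
    # roots reach part of the infiltrated, previously unrooted water
    if (cap > cap_prev && soil$ttsw > cap_prev) {
      gained <- reserve * (cap - cap_prev) / (soil$ttsw - cap_prev)
      store <- store + gained
      reserve <- reserve - gained
    }
    cap_prev <- cap
    ftsw_now <- store / cap
    # demand develops with the crop: proportional to the rooted fraction
    # of the profile (equals daily_demand at constant full capacity)
    demand <- soil$daily_demand * (cap / soil$ttsw) *
      min(1, ftsw_now / soil$stress_onset_ftsw)
    transp[t] <- min(demand, store + rain[t])
    new_store <- store + rain[t] - transp[t]
    spill <- max(0, new_store - cap)
    store <- min(max(new_store, 0), cap)
    room <- (soil$ttsw - cap) - reserve
    to_reserve <- min(spill, max(room, 0))
    reserve <- reserve + to_reserve
    over[t] <- spill - to_reserve
    atsw[t] <- store
  }
  caps <- if (root_growth_days > 0) {
    pmin(soil$ttsw, ifelse(seq_len(n) >= growth_start_day,
                           ttsw0 + (soil$ttsw - ttsw0) *
                             (seq_len(n) - growth_start_day) /
                             root_growth_days,
                           ttsw0))
  } else {
    rep(ttsw0, n)
  }
  out <- tibble::tibble(season = season_id, day = seq_len(n), rain = rain,
                        transpiration = transp, overflow = over,
                        atsw = atsw, ftsw = atsw / caps)
  attr(out, "atsw0") <- soil$initial_fill * ttsw0
  attr(out, "reserve_end") <- reserve
  class(out) <- c("ftsw_series", class(out))
  out
}

#' Simulate a season of daily rainfall
#'
#' Bernoulli wet-day chain with gamma-distributed wet-day depths -- a
#' simple stand-in for a Sahelian rainy season, not a calibration to any
#' station. The monsoon arrives abruptly on an onset day drawn per
#' season and withdraws after a season length drawn per season, with a
#' short ramp at each edge; inter-annual variability in onset and
#' withdrawal is what produces contrasting stress patterns across
#' years (early rain gaps after a false start, or terminal drought when
#' the rains withdraw before maturity).
#'
#' @param n_days Days in the series (counted from the opening of the
#'   soil water balance).
#' @param p_wet_peak Wet-day probability in the core of the season.
#' @param p_pre Daily probability of an isolated pre-monsoon storm; such
#'   "false start" storms can trigger sowing well before the reliable
#'   rains and are the main source of early-season rain gaps.
#' @param onset_mean,onset_sd Mean and SD of the monsoon onset day.
#' @param length_mean,length_sd Mean and SD of the rainy-season length,
#'   days.
#' @param ramp_days Edge ramp of the wet-day probability, days.
#' @param shape,scale Gamma parameters for wet-day rainfall depth, mm.
#' @param seed Integer seed.
#' @return Numeric vector of daily rainfall, mm.
#' @export
simulate_rain_season <- function(n_days = 240, p_wet_peak = 0.45,
                                 p_pre = 0.003,
                                 onset_mean = 55, onset_sd = 12,
                                 length_mean = 125, length_sd = 15,
                                 ramp_days = 8, shape = 0.9, scale = 14,
                                 seed = 1) {
  stopifnot(n_days >= 1, p_wet_peak > 0, p_wet_peak <= 1, p_pre >= 0,
            shape > 0, scale > 0, onset_sd >= 0, length_sd >= 0)
  set.seed(as.integer(seed))
  onset <- max(1, round(rnorm(1, onset_mean, onset_sd)))
  len <- max(20, round(rnorm(1, length_mean, length_sd)))
  t <- seq_len(n_days)
  envelope <- pmin(1, pmax(0, (t - onset) / ramp_days)) *
    pmin(1, pmax(0, (onset + len - t) / ramp_days))
  p_wet <- pmax(p_wet_peak * envelope, ifelse(t < onset, p_pre, 0))
  wet <- rbinom(n_days, 1, p_wet)
  wet * rgamma(n_days, shape = shape, scale = scale)
}
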