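# Stress mortality: threshold-exceedance survival law and the net
# (stress-limited) instantaneous growth rate.

#' Critical thresholds and mortality rates for environmental stressors
#'
#' Container for the three stressors acting on fall armyworm populations:
#' cold (temperature below a critical minimum), heat (temperature above a
#' critical maximum), and desiccation (fraction of land at wilting point
#' above a critical fraction). Beyond each threshold, mortality scales
#' linearly with the depth of exceedance.
#'
#' Defaults are the published calibration: cold threshold 12.97 degC with
#' mortality 0.2 per degC-day; heat threshold 39.8 degC with mortality 0.02
#' per degC-day (10% daily mortality at 45 degC); wilting threshold 0.50
#' with mortality 0.2 per day per unit exceedance (10% daily mortality on
#' fully dry soil).
#'
#' @param CTmin Critical minimum temperature (degC).
#' @param mTmin Cold mortality rate (1 / (degC day)).
#' @param CTmax Critical maximum temperature (degC).
#' @param mTmax Heat mortality rate (1 / (degC day)).
#' @param Cwilting Critical wilting fraction (0-1).
#' @param mwilting Desiccation mortality rate (1/day per unit exceedance).
#' @return An object of class `stress_params`.
#' @export
stress_params <- function(CTmin = 12.97, mTmin = 0.2,
                          CTmax = 39.8, mTmax = 0.02,
                          Cwilting = 0.50, mwilting = 0.2) {
  if (!(CTmin < CTmax)) stop("stress_params: CTmin must be < CTmax")
  if (any(c(mTmin, mTmax, mwilting) < 0)) {
    stop("stress_params: mortality rates must be >= 0")
  }
  if (Cwilting < 0 || Cwilting > 1) {
    stop("stress_params: Cwilting must lie in [0, 1]")
  }
  structure(list(CTmin = CTmin, mTmin = mTmin,
                 CTmax = CTmax, mTmax = mTmax,
                 Cwilting = Cwilting, mwilting = mwilting),
            class = "stress_params")
}

#' @export
print.stress_params <- function(x, ...) {
  cat("<stress_params>\n")
  cat(sprintf("  cold:        CTmin = %g degC, m = %g /(degC day)\n", x$CTmin, x$mTmin))
  cat(sprintf("  heat:        CTmax = %g degC, m = %g /(degC day)\n", x$CTmax, x$mTmax))
  cat(sprintf("  desiccation: Cwilting = %g, m = %g /day\n", x$Cwilting, x$mwilting))
  invisible(x)
}

#' Positive exceedance of a stress threshold
#'
#' The positive number of units by which a stressor value crosses its
#' critical threshold: `max(0, value - threshold)` for stress accumulating
#' above the threshold (heat, wilting), `max(0, threshold - value)` for
#' stress below it (cold). Zero when the threshold is not exceeded.
#' Vectorised.
#'
#' @param value Stressor value(s), in the stressor's units.
#' @param threshold Critical threshold, same units.
#' @param direction `"above"` or `"below"`: the side on which stress
#'   accumulates.
#' @return Non-negative exceedance(s), same units.
#' @examples
#' stress_exceedance(-5, 12.97, "below")  # 17.97 degC of cold stress
#' stress_exceedance(45, 39.8, "above")   # 5.2 degC of heat stress
#' @export
stress_exceedance <- function(value, threshold, direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (direction == "above") pmax(0, value - threshold) else pmax(0, threshold - value)
}

#' Surviving proportion under accumulated stress
#'
#' The survival law `p = exp(-m * a * t)`: the proportion of a population
#' surviving exposure to `a` accumulated stress units for `t` days at
#' mortality rate `m`. Vectorised; always in (0, 1].
#'
#' @param m Mortality rate (1 / (stress unit x day)).
#' @param a Accumulated stress units (>= 0).
#' @param t Duration (days, >= 0).
#' @return Surviving proportion(s).
#' @examples
#' survival_fraction(0.2, 17.97, 3 / 24)  # ~0.64: 3 h at -5 degC
#' survival_fraction(0.02, 5.2, 1)        # ~0.90: one day at 45 degC
#' @export
survival_fraction <- function(m, a, t) {
  if (any(m < 0) || any(a < 0) || any(t < 0)) {
    stop("survival_fraction: m, a and t must all be >= 0")
  }
  exp(-m * a * t)
}

#' Solve the mortality rate from an observed surviving proportion
#'
#' Exact algebraic inverse of [survival_fraction()]:
#' `m = -log(p) / (a * t)`.
#'
#' @param p Surviving proportion, in (0, 1].
#' @param a Accumulated stress units.
#' @param t Duration (days).
#' @return Mortality rate(s).
#' @examples
#' solve_mortality_rate(0.9, 45 - 39.8, 1)  # ~0.02 per degC-day
#' @export
solve_mortality_rate <- function(p, a, t) {
  if (any(p <= 0) || any(p > 1)) {
    stop("solve_mortality_rate: p must lie in (0, 1]")
  }
  if (any(a * t == 0 & p < 1)) {
    stop("solve_mortality_rate: a * t must be positive when p < 1")
  }
  ifelse(p == 1, 0, -log(p) / (a * t))
}

#' Negative (stress) growth rate
#'
#' Sum over stressors of exceedance x mortality rate:
#' `rn = mTmin * max(0, CTmin - T) + mTmax * max(0, T - CTmax) +
#'  mwilting * max(0, wilting - Cwilting)`.
#' Non-negative; zero when no threshold is exceeded. Vectorised (arrays
#' pass through elementwise).
#'
#' @param temp_c Temperature(s), degC.
#' @param wilting Wilting fraction(s) in \[0, 1\]; `NA` allowed (propagates).
#' @param sp A [stress_params()] object.
#' @return Mortality rate(s), 1/day.
#' @export
negative_growth_rate <- function(temp_c, wilting = 0, sp = stress_params()) {
  stopifnot(inherits(sp, "stress_params"))
  if (any(wilting < 0 | wilting > 1, na.rm = TRUE)) {
    stop("negative_growth_rate: wilting must lie in [0, 1]")
  }
  sp$mTmin * stress_exceedance(temp_c, sp$CTmin, "below") +
    sp$mTmax * stress_exceedance(temp_c, sp$CTmax, "above") +
    sp$mwilting * stress_exceedance(wilting, sp$Cwilting, "above")
}

#' Instantaneous stress-limited growth rate
#'
#' Net per-capita rate `rp(T) - rn(T, wilting)`; may be negative where
#' stress mortality dominates. Vectorised.
#'
#' @inheritParams negative_growth_rate
#' @param tr A [thermal_response()] object.
#' @return Net rate(s), 1/day.
#' @export
instantaneous_rate <- function(temp_c, wilting = 0,
                               tr = thermal_response(), sp = stress_params()) {
  positive_growth_rate(temp_c, tr) - negative_growth_rate(temp_c, wilting, sp)
}

#' Aggregate an instantaneous rate series to daily or monthly means
#'
#' Bins a time series of instantaneous rates by calendar day or calendar
#' month and takes the arithmetic mean within each bin. Because
#' `exp(r1 t) * ... * exp(rn t) = exp((r1 + ... + rn) t)`, the mean rate
#' times the bin's total duration reproduces the product of per-period
#' growth factors exactly; order within a bin is irrelevant.
#'
#' @param series A data frame with columns `time` (POSIXct or Date) and
#'   `rate` (1/day).
#' @param target `"daily"` or `"monthly"`.
#' @return A tibble with columns `period` (Date, bin start), `rate` (mean),
#'   and `n` (timesteps in the bin). Bins with any missing rate yield `NA`.
#' @export
aggregate_rates <- function(series, target = c("daily", "monthly")) {
  target <- match.arg(target)
  stopifnot(is.data.frame(series), all(c("time", "rate") %in% names(series)))
  if (nrow(series) == 0) stop("aggregate_rates: empty series")
  tt <- series$time
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("aggregate_rates: timestamps must be strictly increasing")
  }
  bin <- if (target == "daily") {
    lubridate::floor_date(tt, "day")
  } else {
    lubridate::floor_date(tt, "month")
  }
  series |>
    dplyr::mutate(period = as.Date(bin)) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(rate = mean(.data$rate), n = dplyr::n(), .groups = "drop")
}
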