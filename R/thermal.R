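# Thermal performance: Sharpe-Schoolfield temperature response of the
# positive intrinsic growth rate, anchored at 27 degC.

GAS_CONSTANT <- 8.314  # J / (mol K)

#' Thermal response of positive population growth
#'
#' Constructs a Sharpe-Schoolfield temperature-response object describing how
#' the positive component of the intrinsic growth rate varies with
#' temperature. The curve is the classic enzyme-kinetics form with low- and
#' high-temperature inactivation terms; its absolute level is anchored so that
#' the rate at `T_ref` (27 degC) equals `r_ref`, the laboratory-measured
#' intrinsic rate of increase of fall armyworm on maize (reported range
#' 0.12-0.20 per day across populations; default 0.16, the midpoint).
#'
#' The default shape parameters were obtained by calibrating the curve to
#' three anchors: a unique maximum at 33.5 degC, a rate at 40 degC equal to
#' 35% of that maximum, and a near-zero rate (1% of maximum) at the
#' 12.95 degC lower development threshold. See
#' [calibrate_thermal_response()] to re-derive them.
#'
#' @param r_ref Intrinsic rate of increase at the anchor temperature (1/day).
#' @param T_ref Anchor temperature (degC).
#' @param rho_ref Base reaction rate scaling (dimensionless here; the absolute
#'   level is set by `r_ref`, so `rho_ref` only shifts the internal shape
#'   scale).
#' @param HA Enthalpy of activation (J/mol).
#' @param HL,TL Low-temperature inactivation enthalpy (J/mol, negative) and
#'   half-inactivation temperature (K).
#' @param HH,TH High-temperature inactivation enthalpy (J/mol, positive) and
#'   half-inactivation temperature (K).
#' @return An object of class `thermal_response`.
#' @examples
#' tr <- thermal_response()
#' positive_growth_rate(27, tr)   # equals r_ref
#' positive_growth_rate(33.5, tr) # near the maximum
#' @export
thermal_response <- function(r_ref = 0.16, T_ref = 27,
                             rho_ref = 1,
                             HA = 73366.014657,
                             HL = -132388.448723, TL = 304.75394,
                             HH = 323485.841581, TH = 306.863533) {
  stopifnot(is.numeric(r_ref), length(r_ref) == 1, r_ref > 0,
            is.numeric(T_ref), length(T_ref) == 1,
            HL < 0, HH > 0, TL > 0, TH > 0, HA > 0, rho_ref > 0)
  obj <- structure(
    list(r_ref = r_ref, T_ref = T_ref, rho_ref = rho_ref,
         HA = HA, HL = HL, TL = TL, HH = HH, TH = TH),
    class = "thermal_response"
  )
  obj$shape_ref <- sd_shape(T_ref, obj)
  if (!is.finite(obj$shape_ref) || obj$shape_ref <= 0) {
    stop("thermal_response: shape is not positive at T_ref; invalid parameters")
  }
  obj
}

# Raw Schoolfield shape (arbitrary units); vectorised over temperature.
sd_shape <- function(temp_c, tr) {
  TK <- temp_c + 273.15
  Tr <- tr$T_ref + 273.15
  num <- tr$rho_ref * (TK / Tr) * exp((tr$HA / GAS_CONSTANT) * (1 / Tr - 1 / TK))
  den <- 1 +
    exp((tr$HL / GAS_CONSTANT) * (1 / tr$TL - 1 / TK)) +
    exp((tr$HH / GAS_CONSTANT) * (1 / tr$TH - 1 / TK))
  num / den
}

#' Positive growth rate at a temperature
#'
#' Evaluates the positive component of the intrinsic growth rate,
#' `r_p(T) = r_ref * shape(T) / shape(T_ref)`, so that
#' `r_p(T_ref) == r_ref` exactly. Total function: finite, non-negative for
#' all finite temperatures. Vectorised over `temp_c`.
#'
#' @param temp_c Temperature(s), degC.
#' @param tr A [thermal_response()] object.
#' @return Growth rate(s), 1/day.
#' @export
positive_growth_rate <- function(temp_c, tr = thermal_response()) {
  stopifnot(inherits(tr, "thermal_response"))
  tr$r_ref * (sd_shape(temp_c, tr) / tr$shape_ref)
}

#' Calibrate the thermal response to its printed anchors
#'
#' Fits the five Schoolfield shape parameters (HA, HL, TL, HH, TH) by
#' least squares to three anchors: the location of the curve's maximum, the
#' rate at a reference high temperature relative to that maximum, and a
#' near-zero relative rate at the lower development threshold. With five
#' parameters and three constraints the fit is under-determined; a fixed
#' starting point and deterministic Nelder-Mead search make the result
#' reproducible.
#'
#' @param peak_temp Temperature of the curve maximum (degC; default 33.5).
#' @param hot_temp,hot_ratio High-temperature anchor: rate(`hot_temp`) equals
#'   `hot_ratio` x maximum (defaults 40 degC, 0.35).
#' @param low_temp,low_ratio Lower-threshold anchor: rate(`low_temp`) is
#'   targeted at `low_ratio` x maximum (defaults 12.95 degC, 0.01; the
#'   development threshold is treated as "at most 2% of peak", and the 1%
#'   target keeps comfortably inside that bound).
#' @param r_ref,T_ref Passed through to [thermal_response()].
#' @param grid_step Temperature grid resolution used to locate the maximum
#'   during fitting (degC).
#' @param tol Maximum acceptable objective value (sum of squared scaled
#'   residuals) for the fit to be declared converged.
#' @return A calibrated [thermal_response()] object.
#' @seealso [positive_growth_rate()]
#' @export
calibrate_thermal_response <- function(peak_temp = 33.5,
                                       hot_temp = 40, hot_ratio = 0.35,
                                       low_temp = 12.95, low_ratio = 0.01,
                                       r_ref = 0.16, T_ref = 27,
                                       grid_step = 0.01, tol = 1e-4) {
  grid <- seq(-10, 50, by = grid_step)
  objective <- function(x) {
    tr <- list(rho_ref = 1, T_ref = T_ref,
               HA = exp(x[1]), HL = -exp(x[2]), TL = x[3],
               HH = exp(x[4]), TH = x[5])
    v <- sd_shape(grid, tr)
    if (any(!is.finite(v))) return(1e10)
    i <- which.max(v)
    vmax <- v[i]
    ((grid[i] - peak_temp) / 0.02)^2 +
      ((sd_shape(hot_temp, tr) / vmax - hot_ratio) / 0.002)^2 +
      ((sd_shape(low_temp, tr) / vmax - low_ratio) / 0.002)^2
  }
  start <- c(log(7e4), log(2.8e5), 284, log(5.8e5), 307)
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (fit$convergence != 0 || fit$value > tol) {
    stop("calibrate_thermal_response: failed to converge to the anchors ",
         sprintf("(objective %.3g, convergence code %d)",
                 fit$value, fit$convergence))
  }
  thermal_response(r_ref = r_ref, T_ref = T_ref,
                   HA = exp(fit$par[1]),
                   HL = -exp(fit$par[2]), TL = fit$par[3],
                   HH = exp(fit$par[4]), TH = fit$par[5])
}

#' @export
print.thermal_response <- function(x, ...) {
  cat("<thermal_response>\n")
  cat(sprintf("  anchor: r(%g degC) = %g /day\n", x$T_ref, x$r_ref))
  g <- glance(x)
  cat(sprintf("  peak:   %g /day at %.2f degC\n", g$peak_rate, g$peak_temp))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a thermal response into a parameter table
#'
#' @param x A `thermal_response` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy thermal_response
#' @export
tidy.thermal_response <- function(x, ...) {
  terms <- c("r_ref", "T_ref", "rho_ref", "HA", "HL", "TL", "HH", "TH")
  tibble::tibble(term = terms,
                 estimate = vapply(terms, function(f) x[[f]], numeric(1)))
}

#' One-row summary of a thermal response curve
#'
#' Evaluates the curve on a dense grid and reports its maximum, the
#' temperature at the maximum, and the relative rates at the calibration
#' anchor temperatures.
#'
#' @param x A `thermal_response` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance thermal_response
#' @export
glance.thermal_response <- function(x, ...) {
  grid <- seq(-10, 50, by = 0.01)
  v <- positive_growth_rate(grid, x)
  i <- which.max(v)
  tibble::tibble(
    peak_temp = grid[i],
    peak_rate = v[i],
    ratio_at_40 = positive_growth_rate(40, x) / v[i],
    ratio_at_12.95 = positive_growth_rate(12.95, x) / v[i],
    r_ref = x$r_ref
  )
}

#' Plot a thermal response curve
#'
#' @param object A `thermal_response` object.
#' @param from,to Temperature range (degC).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thermal_response
#' @export
autoplot.thermal_response <- function(object, from = 0, to = 45, ...) {
  df <- tibble::tibble(temperature = seq(from, to, by = 0.1))
  df$rate <- positive_growth_rate(df$temperature, object)
  ggplot2::ggplot(df, ggplot2::aes(.data$temperature, .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)",
                  y = "Positive growth rate (1/day)")
}
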