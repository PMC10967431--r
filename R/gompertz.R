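#' Gompertz curve parameters
#'
#' Parameter set for the four-parameter Gompertz S-curve used to describe
#' cumulative body weight, feed intake, and drinking-water intake of
#' fattening pigs:
#' \deqn{y(t) = A + M \exp(-\exp(-B (t - t^*)))}
#' where \eqn{t} is the age of the animal in days, \eqn{A} an offset in the
#' units of the curve, \eqn{M} the asymptote (mature value), \eqn{B} the
#' rate parameter (per day) and \eqn{t^*} the age at which growth is
#' maximal.  Asymptotes are expressed directly in kg (weight, feed) or L
#' (water); no gram-to-kilogram scaling is applied.
#'
#' @param offset_A offset \eqn{A}, same units as the curve value.
#' @param asymptote_M asymptote \eqn{M} (> 0), same units as the curve value.
#' @param rate_B rate parameter \eqn{B} (> 0), per day.
#' @param t_star age at maximal growth \eqn{t^*} (> 0), days.
#' @return An object of class `gompertz_params`.
#' @seealso [gompertz_defaults()] for the calibrated defaults.
#' @export
#' @examples
#' p <- gompertz_params(0, 164.2, 0.0146, 110.4)
#' gompertz_value(p, 110.4)  # inflection: A + M/e
gompertz_params <- function(offset_A, asymptote_M, rate_B, t_star) {
  stopifnot(is.numeric(offset_A), is.numeric(asymptote_M),
            is.numeric(rate_B), is.numeric(t_star))
  if (asymptote_M <= 0) stop("asymptote_M must be > 0")
  if (rate_B <= 0) stop("rate_B must be > 0")
  if (t_star <= 0) stop("t_star must be > 0")
  structure(list(offset_A = offset_A, asymptote_M = asymptote_M,
                 rate_B = rate_B, t_star = t_star),
            class = "gompertz_params")
}

#' Calibrated Gompertz defaults for fattening pigs
#'
#' Regression-calibrated parameter sets for the weight (kg), cumulative
#' feed intake (kg) and cumulative drinking-water intake (L) curves.  The
#' asymptote is routinely re-fitted to scenario endpoints with
#' [fit_endpoints()]; offset, rate and inflection age are held fixed.
#'
#' @param curve one of `"weight"`, `"feed"`, `"water"`.
#' @return A `gompertz_params` object.
#' @export
gompertz_defaults <- function(curve = c("weight", "feed", "water")) {
  curve <- match.arg(curve)
  switch(curve,
    weight = gompertz_params(0,    164.2, 0.0146, 110.4),
    feed   = gompertz_params(-41.9, 608,  0.0111, 154.7),
    water  = gompertz_params(-149, 1432,  0.0103, 147.4))
}

#' Evaluate a Gompertz curve
#'
#' @param params a [gompertz_params()] object.
#' @param t day of age; vectorised.
#' @return Curve value(s) in the units of the parameter set (kg or L).
#' @export
gompertz_value <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"), is.finite(t))
  params$offset_A +
    params$asymptote_M * exp(-exp(-params$rate_B * (t - params$t_star)))
}

# Inverse of the double exponential: age at which the curve passes `value`.
# Defined for offset_A < value < offset_A + asymptote_M.
gompertz_inverse <- function(params, value) {
  u <- (value - params$offset_A) / params$asymptote_M
  if (any(u <= 0) || any(u >= 1)) {
    stop("value outside the open range (offset_A, offset_A + asymptote_M)")
  }
  params$t_star - log(-log(u)) / params$rate_B
}

#' Fit the Gompertz asymptote to scenario endpoints
#'
#' Re-fits the free asymptote \eqn{M} and the entry age \eqn{t_0} so that
#' the curve passes through the observed start and end weight of the
#' growing period, holding offset, rate and inflection age at their
#' calibrated values.  The entry age is recovered in closed form by
#' inverting the double exponential; \eqn{M} is found by root bracketing
#' on the end-of-period residual over `[1.0001 * end_value, 10 * end_value]`.
#'
#' @param defaults a [gompertz_params()] object providing `offset_A`,
#'   `rate_B` and `t_star`.
#' @param start_value curve value at entry (kg or L), > 0 and < `end_value`.
#' @param end_value curve value at the end of the period.
#' @param period_length length of the growing period, days.
#' @return A list with `params` (the refitted `gompertz_params`) and
#'   `age_at_entry` (days).
#' @export
#' @examples
#' fit <- fit_endpoints(gompertz_defaults("weight"), 23.6, 115.6, 96)
#' gompertz_value(fit$params, fit$age_at_entry)               # 23.6
#' gompertz_value(fit$params, fit$age_at_entry + 96)          # 115.6
fit_endpoints <- function(defaults, start_value, end_value, period_length) {
  stopifnot(inherits(defaults, "gompertz_params"),
            start_value > 0, end_value > start_value, period_length > 0)
  residual <- function(M) {
    p <- gompertz_params(defaults$offset_A, M, defaults$rate_B,
                         defaults$t_star)
    t0 <- gompertz_inverse(p, start_value)
    gompertz_value(p, t0 + period_length) - end_value
  }
  lo <- end_value * 1.0001
  hi <- end_value * 10
  # start_value must lie above offset_A for the inverse to exist at lo
  if (start_value <= defaults$offset_A) {
    stop("start_value must exceed the curve offset")
  }
  f_lo <- residual(lo)
  f_hi <- residual(hi)
  if (f_lo * f_hi > 0) {
    stop("no asymptote in [", format(lo), ", ", format(hi),
         "] reaches end_value ", end_value, " after ", period_length,
         " days (residuals ", format(f_lo), " / ", format(f_hi), ")")
  }
  M <- stats::uniroot(residual, c(lo, hi), tol = 1e-10)$root
  params <- gompertz_params(defaults$offset_A, M, defaults$rate_B,
                            defaults$t_star)
  list(params = params, age_at_entry = gompertz_inverse(params, start_value))
}

#' Fit the asymptote of an intake curve to a period total
#'
#' For cumulative feed and water curves, the asymptote is fitted so that
#' the cumulative increase over the growing period equals the recorded
#' total intake.  Because the period increment is linear in \eqn{M}
#' (\eqn{\Delta = M (G(t_0+L) - G(t_0))} with \eqn{G} the unit double
#' exponential), the fit is closed-form.  The entry age comes from the
#' weight fit.
#'
#' @param defaults a [gompertz_params()] object for the intake curve.
#' @param total total cumulative intake over the period (kg feed or L water).
#' @param age_at_entry entry age from the weight fit, days.
#' @param period_length days.
#' @return A refitted `gompertz_params` object.
#' @export
fit_total <- function(defaults, total, age_at_entry, period_length) {
  stopifnot(inherits(defaults, "gompertz_params"), total > 0,
            period_length > 0)
  g <- function(t) exp(-exp(-defaults$rate_B * (t - defaults$t_star)))
  dg <- g(age_at_entry + period_length) - g(age_at_entry)
  gompertz_params(defaults$offset_A, total / dg, defaults$rate_B,
                  defaults$t_star)
}

#' Daily values from a cumulative Gompertz curve
#'
#' First differences of the cumulative curve over a growing period:
#' day \eqn{d} carries \eqn{y(t_0 + d) - y(t_0 + d - 1)}.  Negative
#' differences cannot arise for positive rate parameters, but daily intakes
#' derived from curves with negative offsets are clamped at zero as a
#' guard.
#'
#' @param params a [gompertz_params()] object.
#' @param age_at_entry entry age \eqn{t_0}, days.
#' @param period_length number of days (>= 1).
#' @param clamp_zero clamp negative daily values at 0 (default `TRUE`).
#' @return Numeric vector of length `period_length`.
#' @export
daily_series <- function(params, age_at_entry, period_length,
                         clamp_zero = TRUE) {
  stopifnot(period_length >= 1)
  t <- age_at_entry + seq_len(period_length)
  d <- gompertz_value(params, t) - gompertz_value(params, t - 1)
  if (clamp_zero) d <- pmax(d, 0)
  d
}

#' Growth, feed and water trajectory for a growing period
#'
#' Fits the weight curve to the start/end weights, the feed and water
#' curves to the period totals, and extracts the daily series the
#' excretion balance consumes.
#'
#' @param start_weight,end_weight kg at entry and exit.
#' @param period_days length of the growing period, days.
#' @param total_feed total feed intake over the period, kg.
#' @param total_water total drinking water over the period, L.
#' @param defaults list with elements `weight`, `feed`, `water`, each a
#'   [gompertz_params()]; defaults to [gompertz_defaults()] for each.
#' @return A list of class `growth_trajectory` with the fitted parameter
#'   sets, `age_at_entry`, and a data frame `daily` with columns `day`,
#'   `weight_kg`, `gain_kg`, `feed_kg`, `water_L`.
#' @export
#' @examples
#' tr <- growth_trajectory(23.6, 115.6, 96, 210, 520)
#' head(tr$daily)
growth_trajectory <- function(start_weight, end_weight, period_days,
                              total_feed, total_water,
                              defaults = list(
                                weight = gompertz_defaults("weight"),
                                feed   = gompertz_defaults("feed"),
                                water  = gompertz_defaults("water"))) {
  wfit <- fit_endpoints(defaults$weight, start_weight, end_weight,
                        period_days)
  t0 <- wfit$age_at_entry
  pfeed  <- fit_total(defaults$feed,  total_feed,  t0, period_days)
  pwater <- fit_total(defaults$water, total_water, t0, period_days)
  day <- seq_len(period_days)
  weight <- gompertz_value(wfit$params, t0 + day)
  gain <- daily_series(wfit$params, t0, period_days, clamp_zero = FALSE)
  daily <- data.frame(
    day = day,
    weight_kg = weight,
    gain_kg = gain,
    feed_kg = daily_series(pfeed, t0, period_days),
    water_L = daily_series(pwater, t0, period_days))
  structure(list(weight = wfit$params, feed = pfeed, water = pwater,
                 age_at_entry = t0, period_days = period_days,
                 daily = daily),
            class = "growth_trajectory")
}
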