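#' Reference-method emission from concentrations and ventilation
#'
#' Emission per pig place from a discrete measurement: the concentration
#' difference between outgoing and incoming air (ppm) is converted to
#' mg/m^3 with the gas density, multiplied by the ventilation rate per
#' pig place, and annualized:
#' \deqn{E = (C_{out} - C_{in}) \, \rho \, V \cdot 24 \cdot 365 / 10^6}
#' then reduced by the vacancy factor between production cycles.
#' Densities for the ppm-to-mg/m^3 conversion are 0.667 kg/m^3 for CH4
#' and 0.71 kg/m^3 for NH3 (see [gas_density()]).
#'
#' @param C_out,C_in outgoing / incoming concentration, ppm.
#' @param density ppm-to-mg/m^3 conversion factor, kg/m^3.
#' @param vent ventilation rate, m^3/h per pig place.
#' @param vacancy vacancy factor (default 0.03).
#' @return kg per year per pig place.
#' @export
#' @examples
#' measured_emission(12, 2, gas_density("CH4"), 60, vacancy = 0)
measured_emission <- function(C_out, C_in, density, vent, vacancy = 0.03) {
  stopifnot(all(vent >= 0), all(density > 0), vacancy >= 0, vacancy < 1)
  dC <- C_out - C_in
  if (any(dC < 0)) {
    message("negative concentration difference in ", sum(dC < 0),
            " record(s); retained (sensor noise)")
  }
  dC * density * vent * 24 * 365 / 1e6 * (1 - vacancy)
}

#' Gas densities for ppm conversion
#'
#' @param gas `"CH4"` or `"NH3"`.
#' @return kg/m^3 (0.667 for CH4, 0.71 for NH3).
#' @export
gas_density <- function(gas = c("CH4", "NH3")) {
  gas <- match.arg(gas)
  c(CH4 = 0.667, NH3 = 0.71)[[gas]]
}

#' Mean absolute error
#'
#' @param measured,predicted paired numeric series of equal length.
#' @return MAE in the units of the series.
#' @export
mae <- function(measured, predicted) {
  check_paired(measured, predicted, 1)
  mean(abs(measured - predicted))
}

#' Root mean square error
#'
#' @inheritParams mae
#' @return RMSE in the units of the series; always `>=` the MAE.
#' @export
rmse <- function(measured, predicted) {
  check_paired(measured, predicted, 1)
  sqrt(mean((measured - predicted)^2))
}

#' Coefficient of determination
#'
#' \deqn{R^2 = 1 - \sum (V - \hat V)^2 / \sum (V - \bar V)^2}
#' relative to the mean of the measured series; may be negative when the
#' predictions do worse than the measured mean.
#'
#' @inheritParams mae
#' @return Dimensionless; errors when the measured series has zero
#'   variance or fewer than two values.
#' @export
r2 <- function(measured, predicted) {
  check_paired(measured, predicted, 2)
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) stop("R^2 undefined: measured series has zero variance")
  1 - sum((measured - predicted)^2) / ss_tot
}

check_paired <- function(measured, predicted, n_min) {
  if (length(measured) != length(predicted)) {
    stop("measured and predicted series must have equal length")
  }
  if (length(measured) < n_min) {
    stop("need at least ", n_min, " paired values")
  }
  invisible(TRUE)
}

#' Validation summary for paired series
#'
#' @inheritParams mae
#' @return Data frame with one row: `n`, `mae`, `rmse`, `r2` (`r2` is
#'   `NA` when undefined).
#' @export
validate_series <- function(measured, predicted) {
  r2v <- tryCatch(r2(measured, predicted), error = function(e) NA_real_)
  data.frame(n = length(measured),
             mae = mae(measured, predicted),
             rmse = rmse(measured, predicted),
             r2 = r2v)
}

#' Emission reduction relative to a reference system
#'
#' @param reference_mean mean emission of the reference system (> 0).
#' @param treatment_mean mean emission of the mitigation system.
#' @return Reduction in percent, `100 (1 - treatment/reference)`.
#' @export
#' @examples
#' reduction_percent(2.71, 1.01)  # 62.7
reduction_percent <- function(reference_mean, treatment_mean) {
  if (reference_mean <= 0) stop("reference_mean must be > 0")
  100 * (1 - treatment_mean / reference_mean)
}
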