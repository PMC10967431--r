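#' Diet specification
#'
#' Feed composition and digestibility coefficients driving the excretion
#' mass balances.  Crude protein and ash are components of the dry matter,
#' so `crude_protein_frac + ash_frac <= dry_matter_frac` must hold.
#'
#' @param dry_matter_frac kg DM per kg feed.
#' @param crude_protein_frac kg crude protein per kg feed.
#' @param ash_frac kg ash per kg feed.
#' @param digestibility_OM apparent digestibility of feed organic matter.
#' @param digestibility_CP apparent digestibility of crude protein.
#' @param ash_retention_frac fraction of ash intake retained in the body.
#' @param urinary_organic_frac organic (urea) share of urinary solids,
#'   used to split urinary dry matter between the volatile-solids pool and
#'   minerals.
#' @return An object of class `diet_spec`.
#' @export
#' @examples
#' diet_spec()  # nominal Dutch fattening diet
diet_spec <- function(dry_matter_frac = 0.88,
                      crude_protein_frac = 0.165,
                      ash_frac = 0.055,
                      digestibility_OM = 0.85,
                      digestibility_CP = 0.80,
                      ash_retention_frac = 0.35,
                      urinary_organic_frac = 0.85) {
  fr <- c(dry_matter_frac, crude_protein_frac, ash_frac, digestibility_OM,
          digestibility_CP, ash_retention_frac, urinary_organic_frac)
  if (any(fr < 0 | fr > 1)) stop("all diet fractions must lie in [0, 1]")
  if (crude_protein_frac + ash_frac > dry_matter_frac) {
    stop("crude_protein_frac + ash_frac must not exceed dry_matter_frac")
  }
  structure(list(dry_matter_frac = dry_matter_frac,
                 crude_protein_frac = crude_protein_frac,
                 ash_frac = ash_frac,
                 digestibility_OM = digestibility_OM,
                 digestibility_CP = digestibility_CP,
                 ash_retention_frac = ash_retention_frac,
                 urinary_organic_frac = urinary_organic_frac),
            class = "diet_spec")
}

#' Daily nitrogen balance
#'
#' Partitions nitrogen intake (crude protein / 6.25) into faecal N
#' (undigested protein), retained N (body protein deposition, 16% N), and
#' urinary N as the closing residual.  Retention is capped at digestible N;
#' a negative urinary residual is clamped at zero with a warning.
#'
#' @param feed_kg feed intake, kg/d.
#' @param diet a [diet_spec()].
#' @param weight_gain body-weight gain, kg/d.
#' @param body_protein_per_gain kg body protein per kg gain (default 0.16).
#' @param n_per_protein kg N per kg protein (default 0.16, i.e. 1/6.25).
#' @return List with `N_intake`, `N_faecal`, `N_retained`, `N_urinary`
#'   (all kg N/d).
#' @export
nitrogen_balance <- function(feed_kg, diet, weight_gain,
                             body_protein_per_gain = 0.16,
                             n_per_protein = 0.16) {
  stopifnot(feed_kg >= 0, weight_gain >= 0)
  N_intake <- feed_kg * diet$crude_protein_frac / 6.25
  N_faecal <- (1 - diet$digestibility_CP) * N_intake
  N_digestible <- N_intake - N_faecal
  N_retained <- min(weight_gain * body_protein_per_gain * n_per_protein,
                    N_digestible)
  N_urinary <- N_intake - N_faecal - N_retained
  if (N_urinary < 0) {
    warning("urinary N residual negative (", format(N_urinary),
            " kg N/d); clamped to 0")
    N_urinary <- 0
  }
  list(N_intake = N_intake, N_faecal = N_faecal,
       N_retained = N_retained, N_urinary = N_urinary)
}

#' Daily solids balance
#'
#' Excreted dry matter is assembled from undigested feed organic matter,
#' net excreted ash, and urinary solids (urea plus minerals, parameterised
#' as `c_us` kg solids per kg urinary N from urea stoichiometry:
#' CO(NH2)2 / 2N = 60/28 = 2.14).  Excreted organic matter (the
#' volatile solids fed to the methane module) is the faecal OM plus the
#' organic share of the urinary solids.
#'
#' @param feed_kg kg feed/d.
#' @param diet a [diet_spec()].
#' @param urinary_N kg urinary N/d.
#' @param c_us kg urinary solids per kg urinary N (default 2.14).
#' @return List with `faecal_OM`, `ash_exc`, `urinary_solids`, `DM_exc`,
#'   `OM_exc` (all kg/d).
#' @export
solids_balance <- function(feed_kg, diet, urinary_N, c_us = 2.14) {
  stopifnot(feed_kg >= 0, urinary_N >= 0)
  feed_OM <- feed_kg * (diet$dry_matter_frac - diet$ash_frac)
  faecal_OM <- (1 - diet$digestibility_OM) * feed_OM
  ash_exc <- (1 - diet$ash_retention_frac) * feed_kg * diet$ash_frac
  urinary_solids <- c_us * urinary_N
  DM_exc <- faecal_OM + ash_exc + urinary_solids
  OM_exc <- faecal_OM + diet$urinary_organic_frac * urinary_solids
  list(faecal_OM = faecal_OM, ash_exc = ash_exc,
       urinary_solids = urinary_solids, DM_exc = DM_exc, OM_exc = OM_exc)
}

#' Daily water balance
#'
#' Water reaching the pit is drinking water plus feed moisture plus
#' metabolic water, minus water retained in body growth, respiratory and
#' evaporative losses, and floor evaporation.  Negative balances are
#' clamped at zero with a warning.
#'
#' @param water_L drinking water, L/d.
#' @param feed_kg feed intake, kg/d.
#' @param diet a [diet_spec()].
#' @param weight_gain kg/d.
#' @param evap_floor evaporation from the fouled floor, L/d.
#' @param metabolic_per_DM L metabolic water per kg DM digested (default 0.4).
#' @param body_water_per_gain L body water retained per kg gain (default 0.70).
#' @param respiratory_frac fraction of water intake lost by respiration
#'   and evaporation from the animal (default 0.25).
#' @return `water_to_pit` in L/d.
#' @export
water_balance <- function(water_L, feed_kg, diet, weight_gain,
                          evap_floor = 0,
                          metabolic_per_DM = 0.4,
                          body_water_per_gain = 0.70,
                          respiratory_frac = 0.25) {
  stopifnot(water_L >= 0, feed_kg >= 0, weight_gain >= 0, evap_floor >= 0)
  feed_moisture <- feed_kg * (1 - diet$dry_matter_frac)
  DM_digested <- feed_kg * diet$dry_matter_frac * diet$digestibility_OM
  inflow <- water_L + feed_moisture + metabolic_per_DM * DM_digested
  outflow <- body_water_per_gain * weight_gain +
    respiratory_frac * water_L + evap_floor
  w <- inflow - outflow
  if (w < 0) {
    warning("water balance negative (", format(w), " L/d); clamped to 0")
    w <- 0
  }
  w
}

#' TAN precursor from urinary nitrogen
#'
#' The urea share of urinary N, assumed fully hydrolysed to total
#' ammoniacal nitrogen within the day (urease is in excess on fouled
#' surfaces and in the pit).
#'
#' @param N_urinary kg urinary N/d.
#' @param urea_fraction fraction of urinary N excreted as urea
#'   (default 0.75).
#' @return kg TAN-N per day.
#' @export
tan_potential <- function(N_urinary, urea_fraction = 0.75) {
  stopifnot(urea_fraction >= 0, urea_fraction <= 1, N_urinary >= 0)
  urea_fraction * N_urinary
}

#' One day of excretion
#'
#' Runs the nitrogen, solids and water balances for one average pig-day
#' and assembles the slurry stream discharged to the pit.  The slurry mass
#' is corrected for gas losses during hydrolysis: a configurable share of
#' the excreted organic matter leaves as biogas, and hydrolysed urea-N
#' releases CO2 at a molar ratio of one CO2 per two urea N, a net mass
#' loss of 0.733 kg per kg urea-N hydrolysed after the water of
#' hydrolysis is retained in the slurry.
#'
#' @param feed_kg,water_L,weight_gain daily intake and gain for one pig.
#' @param diet a [diet_spec()].
#' @param evap_floor floor evaporation attributed to this pig, L/d.
#' @param urea_fraction urea share of urinary N (default 0.75).
#' @param biogas_frac_OM share of excreted OM lost as biogas during
#'   hydrolysis (default 0.05).
#' @param co2_per_urea_N kg CO2 per kg urea-N hydrolysed (default 0.733).
#' @param ... passed to [nitrogen_balance()] (e.g.
#'   `body_protein_per_gain`).
#' @return A one-row data frame (class `excretion_day`) with the fields
#'   `feed_kg`, `water_L`, `N_total`, `N_urinary`, `N_faecal`,
#'   `N_retained`, `TAN_potential`, `faecal_OM`, `ash_exc`,
#'   `urinary_solids`, `DM_exc`, `OM_exc`, `water_to_pit`,
#'   `gas_correction`, `slurry_mass` (kg or L per day).
#' @export
#' @examples
#' excretion_day(2.2, 5.5, 0.85, diet_spec())
excretion_day <- function(feed_kg, water_L, weight_gain, diet,
                          evap_floor = 0, urea_fraction = 0.75,
                          biogas_frac_OM = 0.05, co2_per_urea_N = 0.733,
                          ...) {
  nb <- nitrogen_balance(feed_kg, diet, weight_gain, ...)
  sb <- solids_balance(feed_kg, diet, nb$N_urinary)
  w <- water_balance(water_L, feed_kg, diet, weight_gain, evap_floor)
  tan <- tan_potential(nb$N_urinary, urea_fraction)
  gas <- biogas_frac_OM * sb$OM_exc + co2_per_urea_N * tan
  slurry <- sb$DM_exc + w - gas  # 1 kg per L of water
  if (slurry < 0) slurry <- 0
  out <- data.frame(
    feed_kg = feed_kg, water_L = water_L,
    N_total = nb$N_urinary + nb$N_faecal,
    N_urinary = nb$N_urinary, N_faecal = nb$N_faecal,
    N_retained = nb$N_retained, TAN_potential = tan,
    faecal_OM = sb$faecal_OM, ash_exc = sb$ash_exc,
    urinary_solids = sb$urinary_solids, DM_exc = sb$DM_exc,
    OM_exc = sb$OM_exc, water_to_pit = w,
    gas_correction = gas, slurry_mass = slurry)
  class(out) <- c("excretion_day", class(out))
  out
}
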