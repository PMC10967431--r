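#' Synthetic weather series
#'
#' Sinusoidal seasonal cycle with Gaussian noise, emulating a Dutch
#' annual outside-temperature and relative-humidity series.  Temperature
#' peaks in mid July; relative humidity is higher in winter.  The series
#' is fully determined by the seed.
#'
#' @param seed integer RNG seed.
#' @param n_days number of days (default 365).
#' @param start_date first date (default `"2020-10-08"`).
#' @param mean_T annual mean temperature, degrees C (default 10.5).
#' @param amplitude_T seasonal half-range, degrees C (default 7).
#' @param sigma_T day-to-day noise s.d., degrees C (default 3).
#' @param mean_RH annual mean relative humidity, % (default 80).
#' @param amplitude_RH seasonal half-range of RH, % (default 8; RH is
#'   lower in summer).
#' @param sigma_RH RH noise s.d., % (default 5).
#' @return Data frame with columns `date`, `T_out_C`, `RH_out_pct`.
#' @export
#' @examples
#' w <- weather_fixture(42, 30)
#' head(w)
weather_fixture <- function(seed, n_days = 365, start_date = "2020-10-08",
                            mean_T = 10.5, amplitude_T = 7, sigma_T = 3,
                            mean_RH = 80, amplitude_RH = 8, sigma_RH = 5) {
  stopifnot(n_days >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  date <- as.Date(start_date) + seq_len(n_days) - 1
  doy <- as.integer(format(date, "%j"))
  season <- sin(2 * pi * (doy - 105) / 365)  # peaks around 15 July
  T_out <- mean_T + amplitude_T * season + stats::rnorm(n_days, 0, sigma_T)
  RH <- mean_RH - amplitude_RH * season + stats::rnorm(n_days, 0, sigma_RH)
  data.frame(date = date, T_out_C = T_out,
             RH_out_pct = pmin(100, pmax(30, RH)))
}

#' Read a daily weather series from CSV
#'
#' @param path CSV with columns `date`, `T_out_C`, `RH_out_pct`.
#' @return Data frame with `date` parsed as `Date`.
#' @export
read_weather <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "T_out_C", "RH_out_pct")
  if (!all(need %in% names(w))) {
    stop("weather CSV needs columns: ", paste(need, collapse = ", "))
  }
  w$date <- as.Date(w$date)
  w
}

# Saturation vapour pressure (kPa), Magnus form.
saturation_vp <- function(T_C) 0.6108 * exp(17.27 * T_C / (T_C + 237.3))

# Floor evaporation (L/d for the whole room): a reference coefficient at
# 20 C / 60% RH scaled by the saturation deficit of the room air.
floor_evaporation <- function(evap_coef, wetted_area, room_T, room_RH) {
  deficit <- saturation_vp(room_T) * (1 - room_RH / 100)
  deficit_ref <- saturation_vp(20) * 0.40
  evap_coef * wetted_area * 24 * deficit / deficit_ref
}

# Molar mass of N (kg/mol) used to convert TAN mass to molar concentration.
MOLAR_MASS_N <- 0.014

new_balance <- function() {
  list(volume_in = 0, volume_removed = 0,
       VS_in = 0, VS_removed = 0, VS_to_ch4C = 0,
       TAN_in = 0, TAN_removed = 0, TAN_to_nh3 = 0)
}

#' Simulate a housed period with a daily loop
#'
#' Runs the coupled model over `n_days` of weather: indoor climate,
#' growth and intake, excretion balances, channel loading, ammonia and
#' methane fluxes, then end-of-day removals.  With `pigs_present =
#' FALSE` (the vacancy between growing periods) excretion, floor
#' emission and enteric methane are switched off while the stored manure
#' keeps emitting.
#'
#' @param scen a [scenario()].
#' @param weather data frame (`date`, `T_out_C`, `RH_out_pct`), one row
#'   per simulated day.
#' @param states optional list of [pit_state()] per channel carried in
#'   from a previous period; defaults to each channel's
#'   `initial_height` of aged manure (VS and TAN at the long-run slurry
#'   composition of the scenario).
#' @param pigs_present logical vector (length 1 or `nrow(weather)`).
#' @param day_offset 0-based day offset into the growing period, used to
#'   keep removal schedules aligned when a period is simulated in
#'   chunks.
#' @param trajectory optional [growth_trajectory()]; fitted from the
#'   scenario endpoints when missing.
#' @param balance running mass-closure accumulator (internal).
#' @return List with `daily` (data frame, one row per day), `states`
#'   (final channel states) and `balance` (mass-closure accumulator with
#'   volume, VS and TAN inflows, removals and gas losses).
#' @export
run_days <- function(scen, weather, states = NULL, pigs_present = TRUE,
                     day_offset = 0, trajectory = NULL,
                     balance = new_balance()) {
  n <- nrow(weather)
  stopifnot(n >= 1)
  pigs_present <- rep_len(pigs_present, n)
  if (is.null(trajectory)) {
    trajectory <- growth_trajectory(scen$start_weight, scen$end_weight,
                                    scen$period_days, scen$total_feed_kg,
                                    scen$total_water_L)
  }
  if (is.null(states)) {
    states <- initial_states(scen)
    for (st in states) {  # initial inventory counts as inflow
      balance$volume_in <- balance$volume_in + st$volume
      balance$VS_in <- balance$VS_in + st$VS_d + st$VS_nd
      balance$TAN_in <- balance$TAN_in + st$TAN_mass
    }
  }
  heads <- scen$animal_places
  sfc_pH <- surface_pH(scen$bulk_pH, scen$surface_pH_offset)
  puddle_pH <- surface_pH(scen$urine_pH, scen$surface_pH_offset)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gp_day <- day_offset + i
    cl <- indoor_climate(weather$T_out_C[i], weather$RH_out_pct[i],
                         T_set_min = scen$climate$T_set_min,
                         dT_vent = scen$climate$dT_vent,
                         manure_a = scen$climate$manure_a,
                         manure_b = scen$climate$manure_b,
                         rh_factor = scen$climate$rh_factor,
                         air_velocity = scen$climate$air_velocity)
    manure_T_K <- cl$manure_T + 273.15
    room_T_K <- cl$room_T + 273.15

    overflow <- FALSE
    removed_day <- list(volume = 0, VS = 0, TAN = 0)
    exc_room <- NULL
    weight <- feed <- water <- NA_real_

    if (pigs_present[i]) {
      d <- min(gp_day, scen$period_days)  # hold intake at the curve end
      tr <- trajectory$daily[d, ]
      weight <- tr$weight_kg
      feed <- tr$feed_kg
      water <- tr$water_L
      wetted <- scen$floor_areas$solid * scen$fouling$fouled_frac_solid
      evap_room <- floor_evaporation(scen$evap_coef, wetted,
                                     cl$room_T, cl$room_RH)
      exc <- excretion_day(feed, water, max(tr$gain_kg, 0), scen$diet,
                           evap_floor = evap_room / heads,
                           urea_fraction = scen$urea_fraction)
      exc_room <- exc
      slurry_m3 <- exc$slurry_mass * heads / 1000  # slurry density 1000 kg/m^3
      VS_room <- exc$OM_exc * heads
      TAN_room <- exc$TAN_potential * heads
      balance$volume_in <- balance$volume_in + slurry_m3
      balance$VS_in <- balance$VS_in + VS_room
      balance$TAN_in <- balance$TAN_in + TAN_room
      for (ci in seq_along(states)) {
        ch <- scen$channels[[ci]]
        add <- pit_add(states[[ci]], slurry_m3 * ch$manure_share,
                       VS_d = VS_room * ch$manure_share *
                         scen$methane$VS_d_frac,
                       VS_nd = VS_room * ch$manure_share *
                         (1 - scen$methane$VS_d_frac),
                       TAN_mass = TAN_room * ch$manure_share,
                       sched = ch$sched)
        states[[ci]] <- add$state
        if (add$overflow) {
          overflow <- TRUE
          removed_day <- acc_removed(removed_day, add$removed)
          balance <- acc_balance_removed(balance, add$removed)
        }
      }
    }
    # dilution water (water channels) flows in every housed day
    if (pigs_present[i]) {
      for (ci in seq_along(states)) {
        dw <- scen$channels[[ci]]$sched$dilution_water
        if (dw > 0) {
          add <- pit_add(states[[ci]], dw / 1000,
                         sched = scen$channels[[ci]]$sched)
          states[[ci]] <- add$state
          balance$volume_in <- balance$volume_in + dw / 1000
          if (add$overflow) {
            overflow <- TRUE
            removed_day <- acc_removed(removed_day, add$removed)
            balance <- acc_balance_removed(balance, add$removed)
          }
        }
      }
    }

    # ammonia from the channels
    nh3_pit_mol_s <- 0
    for (ci in seq_along(states)) {
      st <- states[[ci]]
      if (st$volume <= 0 || st$TAN_mass <= 0) next
      conc <- st$TAN_mass / MOLAR_MASS_N / st$volume  # mol/m^3
      area <- emitting_area(st$geom, st$height)
      src <- surface_source(area, conc, sfc_pH, manure_T_K,
                            cl$air_velocity_surface, kind = "pit")
      fl <- nh3_flux(src)
      loss_N <- min(fl * 86400 * MOLAR_MASS_N, st$TAN_mass)
      fl <- loss_N / 86400 / MOLAR_MASS_N
      states[[ci]] <- pit_state(st$geom, st$volume, st$VS_d, st$VS_nd,
                                st$TAN_mass - loss_N)
      balance$TAN_to_nh3 <- balance$TAN_to_nh3 + loss_N
      nh3_pit_mol_s <- nh3_pit_mol_s + fl
    }

    # ammonia from the floor (urine puddles), only with pigs present
    nh3_floor_mol_s <- 0
    if (pigs_present[i] && !is.null(exc_room)) {
      urine_L <- scen$urine_frac_water * water
      puddle_TAN <- if (urine_L > 0)
        exc_room$TAN_potential / urine_L / MOLAR_MASS_N * 1000 else 0
      fl <- room_nh3(list(), scen$floor_areas, scen$fouling,
                     puddle_TAN, puddle_pH, cl)
      nh3_floor_mol_s <- fl$total
    }

    # methane from the channels and the animals
    ch4_pit <- 0
    for (ci in seq_along(states)) {
      res <- pit_ch4_day(states[[ci]], scen$methane, manure_T_K)
      vs_before <- states[[ci]]$VS_d
      states[[ci]] <- res$state
      balance$VS_to_ch4C <- balance$VS_to_ch4C +
        (vs_before - res$state$VS_d)
      ch4_pit <- ch4_pit + res$ch4_kg
    }
    ch4_enteric <- if (pigs_present[i])
      enteric_ch4_day(heads, scen$methane) else 0

    # end-of-day removals on the schedule
    for (ci in seq_along(states)) {
      rem <- apply_removal(states[[ci]], scen$channels[[ci]]$sched, gp_day)
      states[[ci]] <- rem$state
      if (rem$removed$volume > 0) {
        removed_day <- acc_removed(removed_day, rem$removed)
        balance <- acc_balance_removed(balance, rem$removed)
      }
    }

    nh3_pit_kg <- nh3_pit_mol_s * 0.017 * 86400
    nh3_floor_kg <- nh3_floor_mol_s * 0.017 * 86400
    rows[[i]] <- data.frame(
      date = weather$date[i], day_in_gp = gp_day,
      pigs_present = pigs_present[i],
      outside_T = cl$outside_T, room_T = cl$room_T,
      manure_T = cl$manure_T, room_RH = cl$room_RH,
      weight_kg = weight, feed_kg = feed, water_L = water,
      slurry_m3 = if (pigs_present[i] && !is.null(exc_room))
        exc_room$slurry_mass * heads / 1000 else 0,
      pit_height_m = states[[1]]$height,
      emitting_area_m2 = sum(vapply(states, function(s)
        emitting_area(s$geom, s$height), numeric(1))),
      nh3_pit_kg = nh3_pit_kg, nh3_floor_kg = nh3_floor_kg,
      nh3_total_kg = nh3_pit_kg + nh3_floor_kg,
      ch4_pit_kg = ch4_pit, ch4_enteric_kg = ch4_enteric,
      ch4_total_kg = ch4_pit + ch4_enteric,
      removed_volume_m3 = removed_day$volume,
      removed_VS_kg = removed_day$VS,
      overflow = overflow)
  }
  list(daily = do.call(rbind, rows), states = states, balance = balance)
}

acc_removed <- function(acc, removed) {
  list(volume = acc$volume + removed$volume,
       VS = acc$VS + removed$VS_d + removed$VS_nd,
       TAN = acc$TAN + removed$TAN_mass)
}

acc_balance_removed <- function(balance, removed) {
  balance$volume_removed <- balance$volume_removed + removed$volume
  balance$VS_removed <- balance$VS_removed + removed$VS_d + removed$VS_nd
  balance$TAN_removed <- balance$TAN_removed + removed$TAN_mass
  balance
}

# Aged-manure starting state per channel: initial_height of slurry at the
# scenario's long-run composition (VS and TAN per m^3 from one day of
# mid-period excretion).
initial_states <- function(scen) {
  tr <- growth_trajectory(scen$start_weight, scen$end_weight,
                          scen$period_days, scen$total_feed_kg,
                          scen$total_water_L)
  mid <- tr$daily[ceiling(scen$period_days / 2), ]
  exc <- excretion_day(mid$feed_kg, mid$water_L, max(mid$gain_kg, 0),
                       scen$diet, urea_fraction = scen$urea_fraction)
  vs_per_m3 <- exc$OM_exc / (exc$slurry_mass / 1000)    # kg VS per m^3
  tan_per_m3 <- exc$TAN_potential / (exc$slurry_mass / 1000)
  lapply(scen$channels, function(ch) {
    h0 <- if (!is.null(ch$initial_height)) ch$initial_height
          else ch$sched$residual_height
    v0 <- pit_volume(ch$geom, min(h0, ch$geom$depth))
    pit_state(ch$geom, v0,
              VS_d = v0 * vs_per_m3 * scen$methane$VS_d_frac,
              VS_nd = v0 * vs_per_m3 * (1 - scen$methane$VS_d_frac),
              TAN_mass = v0 * tan_per_m3)
  })
}

#' Simulate one growing period
#'
#' Convenience wrapper around [run_days()] for a single growing period
#' starting on the first weather row.
#'
#' @param scen a [scenario()].
#' @param weather weather data frame covering at least
#'   `scen$period_days` rows.
#' @param states optional carried-in channel states.
#' @return See [run_days()].
#' @export
#' @examples
#' scen <- scenario_preset("LS")
#' w <- weather_fixture(1, scen$period_days)
#' out <- run_growing_period(scen, w)
#' tail(out$daily[, c("date", "ch4_total_kg", "nh3_total_kg")])
run_growing_period <- function(scen, weather, states = NULL) {
  if (nrow(weather) < scen$period_days) {
    stop("weather covers ", nrow(weather), " days; growing period needs ",
         scen$period_days)
  }
  run_days(scen, weather[seq_len(scen$period_days), ], states = states)
}

#' Simulate a full year of growing periods
#'
#' Walks the weather series, starting a growing period at each calendar
#' date in `scen$gp_starts`.  A period ends after `scen$period_days` days
#' or `gp_gap_days` before the next start, whichever comes first; pit
#' state is carried across the vacancy days, during which the stored
#' manure keeps emitting but there is no excretion and no enteric
#' methane.
#'
#' @param scen a [scenario()].
#' @param weather weather data frame (typically 365 rows beginning on a
#'   growing-period start date).
#' @return List with `daily` (one row per weather day, plus a `gp`
#'   column), `states`, `balance`, and `annual` (see [annual_summary()]).
#' @export
run_year <- function(scen, weather) {
  n <- nrow(weather)
  md <- format(weather$date, "%m-%d")
  starts <- which(md %in% scen$gp_starts)
  if (length(starts) == 0) {
    stop("no growing-period start dates (", paste(scen$gp_starts,
         collapse = ", "), ") found in the weather series")
  }
  # period length per start: capped by the next start minus the gap
  ends <- integer(length(starts))
  for (k in seq_along(starts)) {
    nxt <- if (k < length(starts)) starts[k + 1] else n + scen$gp_gap_days + 1
    ends[k] <- min(starts[k] + scen$period_days - 1,
                   nxt - scen$gp_gap_days - 1, n)
  }
  states <- NULL
  balance <- new_balance()
  pieces <- list()
  gp_id <- integer(0)
  cursor <- 1
  for (k in seq_along(starts)) {
    if (starts[k] > cursor) {          # vacancy before this period
      idx <- cursor:(starts[k] - 1)
      res <- run_days(scen, weather[idx, , drop = FALSE], states = states,
                      pigs_present = FALSE, balance = balance)
      states <- res$states; balance <- res$balance
      pieces <- c(pieces, list(res$daily))
      gp_id <- c(gp_id, rep(0L, length(idx)))
    }
    idx <- starts[k]:ends[k]
    res <- run_days(scen, weather[idx, , drop = FALSE], states = states,
                    pigs_present = TRUE, balance = balance)
    states <- res$states; balance <- res$balance
    pieces <- c(pieces, list(res$daily))
    gp_id <- c(gp_id, rep(k, length(idx)))
    cursor <- ends[k] + 1
  }
  if (cursor <= n) {                   # trailing vacancy
    idx <- cursor:n
    res <- run_days(scen, weather[idx, , drop = FALSE], states = states,
                    pigs_present = FALSE, balance = balance)
    states <- res$states; balance <- res$balance
    pieces <- c(pieces, list(res$daily))
    gp_id <- c(gp_id, rep(0L, length(idx)))
  }
  daily <- do.call(rbind, pieces)
  daily$gp <- gp_id
  daily <- daily[order(daily$date), ]
  rownames(daily) <- NULL
  list(daily = daily, states = states, balance = balance,
       annual = annual_summary(daily, scen))
}

#' Annualize a daily emission series per pig place
#'
#' Mean daily room emission scaled to a year, divided by the number of
#' animal places, and reduced by the vacancy factor.
#'
#' @param daily_kg numeric vector of daily room emissions, kg/d.
#' @param animal_places number of pig places.
#' @param vacancy vacancy factor (default 0.03).
#' @return kg per year per pig place.
#' @export
#' @examples
#' annualize(rep(0.1, 90), 50, vacancy = 0)  # 0.73
annualize <- function(daily_kg, animal_places, vacancy = 0.03) {
  if (length(daily_kg) == 0) stop("empty daily series")
  stopifnot(animal_places > 0, vacancy >= 0, vacancy < 1)
  mean(daily_kg) * 365 / animal_places * (1 - vacancy)
}

#' Annual per-pig-place summary of a simulated year
#'
#' @param daily daily output of [run_year()] or [run_days()].
#' @param scen the [scenario()] that produced it.
#' @return One-row data frame with annualized CH4 and NH3 (total and
#'   itemized), the pit share of NH3, and mean temperatures.
#' @export
annual_summary <- function(daily, scen) {
  a <- function(x) annualize(x, scen$animal_places, scen$vacancy)
  nh3_pit <- a(daily$nh3_pit_kg)
  nh3_floor <- a(daily$nh3_floor_kg)
  data.frame(
    scenario = scen$name,
    ch4_kg_yr_place = a(daily$ch4_total_kg),
    ch4_pit_kg_yr_place = a(daily$ch4_pit_kg),
    ch4_enteric_kg_yr_place = a(daily$ch4_enteric_kg),
    nh3_kg_yr_place = nh3_pit + nh3_floor,
    nh3_pit_kg_yr_place = nh3_pit,
    nh3_floor_kg_yr_place = nh3_floor,
    nh3_pit_share_pct = 100 * nh3_pit / (nh3_pit + nh3_floor),
    mean_room_T = mean(daily$room_T),
    mean_manure_T = mean(daily$manure_T))
}
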