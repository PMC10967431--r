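#' Scenario configuration
#'
#' Full description of one fattening-pig room and its manure-management
#' system: herd and growth endpoints, diet, floor layout, manure channels
#' with their removal schedules, indoor-climate coefficients, gas
#' parameters and the growing-period calendar.
#'
#' @param name scenario label.
#' @param animal_places number of pig places (pigs per place = 1).
#' @param start_weight,end_weight kg at placement and slaughter.
#' @param period_days length of one growing period, days.
#' @param total_feed_kg total feed intake per pig over the period, kg.
#' @param total_water_L total drinking water per pig over the period, L.
#' @param diet a [diet_spec()].
#' @param floor_areas named list `solid`, `slatted_front`, `slatted_back`
#'   (m^2 for the whole room).
#' @param channels list of channels, each a list with elements `geom`
#'   ([pit_geometry()]), `sched` ([removal_schedule()]), `manure_share`
#'   (fraction of excreted slurry routed to the channel; shares must sum
#'   to 1), and optional `initial_height` (m of aged manure present at
#'   the start of the simulation; defaults to the residual height).
#' @param fouling a [floor_fouling()].
#' @param bulk_pH measured bulk slurry pH (model input, not predicted).
#' @param urine_pH measured urine pH for floor puddles.
#' @param surface_pH_offset surface-minus-bulk pH offset (default 0.5).
#' @param climate named list of [indoor_climate()] coefficients
#'   (`T_set_min`, `dT_vent`, `manure_a`, `manure_b`, `rh_factor`,
#'   `air_velocity`).
#' @param methane a [methane_params()].
#' @param urea_fraction urea share of urinary N (default 0.75).
#' @param urine_frac_water share of drinking water excreted as urine,
#'   used for the puddle TAN concentration (default 0.55).
#' @param evap_coef floor evaporation coefficient at 20 C / 60% RH,
#'   L/m^2/h (default 0.05).
#' @param vacancy vacancy factor for annualization (default 0.03).
#' @param gp_starts character vector of `"MM-DD"` growing-period start
#'   dates.
#' @param gp_gap_days minimum empty days between consecutive growing
#'   periods (default 3).
#' @return Object of class `pig_scenario`.
#' @seealso [scenario_preset()] for the shipped room presets.
#' @export
scenario <- function(name, animal_places, start_weight, end_weight,
                     period_days, total_feed_kg, total_water_L,
                     diet = diet_spec(), floor_areas, channels,
                     fouling = floor_fouling(), bulk_pH = 7.0,
                     urine_pH = 7.0, surface_pH_offset = 0.5,
                     climate = list(T_set_min = 20, dT_vent = 3,
                                    manure_a = 0, manure_b = 0.88,
                                    rh_factor = 0.85, air_velocity = 0.15),
                     methane = methane_params(), urea_fraction = 0.75,
                     urine_frac_water = 0.55, evap_coef = 0.05,
                     vacancy = 0.03,
                     gp_starts = c("10-08", "01-21", "04-27", "07-27"),
                     gp_gap_days = 3) {
  stopifnot(animal_places > 0, start_weight > 0,
            end_weight > start_weight, period_days > 0,
            total_feed_kg > 0, total_water_L > 0,
            inherits(diet, "diet_spec"), inherits(fouling, "floor_fouling"),
            inherits(methane, "methane_params"),
            vacancy >= 0, vacancy < 1)
  need <- c("solid", "slatted_front", "slatted_back")
  if (!all(need %in% names(floor_areas))) {
    stop("floor_areas needs elements: ", paste(need, collapse = ", "))
  }
  shares <- vapply(channels, function(ch) ch$manure_share, numeric(1))
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("channel manure shares must sum to 1 (got ", sum(shares), ")")
  }
  for (ch in channels) {
    stopifnot(inherits(ch$geom, "pit_geometry"),
              inherits(ch$sched, "removal_schedule"))
  }
  structure(list(name = name, animal_places = animal_places,
                 start_weight = start_weight, end_weight = end_weight,
                 period_days = period_days, total_feed_kg = total_feed_kg,
                 total_water_L = total_water_L, diet = diet,
                 floor_areas = floor_areas, channels = channels,
                 fouling = fouling, bulk_pH = bulk_pH, urine_pH = urine_pH,
                 surface_pH_offset = surface_pH_offset, climate = climate,
                 methane = methane, urea_fraction = urea_fraction,
                 urine_frac_water = urine_frac_water,
                 evap_coef = evap_coef, vacancy = vacancy,
                 gp_starts = gp_starts, gp_gap_days = gp_gap_days),
            class = "pig_scenario")
}

#' Shipped room presets: long storage (LS) and short storage (SS)
#'
#' Two commercial fattening-pig rooms:
#'
#' * **LS** — long-term storage: 54 places, growth 23.6--115.6 kg, six
#'   pens of 5.10 x 1.88 m, 60% slatted / 40% solid floor, one deep pit
#'   (1.20 m, straight walls) under the slatted floor, emptied about
#'   every 45 days.
#' * **SS** — short-term storage: 78 places, growth 22.6--114.0 kg, six
#'   pens of 5.22 x 2.59 m, 38% slatted / 62% solid floor, a shallow
#'   (0.50 m) back manure channel with 45-degree sloped walls flushed
#'   daily, and a front water channel receiving dilution water, emptied
#'   once per growing period (or when full).
#'
#' Feed and water totals per pig (not part of the room description) use
#' typical Dutch fattening values: about 240 kg feed and 560 L water over
#' a 90-day growing period.
#'
#' @param which `"LS"` or `"SS"`.
#' @param period_days growing-period length, days (default 90).
#' @param dilution_water L/d added to the SS front water channel
#'   (default 200).
#' @return A [scenario()].
#' @export
#' @examples
#' ls <- scenario_preset("LS")
#' ss <- scenario_preset("SS")
scenario_preset <- function(which = c("LS", "SS"), period_days = 90,
                            dilution_water = 200) {
  which <- match.arg(which)
  if (which == "LS") {
    pen_area <- 6 * 5.10 * 1.88            # 57.5 m^2
    slatted <- pen_area * 0.60
    scenario(
      name = "LS", animal_places = 54,
      start_weight = 23.6, end_weight = 115.6,
      period_days = period_days,
      total_feed_kg = 240, total_water_L = 560,
      floor_areas = list(solid = pen_area * 0.40,
                         slatted_front = slatted / 2,
                         slatted_back = slatted / 2),
      channels = list(list(
        geom = pit_geometry(length = 6 * 1.88, top_width = 0.60 * 5.10,
                            depth = 1.20, wall_slope_deg = 90,
                            n_sloped_walls = 0),
        sched = removal_schedule(interval_days = 45,
                                 residual_height = 0.05),
        manure_share = 1)))
  } else {
    pen_area <- 6 * 5.22 * 2.59            # 81.1 m^2
    slatted <- pen_area * 0.38
    ch_len <- 6 * 2.59                     # channels run across the pens
    scenario(
      name = "SS", animal_places = 78,
      start_weight = 22.6, end_weight = 114.0,
      period_days = period_days,
      total_feed_kg = 240, total_water_L = 560,
      floor_areas = list(solid = pen_area * 0.62,
                         slatted_front = slatted / 2,
                         slatted_back = slatted / 2),
      channels = list(
        list(  # back manure channel, flushed daily
          geom = pit_geometry(length = ch_len, top_width = 1.18,
                              depth = 0.50, wall_slope_deg = 45,
                              n_sloped_walls = 2),
          sched = removal_schedule(interval_days = 1,
                                   residual_height = 0.02),
          manure_share = 0.6),
        list(  # front water channel, diluted, emptied once per GP
          geom = pit_geometry(length = ch_len, top_width = 0.80,
                              depth = 0.50, wall_slope_deg = 45,
                              n_sloped_walls = 1),
          sched = removal_schedule(interval_days = period_days,
                                   residual_height = 0,
                                   dilution_water = dilution_water),
          manure_share = 0.4)))
  }
}

#' Read a scenario from a YAML file
#'
#' The file mirrors the arguments of [scenario()]; `diet`, `fouling`,
#' `methane` and per-channel `geom`/`sched` blocks are given as key-value
#' maps passed to the respective constructors.  Alternatively a single
#' key `preset: LS` (or `SS`) loads a shipped preset, with any further
#' keys overriding [scenario_preset()] arguments.
#'
#' @param path YAML file path.
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    args <- cfg[setdiff(names(cfg), "preset")]
    return(do.call(scenario_preset, c(list(which = cfg$preset), args)))
  }
  if (!is.null(cfg$diet)) cfg$diet <- do.call(diet_spec, cfg$diet)
  if (!is.null(cfg$fouling)) cfg$fouling <- do.call(floor_fouling, cfg$fouling)
  if (!is.null(cfg$methane)) cfg$methane <- do.call(methane_params, cfg$methane)
  if (!is.null(cfg$channels)) {
    cfg$channels <- lapply(cfg$channels, function(ch) {
      ch$geom <- do.call(pit_geometry, ch$geom)
      ch$sched <- do.call(removal_schedule, ch$sched)
      ch
    })
  }
  do.call(scenario, cfg)
}

#' @export
print.pig_scenario <- function(x, ...) {
  cat("<pig_scenario>", x$name, "\n")
  cat("  places:", x$animal_places,
      " growth:", x$start_weight, "-", x$end_weight, "kg in",
      x$period_days, "d\n")
  cat("  channels:", length(x$channels),
      " removal interval(s):",
      paste(vapply(x$channels, function(ch) ch$sched$interval_days,
                   integer(1)), collapse = "/"), "d\n")
  invisible(x)
}
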