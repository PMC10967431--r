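# Shared fixtures: tiny deterministic inputs built in code.

# Independent forward evaluation of the growth curve, written out long-hand
# so it does not share code with gompertz_value().
oracle_curve <- function(A, M, B, tstar, t) {
  A + M * exp(-exp(-B * (t - tstar)))
}

# Bisection on the forward trapezoid volume formula; the oracle for
# height_from_volume().
oracle_height <- function(length, top_width, depth, slope_deg, n_sloped,
                          volume, tol = 1e-12) {
  inv_tan <- if (slope_deg == 90) 0 else 1 / tan(slope_deg * pi / 180)
  w_b <- top_width - n_sloped * depth * inv_tan
  vol_at <- function(h) length * (w_b * h + n_sloped * inv_tan * h^2 / 2)
  lo <- 0; hi <- depth
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (vol_at(mid) < volume) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# A compact two-channel scenario that runs fast in driver tests.
tiny_scenario <- function(name = "tiny", interval = 10) {
  scenario(
    name = name, animal_places = 10,
    start_weight = 25, end_weight = 55, period_days = 30,
    total_feed_kg = 60, total_water_L = 140,
    floor_areas = list(solid = 8, slatted_front = 5, slatted_back = 5),
    channels = list(list(
      geom = pit_geometry(4, 2, 1, 90, 0),
      sched = removal_schedule(interval, residual_height = 0.02),
      manure_share = 1)))
}
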