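test_that("shipped presets carry the room descriptions", {
  ls <- scenario_preset("LS")
  expect_equal(ls$animal_places, 54)
  expect_equal(c(ls$start_weight, ls$end_weight), c(23.6, 115.6))
  expect_equal(ls$channels[[1]]$geom$depth, 1.20)
  expect_equal(ls$channels[[1]]$geom$wall_slope_deg, 90)
  expect_equal(ls$channels[[1]]$sched$interval_days, 45L)
  # floor split 60/40 slatted/solid of six 5.10 x 1.88 pens
  pen <- 6 * 5.10 * 1.88
  expect_equal(ls$floor_areas$solid, pen * 0.40)
  expect_equal(ls$floor_areas$slatted_front + ls$floor_areas$slatted_back,
               pen * 0.60)

  ss <- scenario_preset("SS")
  expect_equal(ss$animal_places, 78)
  expect_equal(c(ss$start_weight, ss$end_weight), c(22.6, 114.0))
  expect_length(ss$channels, 2)
  expect_equal(ss$channels[[1]]$sched$interval_days, 1L)
  expect_equal(ss$channels[[1]]$geom$wall_slope_deg, 45)
  expect_equal(ss$channels[[1]]$geom$depth, 0.50)
  expect_gt(ss$channels[[2]]$sched$dilution_water, 0)
  shares <- vapply(ss$channels, function(ch) ch$manure_share, numeric(1))
  expect_equal(sum(shares), 1)
})

test_that("scenario constructor validates its inputs", {
  ok <- tiny_scenario()
  expect_s3_class(ok, "pig_scenario")
  bad <- function(share) {
    scenario(name = "x", animal_places = 10, start_weight = 25,
             end_weight = 55, period_days = 30, total_feed_kg = 60,
             total_water_L = 140,
             floor_areas = list(solid = 8, slatted_front = 5,
                                slatted_back = 5),
             channels = list(list(geom = pit_geometry(4, 2, 1),
                                  sched = removal_schedule(10),
                                  manure_share = share)))
  }
  expect_error(bad(0.8), "sum to 1")
  expect_error(pit_geometry(4, 1, 1.5, 45, 2), "bottom width")
})

test_that("YAML scenarios round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: custom",
    "animal_places: 20",
    "start_weight: 24",
    "end_weight: 112",
    "period_days: 90",
    "total_feed_kg: 235",
    "total_water_L: 540",
    "bulk_pH: 7.2",
    "floor_areas: {solid: 12, slatted_front: 9, slatted_back: 9}",
    "channels:",
    "  - geom: {length: 8, top_width: 2.5, depth: 1.0, wall_slope_deg: 90}",
    "    sched: {interval_days: 30, residual_height: 0.05}",
    "    manure_share: 1"), path)
  scen <- read_scenario(path)
  expect_s3_class(scen, "pig_scenario")
  expect_equal(scen$animal_places, 20)
  expect_equal(scen$bulk_pH, 7.2)
  expect_equal(scen$channels[[1]]$sched$interval_days, 30L)

  preset_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preset: SS", "period_days: 85"), preset_path)
  ss <- read_scenario(preset_path)
  expect_equal(ss$name, "SS")
  expect_equal(ss$period_days, 85)
})

test_that("the command-line interface simulates, fixtures and validates", {
  out_dir <- withr::local_tempdir()
  wpath <- file.path(out_dir, "weather.csv")
  expect_equal(suppressMessages(
    pigemit_cli(c("fixtures", "weather", "--seed", "5",
                  "--days", "95", "--out", wpath))), 0L)
  w <- read_weather(wpath)
  expect_equal(nrow(w), 95)
  expect_equal(w$T_out_C, weather_fixture(5, 95)$T_out_C,
               tolerance = 1e-12)  # CSV round trip

  # a one-GP simulation of the long-storage preset
  spath <- file.path(out_dir, "scen.yaml")
  writeLines(c("preset: LS", "period_days: 90"), spath)
  expect_equal(suppressMessages(
    pigemit_cli(c("simulate", "--scenario", spath, "--weather", wpath,
                  "--out", out_dir, "--gp"))), 0L)
  daily <- utils::read.csv(file.path(out_dir, "daily.csv"))
  expect_equal(nrow(daily), 90)
  summ <- jsonlite::read_json(file.path(out_dir, "summary.json"))
  expect_true(summ$ch4_kg_yr_place > 0)

  # validate against a synthetic measured series
  meas <- data.frame(date = daily$date[c(10, 20, 28)], gas = "NH3",
                     C_out_ppm = c(8, 9, 10), C_in_ppm = 0.5,
                     vent_m3_h_per_place = 55)
  mpath <- file.path(out_dir, "meas.csv")
  utils::write.csv(meas, mpath, row.names = FALSE)
  expect_output(
    expect_equal(pigemit_cli(c("validate", "--sim",
                               file.path(out_dir, "daily.csv"),
                               "--meas", mpath, "--gas", "NH3",
                               "--places", "54")), 0L),
    "MAE")
  # unknown subcommands fail
  expect_equal(suppressMessages(pigemit_cli("frobnicate")), 1L)
})
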