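test_that("height and volume invert each other for simple shapes", {
  # straight walls: rectangular division
  g <- pit_geometry(5.10, 1.88, 1.20, 90, 0)
  expect_equal(height_from_volume(g, 4.7940), 0.5)
  expect_equal(height_from_volume(g, 0), 0)
  # sloped-wall room dimensions: bisection oracle on the forward formula
  gs <- pit_geometry(5.22, 2.59, 0.5, 45, 2)
  h <- height_from_volume(gs, 1.0)
  expect_equal(h, oracle_height(5.22, 2.59, 0.5, 45, 2, 1.0),
               tolerance = 1e-9)
  expect_equal(pit_volume(gs, h), 1.0, tolerance = 1e-12)
})

test_that("inversion matches the bisection oracle on random geometries", {
  set.seed(42)
  for (i in 1:1000) {
    slope <- sample(c(30, 45, 60, 75, 90), 1)
    n <- if (slope == 90) 0 else sample(0:2, 1)
    depth <- runif(1, 0.3, 1.5)
    inv_tan <- if (slope == 90) 0 else 1 / tan(slope * pi / 180)
    top <- n * depth * inv_tan + runif(1, 0.3, 3)  # keep bottom positive
    len <- runif(1, 2, 16)
    g <- pit_geometry(len, top, depth, slope, n)
    v <- runif(1, 0, g$capacity)
    expect_equal(height_from_volume(g, v),
                 oracle_height(len, top, depth, slope, n, v),
                 tolerance = 1e-9)
  }
})

test_that("overflow volume is rejected", {
  g <- pit_geometry(5, 2, 1, 90, 0)
  expect_error(height_from_volume(g, 10.1), "overflow")
})

test_that("emitting area follows the pit shape", {
  g <- pit_geometry(5.10, 1.88, 1.20, 90, 0)
  # straight walls: constant plan area at any fill
  expect_equal(emitting_area(g, 0.1), 5.10 * 1.88)
  expect_equal(emitting_area(g, 1.2), 5.10 * 1.88)
  gs <- pit_geometry(5.22, 2.59, 0.5, 45, 2)
  # full sloped pit reaches the top plan area
  expect_equal(emitting_area(gs, 0.5), 5.22 * 2.59)
  # mid-fill from the forward formula: w_b + 2 h / tan(45)
  expect_equal(emitting_area(gs, 0.25), 5.22 * (1.59 + 2 * 0.25))
  # non-decreasing in height
  a <- vapply(seq(0, 0.5, by = 0.05), function(h) emitting_area(gs, h),
              numeric(1))
  expect_true(all(diff(a) >= 0))
  # empty pit: wetted bottom by default, nothing when disabled
  expect_equal(emitting_area(gs, 0), 5.22 * 1.59)
  expect_equal(emitting_area(gs, 0, empty_emits = FALSE), 0)
})

test_that("removal conserves volume, VS and TAN", {
  g <- pit_geometry(4, 2, 1, 90, 0)
  st <- pit_state(g, 5, VS_d = 80, VS_nd = 20, TAN_mass = 3)
  sched <- removal_schedule(45, residual_height = 0.05)
  # off-day: unchanged
  off <- apply_removal(st, sched, 10)
  expect_identical(off$state$volume, 5)
  expect_equal(off$removed$volume, 0)
  # removal day: removed + remaining equals the pre-removal stock exactly
  on <- apply_removal(st, sched, 45)
  expect_equal(on$state$volume + on$removed$volume, 5)
  expect_equal(on$state$VS_d + on$removed$VS_d, 80)
  expect_equal(on$state$VS_nd + on$removed$VS_nd, 20)
  expect_equal(on$state$TAN_mass + on$removed$TAN_mass, 3)
  expect_equal(on$state$height, 0.05)
  # zero residual leaves nothing behind
  z <- apply_removal(st, removal_schedule(45, 0), 90)
  expect_equal(z$state$volume, 0)
  expect_equal(z$state$VS_d + z$state$VS_nd + z$state$TAN_mass, 0)
})

test_that("loading accumulates additively and handles overflow", {
  g <- pit_geometry(4, 2, 1, 90, 0)
  sched <- removal_schedule(1, 0)
  st <- pit_state(g)
  add <- pit_add(st, 2, VS_d = 10, VS_nd = 2, TAN_mass = 0.5, sched = sched)
  expect_equal(add$state$volume, 2)
  expect_false(add$overflow)
  # inflow beyond capacity triggers an emptying first
  big <- pit_add(add$state, 7, sched = sched)
  expect_true(big$overflow)
  expect_equal(big$removed$volume, 2)
  expect_equal(big$state$volume, 7)
  # without a schedule the overflow is an error
  expect_error(pit_add(pit_state(g, 8), 3), "overflow")
})

test_that("indoor climate follows the set point and tracks outside above it", {
  expect_equal(indoor_climate(25, 70)$room_T, 28)
  expect_equal(indoor_climate(5, 70)$room_T, 20)
  expect_equal(indoor_climate(25, 70)$manure_T, 0.88 * 28)
  # annual fixture series: mean room temperature in the low twenties
  w <- weather_fixture(5, 365)
  room <- vapply(seq_len(365), function(i)
    indoor_climate(w$T_out_C[i], w$RH_out_pct[i])$room_T, numeric(1))
  expect_gt(mean(room), 20)
  expect_lt(mean(room), 25)
})
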