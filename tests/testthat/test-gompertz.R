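test_that("curve value matches direct formula evaluation and limits", {
  p <- gompertz_params(0, 164.2, 0.0146, 110.4)
  # inflection: inner exponent vanishes, value = A + M/e
  expect_equal(gompertz_value(p, 110.4), 164.2 / exp(1))
  # independent long-hand evaluation at t = 60
  expect_equal(gompertz_value(p, 60), oracle_curve(0, 164.2, 0.0146, 110.4, 60))
  # far-past limit collapses to the offset
  pf <- gompertz_params(-41.9, 608, 0.0111, 154.7)
  expect_equal(gompertz_value(pf, -1e6), -41.9)
  # inflection identity holds for arbitrary parameter sets
  set.seed(11)
  for (i in 1:25) {
    q <- gompertz_params(runif(1, -200, 50), runif(1, 50, 2000),
                         runif(1, 0.005, 0.05), runif(1, 50, 250))
    expect_equal(gompertz_value(q, q$t_star),
                 q$offset_A + q$asymptote_M / exp(1))
  }
})

test_that("cumulative curve is strictly increasing for positive rate", {
  p <- gompertz_defaults("water")
  t <- seq(0, 400, by = 1)
  expect_true(all(diff(gompertz_value(p, t)) > 0))
})

test_that("endpoint fit is self-consistent and matches a grid search", {
  d <- gompertz_defaults("weight")
  # evaluating the default curve then refitting recovers it
  s <- gompertz_value(d, 70); e <- gompertz_value(d, 166)
  fit <- fit_endpoints(d, s, e, 96)
  expect_equal(fit$params$asymptote_M, 164.2, tolerance = 1e-6)
  expect_equal(fit$age_at_entry, 70, tolerance = 1e-6)

  # growth range of the long-storage room: brute-force 2-D grid oracle
  fit2 <- fit_endpoints(d, 23.6, 115.6, 96)
  grid_M <- seq(115.7, 1156, length.out = 4000)
  best <- Inf; best_M <- NA; best_t0 <- NA
  for (M in grid_M) {
    u <- 23.6 / M
    t0 <- d$t_star - log(-log(u)) / d$rate_B
    err <- abs(oracle_curve(0, M, d$rate_B, d$t_star, t0 + 96) - 115.6)
    if (err < best) { best <- err; best_M <- M; best_t0 <- t0 }
  }
  expect_equal(fit2$params$asymptote_M, best_M, tolerance = 5e-3)
  expect_equal(fit2$age_at_entry, best_t0, tolerance = 5e-3)
  # both endpoints reproduced
  expect_equal(gompertz_value(fit2$params, fit2$age_at_entry), 23.6,
               tolerance = 1e-6)
  expect_equal(gompertz_value(fit2$params, fit2$age_at_entry + 96), 115.6,
               tolerance = 1e-6)
})

test_that("unreachable end weight reports a bracketing failure", {
  # no admissible asymptote lets a 23.6 kg pig hit 400 kg within 20 days
  expect_error(fit_endpoints(gompertz_defaults("weight"), 23.6, 400, 20),
               "no asymptote")
})

test_that("endpoint fit round-trips random asymptote/entry-age pairs", {
  d <- gompertz_defaults("weight")
  set.seed(7)
  for (i in 1:30) {
    M <- runif(1, 130, 400); t0 <- runif(1, 40, 100); L <- 90
    p <- gompertz_params(0, M, d$rate_B, d$t_star)
    fit <- fit_endpoints(d, gompertz_value(p, t0), gompertz_value(p, t0 + L), L)
    expect_equal(fit$params$asymptote_M, M, tolerance = 1e-4)
    expect_equal(fit$age_at_entry, t0, tolerance = 1e-4)
  }
})

test_that("daily series telescopes and matches direct evaluation", {
  pf <- gompertz_params(-41.9, 608, 0.0111, 154.7)
  s <- daily_series(pf, 70, 96, clamp_zero = FALSE)
  expect_length(s, 96)
  expect_equal(sum(s), gompertz_value(pf, 166) - gompertz_value(pf, 70))
  # day-30 value from an independent long-hand difference
  expect_equal(s[30],
               oracle_curve(-41.9, 608, 0.0111, 154.7, 100) -
               oracle_curve(-41.9, 608, 0.0111, 154.7, 99))
  # near-flat curve gives near-zero daily values
  flat <- gompertz_params(0, 100, 1e-9, 100)
  expect_true(all(abs(daily_series(flat, 0, 10)) < 1e-6))
})

test_that("trajectory honours totals and monotonicity invariants", {
  tr <- growth_trajectory(23.6, 115.6, 96, 240, 560)
  expect_true(all(diff(tr$daily$weight_kg) > 0))
  expect_true(all(tr$daily$feed_kg >= 0))
  expect_true(all(tr$daily$water_L >= 0))
  expect_equal(sum(tr$daily$feed_kg), 240, tolerance = 1e-6)
  expect_equal(sum(tr$daily$water_L), 560, tolerance = 1e-6)
  expect_equal(tr$daily$weight_kg[96], 115.6, tolerance = 1e-6)
})
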