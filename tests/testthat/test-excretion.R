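test_that("nitrogen balance closes and matches a hand-computed case", {
  d <- diet_spec(crude_protein_frac = 0.165, digestibility_CP = 0.80)
  nb <- nitrogen_balance(2.2, d, 0.85, body_protein_per_gain = 0.16)
  # hand balance: intake 2.2*0.165/6.25, faecal 20% of it,
  # retention 0.85*0.16*0.16 (below digestible N), urinary the residual
  expect_equal(nb$N_intake, 0.058080)
  expect_equal(nb$N_faecal, 0.0116160)
  expect_equal(nb$N_retained, 0.021760)
  expect_equal(nb$N_urinary, 0.0247040)

  # zero feed gives all zeros
  z <- nitrogen_balance(0, d, 0)
  expect_equal(unlist(z), c(N_intake = 0, N_faecal = 0,
                            N_retained = 0, N_urinary = 0))

  # conservation for random inputs away from the clamp
  set.seed(3)
  for (i in 1:50) {
    feed <- runif(1, 1, 3.5); gain <- runif(1, 0, 0.6)
    nb <- nitrogen_balance(feed, d, gain)
    expect_equal(nb$N_intake,
                 nb$N_faecal + nb$N_retained + nb$N_urinary)
    expect_true(nb$N_urinary >= 0)
  }
})

test_that("excess retention demand is capped and the clamp warns", {
  d <- diet_spec()
  # huge gain: retention capped at digestible N, urinary residual 0
  nb <- nitrogen_balance(1, d, 50)
  expect_equal(nb$N_retained, nb$N_intake - nb$N_faecal)
  expect_equal(nb$N_urinary, 0)
})

test_that("solids balance re-sums its components", {
  d <- diet_spec(dry_matter_frac = 0.88, ash_frac = 0.055,
                 digestibility_OM = 0.85, ash_retention_frac = 0.35,
                 urinary_organic_frac = 0.85)
  sb <- solids_balance(2.2, d, 0.0247040)
  # independent arithmetic
  faecal_OM <- 0.15 * 2.2 * (0.88 - 0.055)
  ash <- 0.65 * 2.2 * 0.055
  us <- 2.14 * 0.0247040
  expect_equal(sb$faecal_OM, faecal_OM)
  expect_equal(sb$ash_exc, ash)
  expect_equal(sb$urinary_solids, us)
  expect_equal(sb$DM_exc, faecal_OM + ash + us)
  expect_equal(sb$OM_exc, faecal_OM + 0.85 * us)

  # perfect digestion, full ash retention, no urinary N: nothing excreted
  d0 <- diet_spec(digestibility_OM = 1, ash_retention_frac = 1)
  expect_equal(solids_balance(2.2, d0, 0)$DM_exc, 0)

  # DM_exc strictly decreasing in OM digestibility
  dm <- vapply(seq(0.5, 0.95, by = 0.05), function(dig) {
    solids_balance(2.2, diet_spec(digestibility_OM = dig), 0.02)$DM_exc
  }, numeric(1))
  expect_true(all(diff(dm) < 0))
})

test_that("water balance matches the independent balance and is linear", {
  d <- diet_spec()
  # nominal case, long-hand
  w <- water_balance(5.5, 2.2, d, 0.85)
  expect_equal(w, 5.5 + 2.2 * 0.12 + 0.4 * 2.2 * 0.88 * 0.85 -
                  0.70 * 0.85 - 0.25 * 5.5)
  # all inflows zero
  expect_equal(water_balance(0, 0, d, 0), 0)
  # extra drinking water flows through at (1 - respiratory_frac)
  expect_equal(water_balance(6.5, 2.2, d, 0.85) - w, 1 * (1 - 0.25))
  # deficit clamps at zero with a warning
  expect_warning(w0 <- water_balance(0.1, 0, d, 5), "clamped")
  expect_equal(w0, 0)
})

test_that("TAN precursor is the urea share of urinary N", {
  expect_equal(tan_potential(0.030, 0), 0)
  expect_equal(tan_potential(0.030, 1), 0.030)
  expect_equal(tan_potential(0.030, 0.75), 0.0225)
})

test_that("excretion day assembles a consistent slurry stream", {
  ex <- excretion_day(2.2, 5.5, 0.85, diet_spec())
  expect_s3_class(ex, "excretion_day")
  expect_equal(ex$N_total, ex$N_urinary + ex$N_faecal)
  expect_true(ex$TAN_potential <= ex$N_urinary)
  expect_true(ex$DM_exc >= 0)
  expect_equal(ex$slurry_mass,
               ex$DM_exc + ex$water_to_pit - ex$gas_correction)
  expect_equal(ex$gas_correction,
               0.05 * ex$OM_exc + 0.733 * ex$TAN_potential)
  # realistic slurry composition: volatile solids around 5-10% of mass
  expect_gt(ex$OM_exc / ex$slurry_mass, 0.03)
  expect_lt(ex$OM_exc / ex$slurry_mass, 0.12)
})

test_that("diet constructor rejects inconsistent fractions", {
  expect_error(diet_spec(dry_matter_frac = 0.2, crude_protein_frac = 0.165,
                         ash_frac = 0.055), "must not exceed")
  expect_error(diet_spec(digestibility_OM = 1.2), "\\[0, 1\\]")
})
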