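# Synthetic-data generator: temperature regimes, cohorts, traces.

test_that("temperature series reproduces the configured diel cycle", {
  flat <- gen_temperature_series(20, 0, n_days = 3, noise_sd = 0)
  expect_true(all(flat$temp_c == 20))
  expect_equal(nrow(flat), 72)

  ts <- gen_temperature_series(20.5, 3.5, n_days = 4, noise_sd = 0)
  day <- as.Date(ts$timestamp, tz = "UTC")
  expect_equal(as.numeric(tapply(ts$temp_c, day, min)), rep(17, 4))
  expect_equal(as.numeric(tapply(ts$temp_c, day, max)), rep(24, 4))
  # peak late afternoon
  hr <- as.integer(format(ts$timestamp[which.max(ts$temp_c)], "%H"))
  expect_equal(hr, 16)
})

test_that("temperature noise averages out at the configured level", {
  ts <- gen_temperature_series(20, 2, n_days = 30, noise_sd = 0.1, seed = 1)
  expect_lt(abs(mean(ts$temp_c) - 20), 0.1)
})

test_that("temperature series rejects invalid arguments", {
  expect_error(gen_temperature_series(20, 2, n_days = 0), "n_days")
  expect_error(gen_temperature_series(20, -1, n_days = 1), "amplitude")
})

test_that("cohort draws follow the stated distributions", {
  # degenerate: all sds zero -> parameters equal the means
  co <- fixed_fish(rmr_ref = 1.8, k = 0.09, mmr = 12.5)
  expect_equal(co$mass_kg, 0.025)
  expect_equal(co$rmr_ref, 1.8)
  expect_equal(co$k, 0.09)
  expect_equal(co$mmr, 12.5)

  big <- gen_cohort(1000, mass_logmean = log(0.025), seed = 7)
  expect_lt(abs(stats::median(big$mass_kg) - 0.025) / 0.025, 0.05)

  expect_identical(gen_cohort(20, seed = 7), gen_cohort(20, seed = 7))
  expect_error(gen_cohort(0), "n_fish")
  expect_error(gen_cohort(5, mass_logsd = -1), "variance")
})

test_that("cohort invariants hold across random draws", {
  for (s in 1:5) {
    co <- gen_cohort(50, seed = s, treatment = "18-26")
    expect_true(all(co$mass_kg > 0))
    expect_true(all(co$k > 0))
    expect_true(all(co$rec_alpha < co$rec_beta & co$rec_beta < 0))
    # MMR above RMR over the whole holding range
    rmr_hi <- co$rmr_ref * exp(co$k * (26 - co$ref_temp_c))
    expect_true(all(co$mmr > rmr_hi))
  }
})

test_that("noiseless traces invert the MO2 equation exactly", {
  fish <- fixed_fish()
  hold <- gen_temperature_series(20, 2, n_days = 1)
  tr <- gen_respirometry_trace(fish, hold, noise_sd = 0, duration_h = 20)
  cyc <- extract_cycles(tr)
  mo2 <- compute_mo2(cyc$slope, fish$chamber_volume_l, fish$mass_kg,
                     fish$b_rmr)
  truth <- fish$rmr_ref * exp(fish$k * (cyc$temp_c - fish$ref_temp_c))
  expect_equal(mo2, truth, tolerance = 1e-10)
  expect_true(all(cyc$r2 == 1))
})

test_that("default-noise 20-hour plans keep every cycle above the QC cutoff", {
  fish <- fixed_fish()
  hold <- gen_temperature_series(20, 2, n_days = 1)
  tr <- gen_respirometry_trace(fish, hold, noise_sd = 0.001,
                               duration_h = 20, seed = 11)
  cyc <- extract_cycles(tr)
  expect_true(all(cyc$r2 >= 0.9))
})

test_that("traces are reproducible under a seed and refuse unsafe plans", {
  fish <- fixed_fish()
  hold <- gen_temperature_series(20, 2, n_days = 1)
  a <- gen_respirometry_trace(fish, hold, noise_sd = 0.002, duration_h = 2,
                              seed = 3)
  b <- gen_respirometry_trace(fish, hold, noise_sd = 0.002, duration_h = 2,
                              seed = 3)
  expect_identical(a, b)

  # a fish respiring hard enough to drive O2 below 80% saturation in one
  # measure phase must be rejected
  hot <- fixed_fish(rmr_ref = 400, chamber_volume_l = 0.05)
  expect_error(
    gen_respirometry_trace(hot, hold, noise_sd = 0, duration_h = 2),
    "80% air saturation")
})

test_that("anomalous cycles drive fish-level exclusion", {
  fish <- fixed_fish()
  hold <- gen_temperature_series(20, 2, n_days = 1)
  tr <- gen_respirometry_trace(fish, hold, noise_sd = 0, duration_h = 10,
                               anomaly_cycles = seq(1, 60, by = 3),
                               anomaly_amplitude = 0.05)
  cyc <- qc_cycles(extract_cycles(tr))
  expect_gt(mean(!cyc$qc_pass), 0.25)
  expect_false(qc_filter_fish(cyc)$retained)
})

test_that("recovery traces follow the biexponential model", {
  fish <- fixed_fish(B = 0.0)
  # B = 0: single exponential, log(MO2 - rmr) exactly linear in t
  fish$rec_B <- 0
  rec <- gen_recovery_trace(fish, rmr = 2.5, noise_sd = 0)
  lg <- log(rec$mo2 - 2.5)
  expect_equal(stats::cor(lg, rec$time_min)^2, 1, tolerance = 1e-12)

  fish <- fixed_fish()
  rec <- gen_recovery_trace(fish, rmr = 2.5, duration_min = 600,
                            sample_interval_min = 10, noise_sd = 0)
  expect_true(all(diff(rec$mo2) < 0))          # monotone decay
  expect_equal(rec$mo2[1], max(rec$mo2))       # maximum at t = 0
  expect_lt(rec$mo2[length(rec$mo2)] - 2.5, 0.01)  # approaches the asymptote

  bad <- fixed_fish()
  bad$rec_alpha <- 0.1
  expect_error(gen_recovery_trace(bad, rmr = 2.5), "alpha < beta < 0")
})

test_that("post-chase traces encode MMR in the steepest window", {
  fish <- fixed_fish()
  pc <- gen_postchase_trace(fish, rmr_chase = 2.5, temp_c = 20, noise_sd = 0)
  got <- compute_mmr(pc, fish$mass_kg, fish$chamber_volume_l, fish$b_mmr)
  expect_equal(got$mmr, fish$rec_A + fish$rec_B + 2.5, tolerance = 1e-10)
  expect_equal(got$cycle_id, 1)
  expect_equal(got$window_start_s, 0)
})
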