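# Cycle slope fitting, QC rules, and the MO2 equation.

test_that("cycle slopes are unit-converted OLS estimates", {
  t_s <- seq(0, 300, by = 10)
  fit <- fit_cycle_slope(t_s, 10 - 0.001 * t_s)
  expect_equal(fit$slope, -3.6)
  expect_equal(fit$r2, 1)

  # degenerate: constant O2 -> zero slope, undefined R^2
  flat <- fit_cycle_slope(t_s, rep(8, length(t_s)))
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$r2))

  expect_error(fit_cycle_slope(c(0, 10), c(9, 8)), "3 points")
  expect_error(fit_cycle_slope(c(0, 10, 10), c(9, 8, 7)), "increasing")
})

test_that("cycle slopes agree with an lm oracle on noisy data", {
  set.seed(42)
  for (rep in 1:5) {
    t_s <- sort(stats::runif(36, 0, 360))
    o2 <- 9 - 0.0008 * t_s + stats::rnorm(36, 0, 0.01)
    got <- fit_cycle_slope(t_s, o2)
    want <- lm_slope_oracle(t_s, o2)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$r2, want$r2, tolerance = 1e-10)
  }
})

test_that("QC passes R^2 at the cutoff and respects anomaly flags", {
  cyc <- data.frame(fish_id = "f", cycle_id = 1:4,
                    r2 = c(0.89, 0.90, 0.95, NA),
                    runs_p = NA_real_, anomaly = c(FALSE, FALSE, TRUE, FALSE))
  out <- qc_cycles(cyc)
  expect_equal(out$qc_pass, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("the runs test flags smooth non-linear cycles", {
  t_s <- seq(0, 300, by = 10)
  # curved decline: high R^2, but systematically signed residuals
  o2 <- 9 - 0.002 * t_s + 2e-6 * t_s^2
  fit <- fit_cycle_slope(t_s, o2)
  expect_gt(fit$r2, 0.9)
  cyc <- data.frame(fish_id = "f", cycle_id = 1, r2 = fit$r2,
                    runs_p = fit$runs_p, anomaly = FALSE)
  expect_true(qc_cycles(cyc)$qc_pass)                    # runs test off
  expect_false(qc_cycles(cyc, runs_test = TRUE)$qc_pass) # runs test on
})

test_that("fish exclusion uses a strict 25% boundary and ignores order", {
  qc10 <- c(rep(FALSE, 3), rep(TRUE, 7))        # 30% failing
  expect_false(qc_filter_fish(qc10)$retained)
  expect_true(qc_filter_fish(c(rep(FALSE, 2), rep(TRUE, 8)))$retained)
  expect_true(qc_filter_fish(c(FALSE, TRUE, TRUE, TRUE))$retained)  # 25% exact

  set.seed(1)
  expect_equal(qc_filter_fish(sample(qc10))$retained,
               qc_filter_fish(qc10)$retained)
})

test_that("the MO2 equation matches hand-evaluated cases", {
  # at the reference mass the allometric factor is exactly 1 for any b
  for (b in c(0.5, 0.72, 0.74, 1)) {
    expect_equal(compute_mo2(-2, 0.275, 0.025, b), 20)
  }
  expect_equal(compute_mo2(-2, 0.300, 0.050, 0.72), 10 * 2^0.28)
  expect_equal(compute_mo2(0, 0.275, 0.025, 0.72), 0)
  # blank correction subtracts background depletion
  expect_equal(compute_mo2(-2.1, 0.275, 0.025, 0.72, blank_slope = -0.1), 20)

  expect_error(compute_mo2(-2, 0.02, 0.025, 0.72), "exceed")
  expect_error(compute_mo2(0.2, 0.275, 0.025, 0.72), "positive")
})

test_that("MO2 is homogeneous in slope and continuous in mass", {
  expect_equal(compute_mo2(-4, 0.275, 0.030, 0.72),
               2 * compute_mo2(-2, 0.275, 0.030, 0.72))
  # scaling factor monotone increasing in m for b < 1
  m <- seq(0.005, 0.2, by = 0.005)
  f <- (m / 0.025)^(1 - 0.72)
  expect_true(all(diff(f) > 0))
  expect_equal(f[m == 0.025], 1)
})

test_that("scaling exponents are recovered from log-log regressions", {
  m <- c(0.010, 0.018, 0.025, 0.040, 0.075)
  raw <- 30 * m^0.74
  expect_equal(estimate_scaling_exponent(raw, m)$b, 0.74, tolerance = 1e-12)

  # exact two-point slope
  two <- estimate_scaling_exponent(c(2, 4), c(0.02, 0.04))
  expect_equal(two$b, log(2) / log(2))

  set.seed(9)
  m <- exp(stats::rnorm(150, log(0.025), 0.5))
  raw <- 30 * m^0.72 * exp(stats::rnorm(150, 0, 0.1))
  expect_lt(abs(estimate_scaling_exponent(raw, m)$b - 0.72), 0.05)

  expect_error(estimate_scaling_exponent(c(2, 3), c(0.02, 0.02)), "identical")
})
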