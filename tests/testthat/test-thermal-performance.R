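# TPC fitting (T_opt, T_pejus), FAS line (T_FAS3), exponential RMR.

test_that("a noiseless quadratic TPC is recovered in closed form", {
  temp <- rep(c(14, 16, 18, 20, 22), each = 3)
  aas <- 10 - 0.1 * (temp - 18)^2
  fit <- fit_aas_tpc(temp, aas)
  expect_true(fit$valid)
  expect_equal(fit$t_opt, 18, tolerance = 1e-8)
  expect_equal(fit$peak, 10, tolerance = 1e-8)
  expect_equal(fit$t_pej, 18 + c(-1, 1) * sqrt(20), tolerance = 1e-8)
  expect_equal(predict(fit, 18), 10, tolerance = 1e-8)
})

test_that("flat aerobic scope yields an invalid TPC with no parameters", {
  temp <- rep(c(16, 19, 22, 26), each = 4)
  fit <- fit_aas_tpc(temp, rep(8, length(temp)))
  expect_false(fit$valid)
  expect_true(is.na(fit$t_opt))
  expect_true(all(is.na(fit$t_pej)))
  expect_error(fit_aas_tpc(c(16, 16, 19, 19), c(1, 2, 3, 4)), "3 distinct")
})

test_that("T_opt is recovered from noisy individual-fish data", {
  set.seed(21)
  temp <- sample(c(14, 17, 20, 23, 26), 40, replace = TRUE)
  aas <- 10 - 0.12 * (temp - 19)^2 + stats::rnorm(40, 0, 0.6)
  fit <- fit_aas_tpc(temp, aas)
  expect_lt(abs(fit$t_opt - 19), 0.5)
})

test_that("pejus temperatures are symmetric and sit at 80% of peak", {
  set.seed(4)
  for (rep in 1:20) {
    topt <- stats::runif(1, 15, 22)
    peak <- stats::runif(1, 5, 14)
    curv <- stats::runif(1, 0.05, 0.4)
    temp <- stats::runif(30, topt - 6, topt + 6)
    fit <- fit_aas_tpc(temp, peak - curv * (temp - topt)^2 +
                         stats::rnorm(30, 0, 0.2))
    if (!fit$valid) next
    expect_equal(fit$t_opt - fit$t_pej[1], fit$t_pej[2] - fit$t_opt,
                 tolerance = 1e-9)
    expect_equal(predict(fit, fit$t_pej), rep(0.8 * fit$peak, 2),
                 tolerance = 1e-9)
  }
})

test_that("the FAS line locates T_FAS3 exactly", {
  temp <- rep(c(16, 19, 22, 25), each = 3)
  fit <- fit_fas_line(temp, 9 - 0.25 * temp)
  expect_true(fit$defined)
  expect_equal(fit$t_fas3, 24)
  expect_equal(predict(fit, fit$t_fas3), 3, tolerance = 1e-12)

  # generator round trip through a known crossing
  fas <- 3 - 0.45 * (temp - 23.8)
  fit <- suppressWarnings(fit_fas_line(temp, fas))
  expect_equal(fit$t_fas3, 23.8, tolerance = 1e-9)

  # rising FAS: flagged undefined, no error
  up <- fit_fas_line(temp, 1 + 0.2 * temp)
  expect_false(up$defined)
  expect_true(is.na(up$t_fas3))
})

test_that("extrapolated T_FAS3 carries a warning and flag", {
  temp <- rep(c(16, 18, 20), each = 3)
  expect_warning(fit <- fit_fas_line(temp, 9 - 0.2 * temp), "extrapolation")
  expect_true(fit$extrapolated)
})

test_that("exponential RMR fits return the thermal coefficient and Q10", {
  temp <- rep(c(15, 18, 21, 24), each = 2)
  fit <- fit_rmr_exponential(temp, 2 * exp(0.07 * temp))
  expect_equal(fit$k, 0.07, tolerance = 1e-10)
  expect_equal(fit$q10, exp(0.7), tolerance = 1e-9)

  two <- fit_rmr_exponential(c(16, 20), c(2, 3))
  expect_equal(two$k, (log(3) - log(2)) / 4)

  set.seed(12)
  temp <- sample(15:25, 200, replace = TRUE)
  rmr <- 1.8 * exp(0.08 * (temp - 16)) * exp(stats::rnorm(200, 0, 0.1))
  expect_lt(abs(fit_rmr_exponential(temp, rmr)$k - 0.08), 0.01)

  expect_error(fit_rmr_exponential(c(15, 18, 21), c(2, 0, 3)), "positive")
})
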