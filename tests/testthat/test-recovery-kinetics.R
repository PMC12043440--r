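# Biexponential recovery fitting and recovery-time solvers.

pool_recovery <- function(A, alpha, B, beta, rmr, n_fish = 12,
                          times = seq(0, 50, by = 10), cv = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_fish), function(i) {
    mo2 <- A * exp(alpha * times) + B * exp(beta * times) + rmr
    if (cv > 0) mo2 <- mo2 * (1 + stats::rnorm(length(times), 0, cv))
    data.frame(t = times, y = mo2)
  }))
}

test_that("noiseless biexponential data are fit exactly", {
  d <- pool_recovery(8, -0.3, 3, -0.03, 2.5, n_fish = 2)
  fit <- fit_recovery(d$t, d$y, rmr_group = 2.5)
  expect_equal(coef(fit)[["A"]], 8, tolerance = 1e-6)
  expect_equal(coef(fit)[["alpha"]], -0.3, tolerance = 1e-6)
  expect_equal(coef(fit)[["B"]], 3, tolerance = 1e-6)
  expect_equal(coef(fit)[["beta"]], -0.03, tolerance = 1e-6)
  expect_lt(fit$alpha, fit$beta)
  # t = 0 prediction is exactly A + B + asymptote
  expect_equal(predict(fit, 0), fit$A + fit$B + fit$rmr)
})

test_that("single-exponential data drive B to its lower bound", {
  d <- pool_recovery(8, -0.2, 0, -0.03, 2.5, n_fish = 2)
  fit <- fit_recovery(d$t, d$y, rmr_group = 2.5)
  # fitted curve reproduces the data even in the nested single-phase limit
  expect_lt(max(abs(predict(fit, d$t) - d$y)), 1e-6)
  expect_lt(min(fit$A, fit$B) , 1e-4)
  expect_error(fit_recovery(0:6, rep(5, 7), 2), "8")
})

test_that("noisy pooled fits reach the least-squares optimum", {
  for (s in c(2, 31)) {
    d <- pool_recovery(8, -0.3, 3, -0.03, 2.5, n_fish = 12, cv = 0.05,
                       seed = s)
    fit <- fit_recovery(d$t, d$y, rmr_group = 2.5)
    # the fit can never sit above the objective at the true parameters
    rss_truth <- sum((d$y - (8 * exp(-0.3 * d$t) + 3 * exp(-0.03 * d$t) +
                               2.5))^2)
    expect_lte(fit$rss, rss_truth)
    # the slow phase is well identified at this noise level; the fast
    # phase rests on the few early samples and is recovered more coarsely
    expect_lt(abs(fit$beta - (-0.03)) / 0.03, 0.15)
    expect_lt(abs(fit$alpha - (-0.3)) / 0.3, 0.50)
    expect_lt(fit$alpha, fit$beta)
  }
})

test_that("predicted recovery is monotone non-increasing for valid fits", {
  set.seed(8)
  for (rep in 1:20) {
    f <- manual_recovery_fit(stats::runif(1, 2, 10), stats::runif(1, -1, -0.1),
                             stats::runif(1, 0, 5), stats::runif(1, -0.09, -0.01),
                             stats::runif(1, 1, 4))
    t <- seq(0, 300, by = 0.5)
    expect_true(all(diff(predict(f, t)) <= 0))
  }
})

test_that("bisection matches the closed-form single-exponential solution", {
  f <- manual_recovery_fit(8, -0.25, 0, -0.03, 2)
  mmr <- 9
  want <- closed_form_time(8, -0.25, 2, mmr / 3)
  got <- solve_time_fas3(f, 2, mmr)
  expect_true(got$reached)
  expect_lt(abs(got$time_min - want) * 60, 0.1)

  t80 <- solve_time_aas80(f, 2, aas = 8)
  want80 <- closed_form_time(8, -0.25, 2, 2 + 0.2 * 8)
  expect_lt(abs(t80$time_min - want80) * 60, 0.1)
})

test_that("bisection equals a dense-grid scan and ignores bracket widening", {
  f <- manual_recovery_fit(8, -0.3, 3, -0.03, 2.5)
  thr <- 2.5 + 0.2 * 11
  got <- solve_time_aas80(f, 2.5, aas = 11)
  grid <- seq(0, 200, by = 0.01 / 60)          # 0.01-s resolution
  cross <- grid[which(predict(f, grid) <= thr)[1]]
  expect_lt(abs(got$time_min - cross) * 60, 0.1)
  wide <- solve_time_aas80(f, 2.5, aas = 11, max_time_min = 1200)
  expect_equal(got$time_min, wide$time_min)
})

test_that("threshold edge cases return zero or the not-reached flag", {
  f <- manual_recovery_fit(8, -0.3, 3, -0.03, 2.5)
  # already below threshold at t = 0
  expect_equal(thermalscope:::solve_recovery_time(f, 2.5, threshold = 20)$time_min, 0)
  # threshold below the asymptote is unreachable
  nr <- thermalscope:::solve_recovery_time(f, 2.5, threshold = 2.4)
  expect_false(nr$reached)
  expect_true(is.na(nr$time_min))
  # fish with MMR / RMR < 3: FAS = 3 never available
  nr3 <- solve_time_fas3(f, rmr_chase = 4, mmr = 9)
  expect_false(nr3$reached)
})

test_that("Time_FAS3 exceeds Time_AAS80 when its threshold is lower", {
  set.seed(15)
  for (rep in 1:10) {
    rmr <- stats::runif(1, 2, 4)
    aas <- stats::runif(1, 5, 10)
    mmr <- rmr + aas
    f <- manual_recovery_fit(0.7 * aas, -0.3, 0.3 * aas, -0.03, rmr)
    if (mmr / 3 <= rmr) next
    if (mmr / 3 < rmr + 0.2 * aas) {
      t3 <- solve_time_fas3(f, rmr, mmr)
      t80 <- solve_time_aas80(f, rmr, aas)
      if (t3$reached && t80$reached) {
        expect_gte(t3$time_min, t80$time_min)
      }
    }
  }
})

test_that("the literal threshold interpretation is available behind the switch", {
  f <- manual_recovery_fit(8, -0.3, 3, -0.03, 2.5)
  lit <- solve_time_aas80(f, 2.5, aas = 11, interpretation = "literal")
  dflt <- solve_time_aas80(f, 2.5, aas = 11)
  expect_equal(lit$threshold, 0.8 * 11)
  expect_equal(dflt$threshold, 2.5 + 0.2 * 11)
  expect_false(isTRUE(all.equal(lit$time_min, dflt$time_min)))
})
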