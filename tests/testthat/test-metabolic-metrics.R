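# RMR binning, sliding-window MMR, aerobic scope, group summaries.

make_cycles <- function(temp_c, mo2, start_min = NULL, qc = TRUE) {
  n <- length(temp_c)
  data.frame(fish_id = "f1", cycle_id = seq_len(n),
             start_min = start_min %||% (240 + 10 * seq_len(n)),
             temp_c = temp_c, mo2 = mo2,
             qc_pass = rep_len(qc, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("RMR bins average by rounded temperature and drop sparse bins", {
  cyc <- make_cycles(rep(19.2, 5), rep(5, 5))
  expect_equal(compute_rmr(cyc), data.frame(temp_bin = 19, rmr = 5, n = 5L))

  # a bin with fewer than 3 cycles is absent
  cyc <- make_cycles(c(rep(19.1, 4), 21.0, 20.9), c(rep(5, 4), 7, 7.2))
  out <- compute_rmr(cyc)
  expect_equal(out$temp_bin, 19)

  # settling discard removes early cycles
  cyc <- make_cycles(rep(19, 6), c(9, 9, 9, 5, 5, 5),
                     start_min = c(0, 60, 120, 250, 300, 350))
  expect_equal(compute_rmr(cyc)$rmr, 5)
  expect_error(compute_rmr(make_cycles(19, 5, start_min = 10)), "settling")
})

test_that("RMR binning equals a brute-force group-by oracle", {
  set.seed(5)
  for (rep in 1:5) {
    temp <- stats::runif(40, 15.6, 24.4)
    mo2 <- stats::runif(40, 1, 6)
    got <- compute_rmr(make_cycles(temp, mo2))
    want <- brute_rmr_bins(temp, mo2)
    expect_equal(got$temp_bin, want$temp_bin)
    expect_equal(got$rmr, want$rmr)
    expect_equal(got$n, want$n)
  }
})

test_that("half-degree temperatures round away from zero", {
  cyc <- make_cycles(rep(19.5, 3), rep(5, 3))
  expect_equal(compute_rmr(cyc)$temp_bin, 20)
})

make_postchase <- function(o2, dt = 15, cycle_id = 1,
                           start = as.POSIXct("2023-07-02 08:00:00", tz = "UTC")) {
  n <- length(o2)
  data.frame(fish_id = "f1", cycle_id = cycle_id, phase = "measure",
             timestamp = start + dt * (seq_len(n) - 1) + cycle_id * 600,
             o2_mg_per_l = o2, temp_c = 20)
}

test_that("a globally linear decline gives the whole-cycle slope as MMR", {
  t_s <- seq(0, 360, by = 15)
  tr <- make_postchase(9 - 0.0005 * t_s)
  got <- compute_mmr(tr, 0.025, 0.275, b_mmr = 0.74)
  expect_equal(got$slope, -1.8, tolerance = 1e-10)
  expect_equal(got$mmr, compute_mo2(-1.8, 0.275, 0.025, 0.74))
})

test_that("the sliding window finds the steep segment and matches the brute scan", {
  t_s <- seq(0, 360, by = 15)
  # steep first 3 minutes, shallow afterwards
  o2 <- ifelse(t_s <= 180, 9 - 0.002 * t_s, 9 - 0.002 * 180 - 0.0003 * (t_s - 180))
  tr <- make_postchase(o2)
  got <- compute_mmr(tr, 0.025, 0.275)
  expect_equal(got$slope, brute_mmr_slope(t_s, o2), tolerance = 1e-10)
  expect_lte(got$window_start_s, 60)  # window sits in the steep segment
})

test_that("MMR can come from a later post-chase cycle", {
  t_s <- seq(0, 360, by = 15)
  c1 <- make_postchase(9 - 0.0005 * t_s, cycle_id = 1)
  c2 <- make_postchase(9 - 0.0012 * t_s, cycle_id = 2)
  got <- compute_mmr(rbind(c1, c2), 0.025, 0.275)
  expect_equal(got$cycle_id, 2)
})

test_that("windowed MMR is at least as steep as any whole-cycle slope", {
  # generated post-chase traces decline at a non-increasing rate, so the
  # steepest 120-s window can never be shallower than a full-cycle fit
  for (s in 1:3) {
    fish <- fixed_fish()
    pc <- gen_postchase_trace(fish, rmr_chase = 2.5, temp_c = 20,
                              noise_sd = 0.0005, seed = s)
    got <- compute_mmr(pc, fish$mass_kg, fish$chamber_volume_l)
    for (cid in unique(pc$cycle_id)) {
      g <- pc[pc$cycle_id == cid & pc$phase == "measure", ]
      t_s <- as.numeric(g$timestamp) - as.numeric(g$timestamp[1])
      expect_lte(got$slope, fit_cycle_slope(t_s, g$o2_mg_per_l)$slope)
    }
  }
  expect_error(compute_mmr(make_postchase(c(9, 8.9), dt = 30), 0.025, 0.275),
               "window")
})

test_that("aerobic scope uses the chase-temperature bin, per fish", {
  bins <- data.frame(temp_bin = c(18, 19, 20), rmr = c(2.0, 2.4, 2.9),
                     n = c(5L, 6L, 4L))
  sc <- compute_scope(bins, mmr = 12, chase_temp_c = 19)
  expect_equal(sc$aas, 12 - 2.4)
  expect_equal(sc$fas, 12 / 2.4)
  expect_equal(sc$aas + sc$rmr_chase, sc$mmr)   # exact identity

  # MMR equal to RMR: zero absolute scope, unit factorial scope
  sc0 <- compute_scope(bins, mmr = 2.4, chase_temp_c = 19)
  expect_equal(sc0$aas, 0)
  expect_equal(sc0$fas, 1)

  expect_error(compute_scope(bins, 12, chase_temp_c = 23), "chase temperature")
  fb <- compute_scope(bins, 12, chase_temp_c = 21, fallback_nearest = TRUE)
  expect_equal(fb$rmr_temp_bin, 20)
  expect_error(compute_scope(bins, 12, chase_temp_c = 22,
                             fallback_nearest = TRUE), "chase temperature")
})

test_that("group FAS is the mean of per-fish ratios, not a ratio of means", {
  profiles <- data.frame(
    fish_id = c("a", "b", "c"), population = "p", treatment = "t",
    mmr = c(12, 9, 15), rmr_chase = c(2, 3, 2.5))
  profiles$fas <- profiles$mmr / profiles$rmr_chase
  gs <- summarize_group(profiles, metrics = c("mmr", "rmr_chase", "fas"))
  fas_mean <- gs$mean[gs$metric == "fas"]
  expect_equal(fas_mean, mean(profiles$fas))
  expect_false(isTRUE(all.equal(fas_mean,
                                mean(profiles$mmr) / mean(profiles$rmr_chase))))
})

test_that("group summaries report mean, SEM and n", {
  profiles <- data.frame(fish_id = c("a", "b", "c"), population = "p",
                         treatment = "t", aas = c(2, 4, 6))
  gs <- summarize_group(profiles, metrics = "aas")
  expect_equal(gs$mean, 4)
  expect_equal(gs$sem, 2 / sqrt(3))
  expect_equal(gs$n, 3L)

  single <- summarize_group(profiles[1, ], metrics = "aas")
  expect_true(is.na(single$sem))

  # spreadsheet-style oracle on a random cohort
  set.seed(3)
  pr <- data.frame(fish_id = letters[1:10],
                   population = rep(c("p1", "p2"), each = 5),
                   treatment = "t", mmr = stats::runif(10, 9, 15))
  gs <- summarize_group(pr, metrics = "mmr")
  for (p in c("p1", "p2")) {
    v <- pr$mmr[pr$population == p]
    expect_equal(gs$mean[gs$population == p], mean(v))
    expect_equal(gs$sem[gs$population == p], stats::sd(v) / sqrt(5))
  }
})
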