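# Independent oracles used across the suite: every one goes through a
# different numerical path (stats::lm, exhaustive scans, closed forms) than
# the implementation it checks.

# OLS slope/R^2 via stats::lm (the implementation uses closed-form normal
# equations).
lm_slope_oracle <- function(times_s, o2) {
  fit <- stats::lm(o2 ~ times_s)
  list(slope = unname(stats::coef(fit)[2]) * 3600,
       r2 = summary(fit)$r.squared)
}

# Exhaustive steepest-window scan with lm: for every start index, the
# window runs to the first point at least window_s later; steepest slope
# wins, earliest on ties.
brute_mmr_slope <- function(t_s, o2, window_s = 120) {
  best <- Inf
  for (i in seq_along(t_s)) {
    j <- which(t_s - t_s[i] >= window_s)
    j <- j[j > i]
    if (length(j) == 0) next
    j <- min(j)
    idx <- i:j
    sl <- unname(stats::coef(stats::lm(o2[idx] ~ t_s[idx]))[2]) * 3600
    if (sl < best) best <- sl
  }
  if (is.infinite(best)) NULL else best
}

# Brute-force RMR binning: explicit loop over integer bins.
brute_rmr_bins <- function(temp_c, mo2, min_bin_n = 3) {
  bins <- sign(temp_c) * floor(abs(temp_c) + 0.5)
  out <- NULL
  for (b in sort(unique(bins))) {
    v <- mo2[bins == b]
    if (length(v) >= min_bin_n) {
      out <- rbind(out, data.frame(temp_bin = b, rmr = mean(v),
                                   n = length(v)))
    }
  }
  out
}

# Closed-form single-exponential recovery time (B = 0):
# t = log((threshold - rmr) / A) / alpha, in minutes.
closed_form_time <- function(A, alpha, rmr, threshold) {
  log((threshold - rmr) / A) / alpha
}

# Build a recovery_fit by hand (bypassing the fitting path) for solver tests.
manual_recovery_fit <- function(A, alpha, B, beta, rmr) {
  structure(list(A = A, alpha = alpha, B = B, beta = beta, rmr = rmr,
                 n_points = NA_integer_, n_fish = NA_integer_, label = NULL,
                 rss = NA_real_, converged = TRUE, nls = NULL),
            class = "recovery_fit")
}

# One-row cohort with fully specified (zero-variance) physiology, for
# trace-level unit tests.
fixed_fish <- function(rmr_ref = 2, k = 0.08, mmr = 12, mass_kg = 0.025,
                       chamber_volume_l = 0.275, chase_temp_c = 20,
                       A = 8, alpha = -0.3, B = 3, beta = -0.03) {
  co <- gen_cohort(1, mass_logmean = log(mass_kg), mass_logsd = 0,
                   physiology = list(rmr_ref = rmr_ref, rmr_ref_sd = 0,
                                     k = k, k_sd = 0, mmr = mmr, mmr_sd = 0,
                                     A = A, alpha = alpha, B = B, beta = beta,
                                     ctmax_sd = 0),
                   seed = 1, chamber_volume_l = chamber_volume_l,
                   chase_temp_c = chase_temp_c)
  co
}
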