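# Raw O2 traces -> quality-controlled, mass-scaled MO2 per measurement cycle.

#' Fit the O2 depletion slope of one measurement cycle
#'
#' Ordinary least squares of O2 concentration on time within a sealed
#' measure phase. The slope is reported in mg O2 L^-1 h^-1 regardless of the
#' input sampling interval; R^2 is NA when the O2 readings have zero
#' variance (a degenerate cycle that fails QC downstream).
#'
#' @param times_s Time points in seconds, strictly increasing.
#' @param o2 O2 concentrations (mg O2 L^-1), same length.
#' @return List with `slope` (mg O2 L^-1 h^-1), `r2`, `n`, and `runs_p`
#'   (two-sided p-value of a Wald-Wolfowitz runs test on residual signs;
#'   small values indicate systematic non-linearity).
#' @export
fit_cycle_slope <- function(times_s, o2) {
  n <- length(times_s)
  if (n < 3) stop("need at least 3 points to fit a cycle slope")
  if (length(o2) != n) stop("times_s and o2 must have equal length")
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  fit <- ols_line(times_s, o2)
  resid <- o2 - fit$intercept - fit$slope * times_s
  list(slope = fit$slope * 3600, r2 = fit$r2, n = n,
       runs_p = runs_test_p(resid))
}

# Wald-Wolfowitz runs test on the signs of residuals; normal approximation.
# NA when residuals are all of one sign or effectively zero.
runs_test_p <- function(resid, eps = 1e-12) {
  s <- sign(resid[abs(resid) > eps])
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

#' Extract and fit all measurement cycles of a respirometry trace
#'
#' Groups a raw trace by fish and cycle, keeps the measure phases, and fits
#' each O2 decline, recording the mean water temperature and the cycle start
#' time relative to the beginning of the fish's record.
#'
#' @param trace Data frame with columns `fish_id`, `cycle_id`, `phase`,
#'   `timestamp`, `o2_mg_per_l`, `temp_c`.
#' @return Data frame, one row per cycle: `fish_id`, `cycle_id`,
#'   `start_min`, `n_points`, `temp_c` (mean over the phase), `slope`
#'   (mg O2 L^-1 h^-1), `r2`, `runs_p`, `anomaly` (FALSE; set externally or
#'   by [qc_cycles()]), `qc_pass` (NA until [qc_cycles()] is applied).
#' @export
extract_cycles <- function(trace) {
  stopifnot_cols(trace, c("fish_id", "cycle_id", "phase", "timestamp",
                          "o2_mg_per_l", "temp_c"), "trace")
  meas <- trace[trace$phase == "measure", , drop = FALSE]
  if (nrow(meas) == 0) stop("trace contains no measure-phase rows")
  origin <- tapply(as.numeric(meas$timestamp), meas$fish_id, min)
  key <- interaction(meas$fish_id, meas$cycle_id, drop = TRUE)
  groups <- split(seq_len(nrow(meas)), key)
  rows <- lapply(groups, function(idx) {
    g <- meas[idx, , drop = FALSE]
    g <- g[order(g$timestamp), , drop = FALSE]
    t_s <- as.numeric(g$timestamp) - as.numeric(g$timestamp[1])
    fit <- fit_cycle_slope(t_s, g$o2_mg_per_l)
    data.frame(
      fish_id = g$fish_id[1], cycle_id = g$cycle_id[1],
      start_min = (as.numeric(g$timestamp[1]) -
                     origin[[as.character(g$fish_id[1])]]) / 60,
      n_points = fit$n, temp_c = mean(g$temp_c),
      slope = fit$slope, r2 = fit$r2, runs_p = fit$runs_p,
      anomaly = FALSE, qc_pass = NA,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fish_id, out$cycle_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply per-cycle quality control
#'
#' A cycle passes when its regression R^2 is at least `r2_min` (boundary
#' inclusive: R^2 exactly at the cutoff passes) and it carries no anomaly
#' flag. Anomalies may be supplied externally via the `anomaly` column, or
#' detected with a runs test on the regression residuals (patterns produced
#' by equipment rather than fish respiration); the runs test is off by
#' default.
#'
#' @param cycles Cycle table from [extract_cycles()].
#' @param r2_min Minimum R^2 to pass QC (default 0.9).
#' @param runs_test If TRUE, flag cycles whose residual runs-test p-value is
#'   below `runs_alpha` as anomalies.
#' @param runs_alpha Significance level for the runs test.
#' @return `cycles` with `anomaly` and `qc_pass` filled in.
#' @export
qc_cycles <- function(cycles, r2_min = 0.9, runs_test = FALSE,
                      runs_alpha = 0.01) {
  anomaly <- cycles$anomaly %in% TRUE
  if (runs_test) {
    anomaly <- anomaly | (!is.na(cycles$runs_p) & cycles$runs_p < runs_alpha)
  }
  cycles$anomaly <- anomaly
  r2_ok <- !is.na(cycles$r2) & cycles$r2 >= r2_min
  cycles$qc_pass <- r2_ok & !anomaly
  cycles
}

#' Decide whether a fish is retained for resting metabolic rate analysis
#'
#' A fish is excluded entirely from RMR analysis when more than 25% of its
#' MO2 regressions fail QC (strict inequality: exactly 25% failing is
#' retained). The decision does not depend on cycle order.
#'
#' @param cycles QC'd cycle table for a single fish (or a logical `qc_pass`
#'   vector).
#' @param max_fail_fraction Exclusion threshold (default 0.25).
#' @return List with `retained` (logical), `fail_fraction`, `n_cycles`.
#' @export
qc_filter_fish <- function(cycles, max_fail_fraction = 0.25) {
  qc <- if (is.data.frame(cycles)) cycles$qc_pass else cycles
  if (length(qc) < 1) stop("need at least one cycle")
  if (anyNA(qc)) stop("run qc_cycles() first: qc_pass contains NA")
  frac <- mean(!qc)
  list(retained = !(frac > max_fail_fraction), fail_fraction = frac,
       n_cycles = length(qc))
}

#' Convert a depletion slope to mass-specific MO2 scaled to 25 g
#'
#' Implements MO2 = |slope - blank_slope| * (v_R - m) / m * (m / 0.025)^(1 - b):
#' the O2 depletion rate times the effective water volume, per kg of fish,
#' allometrically standardized to the 25 g reference mass.
#'
#' @param slope Fitted depletion slope (mg O2 L^-1 h^-1; negative for a
#'   declining trace). Slopes above +0.05 indicate a sensor fault and raise
#'   an error.
#' @param v_r Respirometer volume (L).
#' @param m Fish body mass (kg); must satisfy 0 < m < v_r.
#' @param b Allometric scaling exponent (0.72 for RMR, 0.74 for MMR).
#' @param blank_slope Background (bacterial) depletion slope to subtract,
#'   same sign convention as `slope`; default 0.
#' @return Mass-specific MO2 (mg O2 kg^-1 h^-1, scaled to 25 g). Vectorized
#'   over `slope`, `v_r`, `m`.
#' @examples
#' compute_mo2(-2, v_r = 0.275, m = 0.025, b = 0.72)  # 20
#' @export
compute_mo2 <- function(slope, v_r, m, b, blank_slope = 0) {
  if (any(m <= 0)) stop("fish mass must be positive")
  if (any(v_r <= m)) stop("respirometer volume must exceed fish mass")
  if (any(slope > 0.05)) {
    stop("strongly positive O2 slope (> +0.05 mg O2 L^-1 h^-1): sensor fault")
  }
  abs(slope - blank_slope) * (v_r - m) / m * (m / 0.025)^(1 - b)
}

#' Estimate an allometric scaling exponent from raw MO2 and body mass
#'
#' Slope of the log-log regression of whole-animal (raw, mg O2 h^-1) MO2 on
#' body mass across fish.
#'
#' @param raw_mo2 Whole-animal MO2 (mg O2 h^-1), one value per fish.
#' @param mass_kg Body masses (kg).
#' @return List with `b` (the exponent), `intercept` (log scale), `r2`, `n`.
#' @export
estimate_scaling_exponent <- function(raw_mo2, mass_kg) {
  if (length(raw_mo2) != length(mass_kg)) stop("inputs must have equal length")
  if (length(raw_mo2) < 2) stop("need at least two fish")
  if (length(unique(mass_kg)) < 2) stop("all masses identical: exponent undefined")
  if (any(raw_mo2 <= 0) || any(mass_kg <= 0)) stop("values must be positive")
  fit <- ols_line(log(mass_kg), log(raw_mo2))
  list(b = fit$slope, intercept = fit$intercept, r2 = fit$r2,
       n = length(raw_mo2))
}
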