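# Per-fish metabolic metrics: temperature-binned RMR, sliding-window MMR,
# and absolute/factorial aerobic scope, with group summaries.

#' Temperature-binned resting metabolic rate for one fish
#'
#' Discards the settling window at the start of the record (handling
#' stress), rounds each cycle's mean temperature to the nearest degree
#' (half away from zero), and averages MO2 within each 1 degree bin. Bins
#' supported by fewer than `min_bin_n` cycles are dropped.
#'
#' @param cycles QC'd cycle table for one fish with an `mo2` column
#'   (mass-specific, scaled), `temp_c`, `start_min`, `qc_pass`.
#' @param settle_discard_min Minutes of data discarded from the start of the
#'   record (default 240).
#' @param min_bin_n Minimum cycles per retained bin (default 3).
#' @return Data frame with columns `temp_bin` (integer degrees C), `rmr`
#'   (mean MO2, mg O2 kg^-1 h^-1), `n` (contributing cycles).
#' @export
compute_rmr <- function(cycles, settle_discard_min = 240, min_bin_n = 3) {
  stopifnot_cols(cycles, c("mo2", "temp_c", "start_min", "qc_pass"), "cycles")
  keep <- cycles$qc_pass & cycles$start_min >= settle_discard_min
  cyc <- cycles[keep, , drop = FALSE]
  if (nrow(cyc) == 0) stop("no QC-passing cycles remain after the settling discard")
  bin <- round_half_away(cyc$temp_c)
  means <- tapply(cyc$mo2, bin, mean)
  counts <- tapply(cyc$mo2, bin, length)
  out <- data.frame(temp_bin = as.numeric(names(means)),
                    rmr = as.numeric(means), n = as.integer(counts))
  out <- out[out$n >= min_bin_n, , drop = FALSE]
  out <- out[order(out$temp_bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rolling-window OLS slopes over a sorted (t, o2) series using prefix sums.
# For each start index i the window runs to the first j with t_j - t_i >=
# window_s; windows that cannot reach the full span are not formed.
# Returns start index, start time, end time, slope (per hour), n.
rolling_window_slopes <- function(t_s, o2, window_s) {
  n <- length(t_s)
  j_end <- findInterval(t_s + window_s, t_s, left.open = TRUE) + 1L
  starts <- which(j_end <= n)
  if (length(starts) == 0) return(NULL)
  cs_t <- c(0, cumsum(t_s)); cs_o <- c(0, cumsum(o2))
  cs_tt <- c(0, cumsum(t_s * t_s)); cs_to <- c(0, cumsum(t_s * o2))
  seg <- function(cs, i, j) cs[j + 1] - cs[i]
  j <- j_end[starts]
  m <- j - starts + 1
  st <- seg(cs_t, starts, j); so <- seg(cs_o, starts, j)
  stt <- seg(cs_tt, starts, j); sto <- seg(cs_to, starts, j)
  slope <- (m * sto - st * so) / (m * stt - st * st)
  data.frame(start_idx = starts, t_start = t_s[starts], t_end = t_s[j],
             slope = slope * 3600, n = m)
}

#' Maximum metabolic rate from the steepest 120-second window
#'
#' Scans every contiguous `window_s`-second window (stepped at the raw
#' sampling interval) across all post-chase measure cycles and takes the
#' steepest O2 depletion slope, converting it to mass-specific MO2 with the
#' MMR scaling exponent. Ties are broken by the earliest window; windows
#' never span a flush phase.
#'
#' @param postchase_trace Raw post-chase trace (trace-interface columns).
#' @param mass_kg,volume_l Fish mass (kg) and respirometer volume (L).
#' @param b_mmr MMR scaling exponent (default 0.74).
#' @param window_s Window length in seconds (default 120).
#' @param blank_slope Background depletion slope (default 0).
#' @return List with `mmr` (mg O2 kg^-1 h^-1, scaled), `slope`
#'   (mg O2 L^-1 h^-1), `cycle_id`, `window_start_s` (within the cycle),
#'   and `n_windows` scanned.
#' @export
compute_mmr <- function(postchase_trace, mass_kg, volume_l, b_mmr = 0.74,
                        window_s = 120, blank_slope = 0) {
  stopifnot_cols(postchase_trace, c("cycle_id", "phase", "timestamp",
                                    "o2_mg_per_l"), "postchase_trace")
  meas <- postchase_trace[postchase_trace$phase == "measure", , drop = FALSE]
  if (nrow(meas) == 0) stop("post-chase trace contains no measure-phase rows")
  best <- NULL
  n_windows <- 0L
  for (cid in unique(meas$cycle_id)) {
    g <- meas[meas$cycle_id == cid, , drop = FALSE]
    g <- g[order(g$timestamp), , drop = FALSE]
    t_s <- as.numeric(g$timestamp) - as.numeric(g$timestamp[1])
    win <- rolling_window_slopes(t_s, g$o2_mg_per_l, window_s)
    if (is.null(win)) next
    n_windows <- n_windows + nrow(win)
    k <- which.min(win$slope)             # steepest decline; first on ties
    if (is.null(best) || win$slope[k] < best$slope) {
      best <- list(slope = win$slope[k], cycle_id = cid,
                   window_start_s = win$t_start[k])
    }
  }
  if (is.null(best)) {
    stop(sprintf("no measure cycle spans the %d-second window", window_s))
  }
  mmr <- compute_mo2(best$slope, volume_l, mass_kg, b_mmr, blank_slope)
  list(mmr = mmr, slope = best$slope, cycle_id = best$cycle_id,
       window_start_s = best$window_start_s, n_windows = n_windows)
}

#' Absolute and factorial aerobic scope for one fish
#'
#' Uses the RMR bin that corresponds to the chase temperature (both MMR and
#' RMR_chase measured at the same temperature): AAS = MMR - RMR_chase and
#' FAS = MMR / RMR_chase, always computed per fish, never from group means.
#'
#' @param rmr_by_temp RMR bin table from [compute_rmr()].
#' @param mmr Maximum metabolic rate (mg O2 kg^-1 h^-1, scaled).
#' @param chase_temp_c Chase temperature (integer degrees C).
#' @param fallback_nearest If TRUE, a missing chase-temperature bin falls
#'   back to the nearest bin within 1 degree C; by default a missing bin is
#'   an error (the direct-measurement design).
#' @return List with `rmr_chase`, `rmr_temp_bin`, `mmr`, `aas`, `fas`.
#' @export
compute_scope <- function(rmr_by_temp, mmr, chase_temp_c,
                          fallback_nearest = FALSE) {
  hit <- which(rmr_by_temp$temp_bin == chase_temp_c)
  if (length(hit) == 0 && fallback_nearest) {
    d <- abs(rmr_by_temp$temp_bin - chase_temp_c)
    if (any(d <= 1)) hit <- which.min(d)
  }
  if (length(hit) == 0) {
    stop(sprintf("no RMR bin at the chase temperature (%s degrees C)",
                 format(chase_temp_c)))
  }
  rmr_chase <- rmr_by_temp$rmr[hit[1]]
  list(rmr_chase = rmr_chase, rmr_temp_bin = rmr_by_temp$temp_bin[hit[1]],
       mmr = mmr, aas = mmr - rmr_chase, fas = mmr / rmr_chase)
}

#' Group mean and standard error of metabolic metrics
#'
#' Summarizes per-fish metric columns by population and treatment:
#' mean, SEM (sd / sqrt(n)) and n per metric. SEM is NA for a single fish.
#'
#' @param profiles Data frame of per-fish metrics with `population` and
#'   `treatment` columns.
#' @param metrics Character vector of metric column names to summarize.
#' @return Data frame in long form: `population`, `treatment`, `metric`,
#'   `mean`, `sem`, `n`.
#' @export
summarize_group <- function(profiles,
                            metrics = c("mmr", "rmr_chase", "aas", "fas",
                                        "ctmax_c")) {
  metrics <- intersect(metrics, names(profiles))
  if (nrow(profiles) < 1) stop("need at least one profile")
  key <- interaction(profiles$population, profiles$treatment, drop = TRUE)
  rows <- lapply(split(profiles, key), function(g) {
    do.call(rbind, lapply(metrics, function(mt) {
      v <- g[[mt]][!is.na(g[[mt]])]
      data.frame(population = g$population[1], treatment = g$treatment[1],
                 metric = mt,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = sem(v), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
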