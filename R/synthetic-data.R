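# Synthetic field-study generator: diel-fluctuating stream temperatures,
# intermittent-flow respirometry traces, and post-exercise recovery series
# with known ground truth, so the whole pipeline is testable end to end.

# Evaluate an expression under a private RNG state so generators are
# reproducible without disturbing the caller's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a diel-cycling stream temperature series
#'
#' Emulates an hourly water-temperature logger record: a sinusoidal diel
#' cycle peaking in late afternoon (default 16:00, trough 04:00) around a
#' seasonal mean, with optional additive Gaussian reading noise.
#'
#' @param mean_temp Mean water temperature (degrees C).
#' @param amplitude Half the diel range (degrees C); daily temperatures span
#'   `mean_temp - amplitude` to `mean_temp + amplitude`.
#' @param n_days Number of whole days to generate.
#' @param sampling_hours Sampling interval in hours (default 1, the usual
#'   logger configuration).
#' @param noise_sd Standard deviation of additive Gaussian noise (degrees C).
#' @param seed Optional integer seed; identical seeds give identical series.
#' @param peak_hour Hour of day (0-24) at which the sinusoid peaks.
#' @param start Start timestamp (POSIXct, midnight of day one).
#' @return A data frame with columns `timestamp` (POSIXct, UTC) and
#'   `temp_c`, of length `n_days * 24 / sampling_hours`.
#' @examples
#' ts <- gen_temperature_series(20.5, 3.5, n_days = 2)
#' range(ts$temp_c)  # 17.0 .. 24.0
#' @export
gen_temperature_series <- function(mean_temp, amplitude, n_days,
                                   sampling_hours = 1, noise_sd = 0,
                                   seed = NULL, peak_hour = 16,
                                   start = as.POSIXct("2023-07-01 00:00:00",
                                                      tz = "UTC")) {
  if (n_days <= 0) stop("n_days must be positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (sampling_hours <= 0) stop("sampling_hours must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- as.integer(round(n_days * 24 / sampling_hours))
  hours <- (seq_len(n) - 1) * sampling_hours
  temp <- mean_temp + amplitude * cos(2 * pi * (hours %% 24 - peak_hour) / 24)
  if (noise_sd > 0) {
    temp <- temp + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  data.frame(timestamp = start + hours * 3600, temp_c = temp)
}

#' Default physiological parameters for the synthetic cohort
#'
#' Population-level means and between-fish standard deviations emulating
#' juvenile summer steelhead: resting metabolic rate (RMR) rising
#' exponentially with temperature, a temperature-flat maximum metabolic rate
#' (MMR) plateau, biexponential post-exercise recovery, and critical thermal
#' maximum (CTmax). All rates are mass-specific, scaled to the 25 g
#' reference mass, in mg O2 kg^-1 h^-1.
#'
#' @return A named list: `rmr_ref` (RMR at `ref_temp_c`), `rmr_ref_sd`,
#'   `k` (RMR thermal coefficient, per degree C; Q10 = exp(10 k)), `k_sd`,
#'   `ref_temp_c`, `mmr` (plateau), `mmr_sd`, `mmr_topt`/`mmr_curv`
#'   (optional mild quadratic MMR mode: MMR(T) = mmr - mmr_curv
#'   (T - mmr_topt)^2; the default `mmr_curv = 0` keeps MMR flat),
#'   recovery parameters `A`, `alpha`, `B`, `beta` (amplitudes mg O2 kg^-1
#'   h^-1; rates min^-1), `ctmax`, `ctmax_sd`, and allometric scaling
#'   exponents `b_rmr`, `b_mmr`.
#' @export
default_physiology <- function() {
  list(
    rmr_ref = 1.8, rmr_ref_sd = 0.25,
    k = 0.09, k_sd = 0.008,
    ref_temp_c = 16,
    mmr = 12.5, mmr_sd = 0.9,
    mmr_topt = NA_real_, mmr_curv = 0,
    A = 8, alpha = -0.3, B = 3, beta = -0.03,
    ctmax = 30.5, ctmax_sd = 0.4,
    b_rmr = 0.72, b_mmr = 0.74
  )
}

parse_treatment <- function(label) {
  parts <- suppressWarnings(as.numeric(strsplit(label, "[-–]")[[1]]))
  if (length(parts) != 2 || anyNA(parts) || parts[2] < parts[1]) {
    stop("treatment label must look like '18-22' (low-high, degrees C)")
  }
  parts
}

#' Generate a cohort of fish with known true physiology
#'
#' Draws per-fish body mass (truncated log-normal) and physiological
#' parameters (Gaussian around the supplied means) for one population and
#' holding treatment. The returned data frame is the generator's ground
#' truth: every downstream quantity can be forward-computed from it.
#'
#' @param n_fish Number of fish (>= 1).
#' @param mass_logmean,mass_logsd Log-scale mean and sd of body mass (kg);
#'   draws are truncated at +/- 3 log-sd.
#' @param physiology Parameter list as from [default_physiology()].
#' @param seed Optional integer seed.
#' @param population,treatment Population label and holding-range label
#'   (e.g. "18-22", degrees C).
#' @param chase_temp_c Chase/test temperature; defaults to the rounded
#'   midpoint of the treatment range.
#' @param chamber_volume_l Respirometer volume (litres).
#' @return A data frame of class `cohort_truth`, one row per fish, with the
#'   identity columns of the metadata interface plus true parameters
#'   `rmr_ref`, `k`, `ref_temp_c`, `mmr`, `rec_A`, `rec_alpha`, `rec_B`,
#'   `rec_beta`, `ctmax_c`, `b_rmr`, `b_mmr`.
#' @export
gen_cohort <- function(n_fish, mass_logmean = log(0.025), mass_logsd = 0.35,
                       physiology = default_physiology(), seed = NULL,
                       population = "synthetic", treatment = "18-22",
                       chase_temp_c = NULL, chamber_volume_l = 0.275) {
  if (n_fish < 1) stop("n_fish must be >= 1")
  p <- utils::modifyList(default_physiology(), physiology)
  sds <- c(mass_logsd, p$rmr_ref_sd, p$k_sd, p$mmr_sd, p$ctmax_sd)
  if (any(sds < 0)) stop("variance parameters must be non-negative")
  rng <- parse_treatment(treatment)
  if (is.null(chase_temp_c)) chase_temp_c <- round_half_away(mean(rng))

  draws <- with_seed(seed, {
    z <- stats::rnorm(n_fish)
    z <- pmin(pmax(z, -3), 3)                 # truncate mass at +/- 3 log-sd
    list(
      mass = exp(mass_logmean + mass_logsd * z),
      rmr_ref = stats::rnorm(n_fish, p$rmr_ref, p$rmr_ref_sd),
      k = stats::rnorm(n_fish, p$k, p$k_sd),
      mmr = stats::rnorm(n_fish, p$mmr, p$mmr_sd),
      ctmax = stats::rnorm(n_fish, p$ctmax, p$ctmax_sd)
    )
  })
  rmr_ref <- pmax(draws$rmr_ref, 0.05)
  k <- pmax(draws$k, 1e-4)
  # MMR must exceed RMR over the whole holding range (at the range edges,
  # where the quadratic mode - if active - is lowest and RMR is highest).
  rmr_at_max <- rmr_ref * exp(k * (rng[2] - p$ref_temp_c))
  curv_drop <- if (is.na(p$mmr_topt) || p$mmr_curv == 0) 0 else {
    p$mmr_curv * max((rng - p$mmr_topt)^2)
  }
  mmr <- pmax(draws$mmr, 1.2 * rmr_at_max + curv_drop)
  if (any(draws$mass >= chamber_volume_l)) {
    stop("drawn fish mass exceeds chamber volume; increase chamber_volume_l")
  }

  out <- data.frame(
    fish_id = sprintf("%s_%s_f%02d", population, gsub("[^0-9]", "", treatment),
                      seq_len(n_fish)),
    population = population,
    treatment = treatment,
    mass_kg = draws$mass,
    chamber_volume_l = chamber_volume_l,
    chase_temp_c = chase_temp_c,
    ctmax_c = draws$ctmax,
    rmr_ref = rmr_ref,
    k = k,
    ref_temp_c = p$ref_temp_c,
    mmr = mmr,
    mmr_topt = p$mmr_topt, mmr_curv = p$mmr_curv,
    rec_A = p$A, rec_alpha = p$alpha, rec_B = p$B, rec_beta = p$beta,
    b_rmr = p$b_rmr, b_mmr = p$b_mmr,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_truth", "data.frame")
  out
}

# True mass-specific RMR (scaled to 25 g) of one fish at temperature temp_c.
true_rmr <- function(fish, temp_c) {
  fish$rmr_ref * exp(fish$k * (temp_c - fish$ref_temp_c))
}

# True MMR at temp_c: flat plateau, or the mild quadratic mode when active.
true_mmr <- function(fish, temp_c) {
  if (is.na(fish$mmr_topt) || fish$mmr_curv == 0) return(fish$mmr)
  fish$mmr - fish$mmr_curv * (temp_c - fish$mmr_topt)^2
}

# Convert a mass-specific rate scaled to 25 g into the O2 depletion slope
# (mg O2 L^-1 h^-1, magnitude) it produces in the chamber: the inverse of
# the MO2 equation used by the processing module.
rate_to_slope <- function(rate_scaled, mass_kg, volume_l, b) {
  raw_per_kg <- rate_scaled / (mass_kg / 0.025)^(1 - b)
  raw_per_kg * mass_kg / (volume_l - mass_kg)
}

#' Generate an intermittent-flow respirometry trace for one fish
#'
#' Produces alternating measure/flush cycles. During each measure phase the
#' chamber O2 declines linearly at the slope implied by the fish's true RMR
#' at the ambient temperature (inverting the MO2 equation); flush phases
#' restore air saturation. Optional Gaussian reading noise and injected
#' sawtooth anomalies exercise the quality-control rules downstream.
#'
#' @param fish One row of a [gen_cohort()] data frame.
#' @param temp_series Temperature series (as from [gen_temperature_series()]);
#'   its span limits the trace duration.
#' @param measure_min,flush_min Measure and flush phase durations (minutes).
#' @param o2_sampling_s,flush_sampling_s Sampling intervals (seconds) within
#'   measure and flush phases.
#' @param noise_sd Gaussian sd of O2 readings (mg O2 L^-1).
#' @param o2_sat Air-saturation O2 concentration (mg O2 L^-1).
#' @param anomaly_cycles Integer cycle ids to corrupt with a sawtooth
#'   artefact (emulating equipment problems, not fish respiration).
#' @param anomaly_amplitude Sawtooth amplitude (mg O2 L^-1).
#' @param blank_slope Constant background (bacterial) depletion slope to add
#'   (mg O2 L^-1 h^-1, magnitude); default 0.
#' @param duration_h Optional cap on trace duration (hours).
#' @param seed Optional integer seed.
#' @return Data frame with the trace-interface columns `fish_id`, `cycle_id`,
#'   `phase`, `timestamp`, `o2_mg_per_l`, `temp_c`.
#' @export
gen_respirometry_trace <- function(fish, temp_series,
                                   measure_min = 6, flush_min = 4,
                                   o2_sampling_s = 15, flush_sampling_s = 60,
                                   noise_sd = 0.001, o2_sat = 9.0,
                                   anomaly_cycles = integer(0),
                                   anomaly_amplitude = 0.05,
                                   blank_slope = 0,
                                   duration_h = NULL, seed = NULL) {
  if (measure_min <= 0 || flush_min <= 0) stop("phase durations must be positive")
  if (fish$mass_kg >= fish$chamber_volume_l) {
    stop("fish mass (kg) must be smaller than chamber volume (L)")
  }
  sched <- cycle_midpoint_temps(temp_series, measure_min, flush_min,
                                duration_h)
  n_cycles <- nrow(sched)
  t0 <- min(temp_series$timestamp)
  t_meas <- seq(0, measure_min * 60, by = o2_sampling_s)
  t_flush <- seq(0, flush_min * 60 - flush_sampling_s, by = flush_sampling_s)

  pieces <- vector("list", n_cycles)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n_cycles * length(t_meas), 0, noise_sd))
  } else numeric(0)
  for (i in seq_len(n_cycles)) {
    start_s <- sched$start_min[i] * 60
    temp_i <- sched$temp_c[i]
    slope <- rate_to_slope(true_rmr(fish, temp_i), fish$mass_kg,
                           fish$chamber_volume_l, fish$b_rmr) + blank_slope
    o2 <- o2_sat - slope / 3600 * t_meas
    if (min(o2) < 0.8 * o2_sat) {
      stop("O2 would fall below 80% air saturation: flush plan insufficient ",
           "for this chamber/fish combination")
    }
    if (i %in% anomaly_cycles) {
      o2 <- o2 + anomaly_amplitude * (2 * ((t_meas %% 60) / 60) - 1)
    }
    if (noise_sd > 0) {
      idx <- (i - 1) * length(t_meas) + seq_along(t_meas)
      o2 <- o2 + noise[idx]
    }
    meas <- data.frame(
      fish_id = fish$fish_id, cycle_id = i, phase = "measure",
      timestamp = t0 + start_s + t_meas, o2_mg_per_l = o2, temp_c = temp_i,
      stringsAsFactors = FALSE
    )
    flush <- data.frame(
      fish_id = fish$fish_id, cycle_id = i, phase = "flush",
      timestamp = t0 + start_s + measure_min * 60 + t_flush,
      o2_mg_per_l = o2_sat, temp_c = temp_i,
      stringsAsFactors = FALSE
    )
    pieces[[i]] <- rbind(meas, flush)
  }
  do.call(rbind, pieces)
}

# Cycle schedule against a temperature series: cycle start (minutes from
# series start) and the temperature at the measure-phase midpoint, which is
# also the (constant) temperature the generated cycle experiences. Shared
# between trace generation and ground-truth computation so the two always
# agree.
cycle_midpoint_temps <- function(temp_series, measure_min = 6, flush_min = 4,
                                 duration_h = NULL) {
  span_h <- as.numeric(difftime(max(temp_series$timestamp),
                                min(temp_series$timestamp), units = "hours"))
  if (!is.null(duration_h)) span_h <- min(span_h, duration_h)
  cycle_min <- measure_min + flush_min
  n_cycles <- floor(span_h * 60 / cycle_min)
  if (n_cycles < 1) stop("temperature series too short for a single cycle")
  rel_h <- as.numeric(difftime(temp_series$timestamp,
                               min(temp_series$timestamp), units = "hours"))
  start_min <- (seq_len(n_cycles) - 1) * cycle_min
  mid_h <- (start_min + measure_min / 2) / 60
  data.frame(cycle_id = seq_len(n_cycles), start_min = start_min,
             temp_c = stats::approx(rel_h, temp_series$temp_c, xout = mid_h,
                                    rule = 2)$y)
}

# Biexponential recovery rate (mg O2 kg^-1 h^-1) at time t (minutes) after
# the maximum; asymptote rmr.
biexp_rate <- function(t, A, alpha, B, beta, rmr) {
  A * exp(alpha * t) + B * exp(beta * t) + rmr
}

# Integral of biexp_rate from 0 to t (rate-minutes).
biexp_integral <- function(t, A, alpha, B, beta, rmr) {
  A / alpha * (exp(alpha * t) - 1) + B / beta * (exp(beta * t) - 1) + rmr * t
}

#' Generate a post-chase O2 trace for maximum metabolic rate extraction
#'
#' Emulates the respirometry record of the hour following an exhaustive
#' chase: the depletion rate is held at MMR = A + B + rmr for a brief
#' post-chase plateau (`mmr_hold_min`), then follows the biexponential
#' recovery decay; flush phases restore saturation. Under zero noise the
#' steepest 120-s regression window recovers MMR exactly.
#'
#' @param fish One row of a [gen_cohort()] cohort.
#' @param rmr_chase Asymptotic resting rate at the chase temperature
#'   (mg O2 kg^-1 h^-1, scaled to 25 g).
#' @param temp_c Chase temperature recorded on the trace.
#' @param n_cycles Number of measure/flush cycles to generate.
#' @param mmr_hold_min Duration of the sustained-maximum plateau (minutes).
#' @param start Timestamp of the first post-chase measurement.
#' @inheritParams gen_respirometry_trace
#' @return Data frame with the trace-interface columns.
#' @export
gen_postchase_trace <- function(fish, rmr_chase, temp_c, n_cycles = 6,
                                measure_min = 6, flush_min = 4,
                                o2_sampling_s = 15, flush_sampling_s = 60,
                                noise_sd = 0.001, o2_sat = 9.0,
                                mmr_hold_min = 2, seed = NULL,
                                start = as.POSIXct("2023-07-02 08:00:00",
                                                   tz = "UTC")) {
  A <- fish$rec_A; alpha <- fish$rec_alpha
  B <- fish$rec_B; beta <- fish$rec_beta
  if (!(alpha < beta && beta < 0)) stop("recovery parameters must satisfy alpha < beta < 0")
  mmr_rate <- A + B + rmr_chase
  # cumulative scaled-rate integral (rate-minutes) since the chase, with the
  # plateau spliced in before the decay clock starts
  cum_rate <- function(t_min) {
    ifelse(t_min <= mmr_hold_min,
           mmr_rate * t_min,
           mmr_rate * mmr_hold_min +
             biexp_integral(t_min - mmr_hold_min, A, alpha, B, beta, rmr_chase))
  }
  conv <- rate_to_slope(1, fish$mass_kg, fish$chamber_volume_l, fish$b_mmr)
  t_meas <- seq(0, measure_min * 60, by = o2_sampling_s)
  t_flush <- seq(0, flush_min * 60 - flush_sampling_s, by = flush_sampling_s)
  cycle_min <- measure_min + flush_min

  pieces <- vector("list", n_cycles)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n_cycles * length(t_meas), 0, noise_sd))
  } else numeric(0)
  for (i in seq_len(n_cycles)) {
    start_min <- (i - 1) * cycle_min
    drop <- conv * (cum_rate(start_min + t_meas / 60) - cum_rate(start_min)) / 60
    o2 <- o2_sat - drop
    if (noise_sd > 0) {
      idx <- (i - 1) * length(t_meas) + seq_along(t_meas)
      o2 <- o2 + noise[idx]
    }
    meas <- data.frame(
      fish_id = fish$fish_id, cycle_id = i, phase = "measure",
      timestamp = start + start_min * 60 + t_meas,
      o2_mg_per_l = o2, temp_c = temp_c, stringsAsFactors = FALSE
    )
    flush <- data.frame(
      fish_id = fish$fish_id, cycle_id = i, phase = "flush",
      timestamp = start + (start_min + measure_min) * 60 + t_flush,
      o2_mg_per_l = o2_sat, temp_c = temp_c, stringsAsFactors = FALSE
    )
    pieces[[i]] <- rbind(meas, flush)
  }
  do.call(rbind, pieces)
}

#' Generate a post-exercise MO2 recovery series
#'
#' Samples the biexponential recovery model
#' MO2(t) = A exp(alpha t) + B exp(beta t) + rmr at regular intervals,
#' emulating the roughly 10-minute MO2 estimates obtained from successive
#' measurement cycles during the hour after an exhaustive chase.
#'
#' @param fish One row of a [gen_cohort()] cohort (supplies A, alpha, B, beta).
#' @param rmr Asymptote: the fish's resting rate at the chase temperature.
#' @param sample_interval_min Sampling interval (minutes).
#' @param duration_min Record length (minutes).
#' @param noise_sd Noise level: an absolute sd (mg O2 kg^-1 h^-1) when
#'   `noise = "additive"`, or a coefficient of variation when
#'   `noise = "multiplicative"`.
#' @param noise Noise model.
#' @param seed Optional integer seed.
#' @return Data frame with columns `fish_id`, `time_min`, `mo2`.
#' @export
gen_recovery_trace <- function(fish, rmr, sample_interval_min = 10,
                               duration_min = 60, noise_sd = 0,
                               noise = c("additive", "multiplicative"),
                               seed = NULL) {
  noise <- match.arg(noise)
  A <- fish$rec_A; alpha <- fish$rec_alpha
  B <- fish$rec_B; beta <- fish$rec_beta
  if (!(alpha < beta && beta < 0)) stop("recovery parameters must satisfy alpha < beta < 0")
  if (A < 0 || B < 0) stop("recovery amplitudes A and B must be >= 0")
  if (duration_min <= 0) stop("duration_min must be positive")
  t <- seq(0, duration_min, by = sample_interval_min)
  mo2 <- biexp_rate(t, A, alpha, B, beta, rmr)
  if (noise_sd > 0) {
    eps <- with_seed(seed, stats::rnorm(length(t)))
    mo2 <- if (noise == "additive") mo2 + noise_sd * eps
           else mo2 * (1 + noise_sd * eps)
  }
  data.frame(fish_id = fish$fish_id, time_min = t, mo2 = mo2,
             stringsAsFactors = FALSE)
}
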