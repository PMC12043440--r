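# End-to-end orchestration: simulate (or read) inputs, process traces,
# compute metabolic metrics, fit thermal-performance and recovery models,
# and assemble the vulnerability report.

#' Default synthetic study scenario
#'
#' Two stream populations with contrasting thermal regimes: a cool coastal
#' stream (moderate diel cycle) and a warm inland stream (large diel
#' swings), each with three to four fluctuating holding treatments, a
#' 20-hour resting respirometry record per fish, a post-chase hour for MMR
#' and recovery, and a 60-day habitat logger series.
#'
#' @param n_per_treatment Fish per population x treatment group.
#' @return A scenario list understood by [simulate_scenario()].
#' @export
default_scenario <- function(n_per_treatment = 4) {
  list(
    populations = list(
      list(name = "coolstream",
           habitat = list(mean_temp = 13, amplitude = 2.5, n_days = 60),
           physiology = list(mmr_topt = 19, mmr_curv = 0.12),
           treatments = c("15-19", "18-22", "20-24", "23-26")),
      list(name = "warmstream",
           habitat = list(mean_temp = 19.5, amplitude = 5, n_days = 60),
           physiology = list(rmr_ref = 2.2, k = 0.08, mmr = 13.5,
                             ctmax = 31.4),
           treatments = c("18-22", "20-24", "23-27"))
    ),
    n_per_treatment = n_per_treatment,
    mass_logmean = log(0.025), mass_logsd = 0.35,
    chamber_volume_l = 0.275,
    rmr_hours = 20, measure_min = 6, flush_min = 4, o2_sampling_s = 15,
    postchase_cycles = 6, mmr_hold_min = 2, o2_sat = 9,
    recovery_interval_min = 10, recovery_duration_min = 60,
    noise = list(o2_sd = 0.001, habitat_sd = 0.2, recovery_cv = 0.05)
  )
}

#' Zero-noise variant of the default scenario
#'
#' Identical study design with every observational noise source set to
#' zero; the pipeline then recovers the generator's ground truth exactly
#' (to float tolerance), which is the basis of the closure tests.
#'
#' @inheritParams default_scenario
#' @return A scenario list.
#' @export
noiseless_scenario <- function(n_per_treatment = 4) {
  sc <- default_scenario(n_per_treatment)
  sc$noise <- list(o2_sd = 0, habitat_sd = 0, recovery_cv = 0)
  sc
}

resolve_scenario <- function(scenario) {
  if (is.character(scenario)) {
    scenario <- switch(scenario,
                       default = default_scenario(),
                       noiseless = noiseless_scenario(),
                       stop(sprintf("unknown scenario '%s'", scenario)))
  }
  scenario
}

# Ground-truth recovery time: same thresholds as the solvers, but located
# with uniroot at high precision (an independent numerical path from the
# package's bisection), then rounded to the nearest 0.1 second.
truth_recovery_time <- function(A, alpha, B, beta, rmr, threshold,
                                max_time_min = 600) {
  f <- function(t) biexp_rate(t, A, alpha, B, beta, rmr) - threshold
  if (threshold <= rmr) return(list(time_min = NA_real_, reached = FALSE))
  if (f(0) <= 0) return(list(time_min = 0, reached = TRUE))
  if (f(max_time_min) > 0) return(list(time_min = NA_real_, reached = FALSE))
  t <- stats::uniroot(f, c(0, max_time_min), tol = 1e-9)$root
  list(time_min = round(t * 600) / 600, reached = TRUE)
}

#' Simulate a complete synthetic field study with known ground truth
#'
#' Generates, for every fish of every population x treatment group: a
#' diel-fluctuating holding temperature series, a 20-hour resting
#' respirometry trace, a post-chase O2 trace for MMR, and a post-exercise
#' MO2 recovery series; plus one habitat logger series per population. The
#' returned `truth` element forward-computes every downstream quantity from
#' the generative parameters (temperature-binned RMR over the actual cycle
#' schedule, RMR_chase, MMR, AAS, FAS, group recovery parameters, and
#' recovery times), so a zero-noise run can be checked for exact closure.
#'
#' @param scenario Scenario list (or `"default"` / `"noiseless"`).
#' @param seed Integer master seed; all per-fish seeds derive from it.
#' @param settle_discard_min,min_bin_n RMR binning rules used for the truth
#'   tables (must match the analysis configuration for closure).
#' @return List with `metadata`, `traces`, `postchase`, `recovery`,
#'   `habitat` (named list of series), `cohort` (true per-fish parameters)
#'   and `truth` (list: `fish`, `rmr_bins`, `groups`, `times`).
#' @export
simulate_scenario <- function(scenario = "default", seed = 1L,
                              settle_discard_min = 240, min_bin_n = 3) {
  sc <- resolve_scenario(scenario)
  n_groups <- sum(vapply(sc$populations, function(p) length(p$treatments), 0L))
  n_fish_total <- n_groups * sc$n_per_treatment
  subseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                         n_groups + 3 * n_fish_total +
                                           length(sc$populations)))
  s_idx <- 0L
  next_seed <- function() {
    s_idx <<- s_idx + 1L
    subseeds[s_idx]
  }

  cohorts <- list(); traces <- list(); postchase <- list(); recovery <- list()
  truth_fish <- list(); truth_bins <- list(); truth_groups <- list()
  truth_times <- list()

  for (pop in sc$populations) {
    for (trt in pop$treatments) {
      cohort <- gen_cohort(sc$n_per_treatment,
                           mass_logmean = sc$mass_logmean,
                           mass_logsd = sc$mass_logsd,
                           physiology = pop$physiology,
                           seed = next_seed(),
                           population = pop$name, treatment = trt,
                           chamber_volume_l = sc$chamber_volume_l)
      rng <- parse_treatment(trt)
      hold <- gen_temperature_series(mean(rng), diff(rng) / 2, n_days = 2)
      sched <- cycle_midpoint_temps(hold, sc$measure_min, sc$flush_min,
                                    duration_h = sc$rmr_hours)
      kept <- sched[sched$start_min >= settle_discard_min, , drop = FALSE]
      bin <- round_half_away(kept$temp_c)

      # pass 1: truth RMR bins and RMR_chase per fish, from the true rate
      # function over the actual cycle schedule
      rmr_chase <- numeric(nrow(cohort))
      for (i in seq_len(nrow(cohort))) {
        fish <- cohort[i, ]
        rates <- true_rmr(fish, kept$temp_c)
        bmean <- tapply(rates, bin, mean)
        bcount <- tapply(rates, bin, length)
        keep_bin <- bcount >= min_bin_n
        bins_i <- data.frame(fish_id = fish$fish_id,
                             temp_bin = as.numeric(names(bmean))[keep_bin],
                             rmr = as.numeric(bmean)[keep_bin],
                             n = as.integer(bcount)[keep_bin],
                             stringsAsFactors = FALSE)
        truth_bins[[length(truth_bins) + 1]] <- bins_i
        hit <- bins_i$rmr[bins_i$temp_bin == fish$chase_temp_c]
        if (length(hit) == 0) {
          stop(sprintf("scenario design error: no RMR bin at chase temperature for %s",
                       fish$fish_id))
        }
        rmr_chase[i] <- hit[1]
      }

      # Tie recovery amplitudes to each fish's true scope: A_i + B_i =
      # MMR_i(T_chase) - RMR_chase_i, keeping the group's fast/slow split
      # and decay rates, so the post-chase trace, the recovery series and
      # the drawn MMR are mutually consistent.
      aas_i <- vapply(seq_len(nrow(cohort)), function(i) {
        true_mmr(cohort[i, ], cohort$chase_temp_c[i]) - rmr_chase[i]
      }, numeric(1))
      if (any(aas_i <= 0)) stop("scenario design error: non-positive true AAS")
      frac_fast <- cohort$rec_A[1] / (cohort$rec_A[1] + cohort$rec_B[1])
      cohort$rec_A <- frac_fast * aas_i
      cohort$rec_B <- (1 - frac_fast) * aas_i
      group_A <- frac_fast * mean(aas_i)
      group_B <- (1 - frac_fast) * mean(aas_i)

      # pass 2: generate traces and truth recovery times (group-level
      # parameters with each fish's own RMR_chase, as in the analysis)
      for (i in seq_len(nrow(cohort))) {
        fish <- cohort[i, ]

        traces[[length(traces) + 1]] <- gen_respirometry_trace(
          fish, hold, measure_min = sc$measure_min, flush_min = sc$flush_min,
          o2_sampling_s = sc$o2_sampling_s, noise_sd = sc$noise$o2_sd,
          o2_sat = sc$o2_sat, duration_h = sc$rmr_hours, seed = next_seed())
        postchase[[length(postchase) + 1]] <- gen_postchase_trace(
          fish, rmr_chase[i], temp_c = fish$chase_temp_c,
          n_cycles = sc$postchase_cycles, measure_min = sc$measure_min,
          flush_min = sc$flush_min, o2_sampling_s = sc$o2_sampling_s,
          noise_sd = sc$noise$o2_sd, o2_sat = sc$o2_sat,
          mmr_hold_min = sc$mmr_hold_min, seed = next_seed())
        recovery[[length(recovery) + 1]] <- gen_recovery_trace(
          fish, rmr_chase[i], sample_interval_min = sc$recovery_interval_min,
          duration_min = sc$recovery_duration_min,
          noise_sd = sc$noise$recovery_cv, noise = "multiplicative",
          seed = next_seed())

        mmr_i <- fish$rec_A + fish$rec_B + rmr_chase[i]
        t80 <- truth_recovery_time(group_A, fish$rec_alpha, group_B,
                                   fish$rec_beta, rmr_chase[i],
                                   rmr_chase[i] + 0.2 * aas_i[i])
        tf3 <- truth_recovery_time(group_A, fish$rec_alpha, group_B,
                                   fish$rec_beta, rmr_chase[i], mmr_i / 3)
        truth_times[[length(truth_times) + 1]] <- data.frame(
          fish_id = fish$fish_id,
          time_aas80 = t80$time_min, aas80_reached = t80$reached,
          time_fas3 = tf3$time_min, fas3_reached = tf3$reached,
          stringsAsFactors = FALSE)
      }

      truth_fish[[length(truth_fish) + 1]] <- data.frame(
        fish_id = cohort$fish_id, population = pop$name, treatment = trt,
        chase_temp_c = cohort$chase_temp_c, rmr_chase = rmr_chase,
        mmr = cohort$rec_A + cohort$rec_B + rmr_chase,
        aas = cohort$rec_A + cohort$rec_B,
        fas = (cohort$rec_A + cohort$rec_B + rmr_chase) / rmr_chase,
        stringsAsFactors = FALSE)
      truth_groups[[length(truth_groups) + 1]] <- data.frame(
        population = pop$name, treatment = trt,
        A = group_A, alpha = cohort$rec_alpha[1],
        B = group_B, beta = cohort$rec_beta[1],
        rmr_group = mean(rmr_chase), stringsAsFactors = FALSE)
      cohorts[[length(cohorts) + 1]] <- cohort
    }
  }

  habitat <- list()
  for (pop in sc$populations) {
    habitat[[pop$name]] <- gen_temperature_series(
      pop$habitat$mean_temp, pop$habitat$amplitude,
      n_days = pop$habitat$n_days, noise_sd = sc$noise$habitat_sd,
      seed = next_seed())
  }

  cohort_all <- do.call(rbind, cohorts)
  metadata <- cohort_all[, c("fish_id", "population", "treatment", "mass_kg",
                             "chamber_volume_l", "chase_temp_c", "ctmax_c")]
  rownames(metadata) <- NULL
  list(
    metadata = metadata,
    traces = do.call(rbind, traces),
    postchase = do.call(rbind, postchase),
    recovery = do.call(rbind, recovery),
    habitat = habitat,
    cohort = cohort_all,
    truth = list(fish = do.call(rbind, truth_fish),
                 rmr_bins = do.call(rbind, truth_bins),
                 groups = do.call(rbind, truth_groups),
                 times = do.call(rbind, truth_times))
  )
}

read_pipeline_inputs <- function(paths) {
  schema <- validate_inputs(paths)
  errs <- schema[schema$level == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("input validation failed:\n",
         paste(sprintf("  %s: %s", errs$file, errs$message), collapse = "\n"))
  }
  habitat <- NULL
  if (!is.null(paths$habitat)) {
    hp <- paths$habitat
    if (is.null(names(hp)) && length(hp) == 1 && is.character(hp)) {
      habitat <- list(all = read_habitat_csv(hp))
    } else {
      habitat <- lapply(hp, read_habitat_csv)
    }
  }
  list(
    metadata = read_metadata_csv(paths$metadata),
    traces = read_trace_csv(paths$traces),
    postchase = if (!is.null(paths$postchase)) read_trace_csv(paths$postchase),
    recovery = if (!is.null(paths$recovery)) read_recovery_csv(paths$recovery),
    habitat = habitat,
    truth = NULL
  )
}

# Per-cycle MO2 estimates from a post-chase trace: used for the recovery
# series when no directly sampled recovery MO2 record is supplied.
postchase_cycle_mo2 <- function(trace, mass_kg, volume_l, b, blank_slope = 0) {
  cyc <- extract_cycles(trace)
  data.frame(
    fish_id = cyc$fish_id,
    time_min = cyc$start_min + stats::median(diff(sort(cyc$start_min))) / 2,
    mo2 = compute_mo2(cyc$slope, volume_l, mass_kg, b, blank_slope),
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) inputs, then: fits and QC-filters every measurement
#' cycle, converts slopes to mass-scaled MO2, computes per-fish
#' temperature-binned RMR, sliding-window MMR, AAS and FAS, summarizes
#' groups, fits the AAS thermal performance curve and the FAS-temperature
#' line per population, fits pooled biexponential recovery models per
#' population x treatment and solves per-fish recovery times, summarizes
#' habitat series and CTmax, and assembles the vulnerability report. Every
#' QC exclusion is logged with its triggering rule.
#'
#' @param config Configuration list from [default_config()] (possibly
#'   modified or read with [read_config()]). When `config$paths` is NULL
#'   the scenario named in `config$scenario` is simulated with
#'   `config$seed`.
#' @return Object of class `scope_report`: a list with `profiles`,
#'   `rmr_bins`, `group_summary`, `tpc`, `fas`, `rmr_fit`, `recovery_fits`,
#'   `recovery_times`, `habitat`, `ctmax`, `vulnerability`, `exclusions`,
#'   `scaling`, `config`, and (for simulated runs) `truth`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- utils::modifyList(default_config(), config, keep.null = TRUE)
  qc <- config$qc
  inputs <- if (is.null(config$paths)) {
    simulate_scenario(config$scenario, seed = config$seed,
                      settle_discard_min = qc$settle_discard_min,
                      min_bin_n = qc$min_bin_n)
  } else {
    read_pipeline_inputs(config$paths)
  }
  metadata <- inputs$metadata

  cycles <- extract_cycles(inputs$traces)
  cycles <- qc_cycles(cycles, r2_min = qc$r2_min, runs_test = qc$runs_test,
                      runs_alpha = qc$runs_alpha)
  exclusions <- list()
  bad <- cycles[!cycles$qc_pass, , drop = FALSE]
  if (nrow(bad) > 0) {
    exclusions[[length(exclusions) + 1]] <- data.frame(
      unit = "cycle", id = sprintf("%s/cycle%03d", bad$fish_id, bad$cycle_id),
      rule = ifelse(bad$anomaly, "data anomaly",
                    sprintf("R^2 < %.2f", qc$r2_min)),
      stringsAsFactors = FALSE)
  }

  b_rmr <- config$scaling$b_rmr
  b_mmr <- config$scaling$b_mmr

  meta_idx <- match(cycles$fish_id, metadata$fish_id)
  if (anyNA(meta_idx)) stop("trace contains fish absent from metadata")
  cycles$mo2 <- compute_mo2(cycles$slope,
                            metadata$chamber_volume_l[meta_idx],
                            metadata$mass_kg[meta_idx], b_rmr,
                            config$blank_slope)
  if (isTRUE(config$scaling$estimate_from_data)) {
    est <- estimate_scaling_from_cycles(cycles, metadata, qc)
    b_rmr <- est$b_rmr
    cycles$mo2 <- compute_mo2(cycles$slope,
                              metadata$chamber_volume_l[meta_idx],
                              metadata$mass_kg[meta_idx], b_rmr,
                              config$blank_slope)
  }

  profiles <- list(); rmr_bins <- list()
  for (i in seq_len(nrow(metadata))) {
    fid <- metadata$fish_id[i]
    cyc_f <- cycles[cycles$fish_id == fid, , drop = FALSE]
    if (nrow(cyc_f) == 0) next
    filt <- qc_filter_fish(cyc_f, qc$max_fail_fraction)
    if (!filt$retained) {
      exclusions[[length(exclusions) + 1]] <- data.frame(
        unit = "fish", id = fid,
        rule = sprintf("more than %.0f%% of MO2 regressions failed QC (%.0f%%)",
                       100 * qc$max_fail_fraction, 100 * filt$fail_fraction),
        stringsAsFactors = FALSE)
      next
    }
    bins <- compute_rmr(cyc_f, settle_discard_min = qc$settle_discard_min,
                        min_bin_n = qc$min_bin_n)
    rmr_bins[[length(rmr_bins) + 1]] <- cbind(fish_id = fid, bins,
                                              stringsAsFactors = FALSE)
    pc_f <- inputs$postchase[inputs$postchase$fish_id == fid, , drop = FALSE]
    if (nrow(pc_f) == 0) next
    mmr_f <- compute_mmr(pc_f, metadata$mass_kg[i],
                         metadata$chamber_volume_l[i], b_mmr,
                         window_s = config$mmr$window_s,
                         blank_slope = config$blank_slope)
    scope <- compute_scope(bins, mmr_f$mmr, metadata$chase_temp_c[i],
                           fallback_nearest = config$scope$chase_bin_fallback)
    profiles[[length(profiles) + 1]] <- data.frame(
      fish_id = fid, population = metadata$population[i],
      treatment = metadata$treatment[i],
      chase_temp_c = metadata$chase_temp_c[i],
      mass_kg = metadata$mass_kg[i],
      rmr_chase = scope$rmr_chase, mmr = scope$mmr,
      aas = scope$aas, fas = scope$fas,
      mmr_cycle = mmr_f$cycle_id,
      ctmax_c = metadata$ctmax_c[i],
      stringsAsFactors = FALSE)
  }
  if (length(profiles) == 0) stop("no fish survived QC: nothing to analyse")
  profiles <- do.call(rbind, profiles)
  rownames(profiles) <- NULL
  rmr_bins <- do.call(rbind, rmr_bins)

  group_summary <- summarize_group(profiles)

  tpc <- list(); fas <- list(); rmr_fit <- list()
  for (pop in unique(profiles$population)) {
    pr <- profiles[profiles$population == pop, , drop = FALSE]
    tpc[[pop]] <- if (length(unique(pr$chase_temp_c)) >= 3) {
      fit_aas_tpc(pr$chase_temp_c, pr$aas)
    }
    fas[[pop]] <- if (length(unique(pr$chase_temp_c)) >= 2) {
      fit_fas_line(pr$chase_temp_c, pr$fas)
    }
    pb <- rmr_bins[rmr_bins$fish_id %in% pr$fish_id, , drop = FALSE]
    rmr_fit[[pop]] <- if (length(unique(pb$temp_bin)) >= 2) {
      fit_rmr_exponential(pb$temp_bin, pb$rmr)
    }
  }

  recovery_series <- inputs$recovery
  if (is.null(recovery_series) && !is.null(inputs$postchase)) {
    pcs <- lapply(seq_len(nrow(metadata)), function(i) {
      tr <- inputs$postchase[inputs$postchase$fish_id == metadata$fish_id[i], ,
                             drop = FALSE]
      if (nrow(tr) == 0) return(NULL)
      postchase_cycle_mo2(tr, metadata$mass_kg[i],
                          metadata$chamber_volume_l[i], b_mmr,
                          config$blank_slope)
    })
    recovery_series <- do.call(rbind, pcs)
  }

  recovery_fits <- list(); recovery_times <- list()
  if (!is.null(recovery_series)) {
    pidx <- match(recovery_series$fish_id, profiles$fish_id)
    recovery_series$population <- profiles$population[pidx]
    recovery_series$treatment <- profiles$treatment[pidx]
    recovery_series <- recovery_series[!is.na(pidx), , drop = FALSE]
    key <- interaction(recovery_series$population, recovery_series$treatment,
                       drop = TRUE)
    for (g in split(recovery_series, key)) {
      label <- sprintf("%s %s", g$population[1], g$treatment[1])
      pr_g <- profiles[profiles$population == g$population[1] &
                         profiles$treatment == g$treatment[1], , drop = FALSE]
      fit <- fit_recovery(g$time_min, g$mo2, rmr_group = mean(pr_g$rmr_chase),
                          t_split = config$recovery$t_split_min,
                          label = label, n_fish = length(unique(g$fish_id)))
      recovery_fits[[label]] <- fit
      for (j in seq_len(nrow(pr_g))) {
        t80 <- solve_time_aas80(fit, pr_g$rmr_chase[j], pr_g$aas[j],
                                interpretation = config$recovery$interpretation,
                                max_time_min = config$recovery$max_time_min)
        tf3 <- solve_time_fas3(fit, pr_g$rmr_chase[j], pr_g$mmr[j],
                               max_time_min = config$recovery$max_time_min)
        recovery_times[[length(recovery_times) + 1]] <- data.frame(
          fish_id = pr_g$fish_id[j], population = pr_g$population[j],
          treatment = pr_g$treatment[j],
          time_aas80 = t80$time_min, aas80_reached = t80$reached,
          time_fas3 = tf3$time_min, fas3_reached = tf3$reached,
          stringsAsFactors = FALSE)
      }
    }
  }
  recovery_times <- if (length(recovery_times)) {
    do.call(rbind, recovery_times)
  }

  habitat <- NULL
  vulnerability <- NULL
  ctmax <- NULL
  if (any(!is.na(profiles$ctmax_c))) {
    ambient <- unlist(config$ambient_treatments)
    ctmax <- ctmax_summary(profiles, ambient = ambient %||% character(0))
  }
  if (!is.null(inputs$habitat)) {
    habitat <- lapply(inputs$habitat, summarize_habitat)
    pops <- unique(profiles$population)
    get_h <- function(pop) {
      h <- habitat[[pop]] %||% (if (length(habitat) == 1) habitat[[1]])
      if (is.null(h)) NA_real_ else h$max_temp
    }
    amb_ct <- vapply(pops, function(pop) {
      if (is.null(ctmax)) return(NA_real_)
      ct <- ctmax[ctmax$population == pop & ctmax$is_ambient, , drop = FALSE]
      if (nrow(ct)) ct$mean[1] else NA_real_
    }, numeric(1))
    get_fit <- function(lst, pop, field) {
      f <- lst[[pop]]
      if (is.null(f)) NA_real_ else f[[field]]
    }
    vulnerability <- vulnerability_report(
      populations = pops,
      t_opt = vapply(pops, function(p) {
        f <- tpc[[p]]; if (is.null(f) || !f$valid) NA_real_ else f$t_opt
      }, numeric(1)),
      t_pej_lower = vapply(pops, function(p) {
        f <- tpc[[p]]; if (is.null(f) || !f$valid) NA_real_ else f$t_pej[1]
      }, numeric(1)),
      t_pej_upper = vapply(pops, function(p) {
        f <- tpc[[p]]; if (is.null(f) || !f$valid) NA_real_ else f$t_pej[2]
      }, numeric(1)),
      t_fas3 = vapply(pops, function(p) {
        f <- fas[[p]]; if (is.null(f) || !f$defined) NA_real_ else f$t_fas3
      }, numeric(1)),
      ctmax_ambient = amb_ct,
      max_stream_temp = vapply(pops, get_h, numeric(1))
    )
  }

  exclusions <- if (length(exclusions)) {
    do.call(rbind, exclusions)
  } else {
    data.frame(unit = character(0), id = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(exclusions))) {
    message(sprintf("excluded %s %s: %s", exclusions$unit[k],
                    exclusions$id[k], exclusions$rule[k]))
  }

  structure(list(
    profiles = profiles, rmr_bins = rmr_bins, group_summary = group_summary,
    tpc = tpc, fas = fas, rmr_fit = rmr_fit,
    recovery_fits = recovery_fits, recovery_times = recovery_times,
    habitat = habitat, ctmax = ctmax, vulnerability = vulnerability,
    exclusions = exclusions,
    scaling = list(b_rmr = b_rmr, b_mmr = b_mmr),
    config = config, truth = inputs$truth
  ), class = "scope_report")
}

# Data-driven scaling exponent: log-log regression of raw whole-animal RMR
# MO2 (mean over QC-passing cycles after the settling discard) on body mass.
estimate_scaling_from_cycles <- function(cycles, metadata, qc) {
  keep <- cycles$qc_pass & cycles$start_min >= qc$settle_discard_min
  cyc <- cycles[keep, , drop = FALSE]
  idx <- match(cyc$fish_id, metadata$fish_id)
  raw <- abs(cyc$slope) * (metadata$chamber_volume_l[idx] -
                             metadata$mass_kg[idx])
  per_fish <- tapply(raw, cyc$fish_id, mean)
  mass <- metadata$mass_kg[match(names(per_fish), metadata$fish_id)]
  est <- estimate_scaling_exponent(as.numeric(per_fish), mass)
  list(b_rmr = est$b, r2 = est$r2, n = est$n)
}

#' @export
print.scope_report <- function(x, ...) {
  cat("Aerobic scope / thermal vulnerability report\n")
  cat(sprintf("  %d fish profiled across %d population x treatment groups\n",
              nrow(x$profiles),
              nrow(unique(x$profiles[, c("population", "treatment")]))))
  cat(sprintf("  %d QC exclusions logged\n", nrow(x$exclusions)))
  if (!is.null(x$vulnerability)) {
    cat("\nVulnerability report:\n")
    print(x$vulnerability, digits = 3)
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits CSV tables (profiles, RMR bins, group summary, recovery times,
#' vulnerability, exclusion log), a machine-readable JSON sidecar of all
#' fit parameters, and the configuration as YAML.
#'
#' @param report A `scope_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  w(report$profiles, "profiles.csv")
  w(report$rmr_bins, "rmr_bins.csv")
  w(report$group_summary, "group_summary.csv")
  w(report$recovery_times, "recovery_times.csv")
  w(report$vulnerability, "vulnerability.csv")
  w(report$exclusions, "exclusions.csv")
  fits <- list(
    scaling = report$scaling,
    tpc = lapply(report$tpc, function(f) if (!is.null(f))
      list(coefficients = as.list(f$coefficients), valid = f$valid,
           t_opt = f$t_opt, peak = f$peak, t_pej = f$t_pej, r2 = f$r2,
           n = f$n)),
    fas = lapply(report$fas, function(f) if (!is.null(f))
      list(b0 = f$b0, b1 = f$b1, t_fas3 = f$t_fas3, defined = f$defined,
           extrapolated = f$extrapolated, r2 = f$r2, n = f$n)),
    rmr = lapply(report$rmr_fit, function(f) if (!is.null(f))
      list(intercept = f$intercept, k = f$k, q10 = f$q10, r2 = f$r2,
           n = f$n)),
    recovery = lapply(report$recovery_fits, function(f)
      list(A = f$A, alpha = f$alpha, B = f$B, beta = f$beta, rmr = f$rmr,
           n_points = f$n_points, n_fish = f$n_fish))
  )
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_config(report$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
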