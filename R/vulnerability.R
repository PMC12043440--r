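# Habitat temperature summaries, CTmax aggregation, and the two
# climate-vulnerability indices: thermal safety margin (TSM) and functional
# warming tolerance (FWT).

#' Summarize a habitat temperature-logger series
#'
#' Calendar-day aggregation of an hourly stream temperature record: daily
#' mean/min/max/range, the overall maximum with its timestamp, the annual
#' range, and the largest daily range within the summer months (June to
#' August). Readings below `low_temp_mask` can optionally be dropped
#' (loggers may read unreliably near freezing); masking is off by default.
#'
#' @param series Data frame with `timestamp` (POSIXct, sorted) and `temp_c`.
#' @param low_temp_mask Optional temperature floor (degrees C); readings
#'   strictly below it are discarded before summarizing. NULL (default)
#'   keeps everything.
#' @return List of class `habitat_summary`: `max_temp`, `max_timestamp`,
#'   `annual_range`, `summer_max_daily_range` (NA when no summer days),
#'   `daily` (data frame: `date`, `mean`, `min`, `max`, `range`), `n_days`,
#'   `n_readings`.
#' @export
summarize_habitat <- function(series, low_temp_mask = NULL) {
  stopifnot_cols(series, c("timestamp", "temp_c"), "habitat series")
  if (nrow(series) == 0) stop("empty temperature series")
  if (is.unsorted(as.numeric(series$timestamp))) {
    stop("timestamps must be sorted")
  }
  if (!is.null(low_temp_mask)) {
    series <- series[series$temp_c >= low_temp_mask, , drop = FALSE]
    if (nrow(series) == 0) stop("no readings remain after low-temperature mask")
  }
  date <- as.Date(series$timestamp, tz = "UTC")
  if (length(unique(date)) < 1) stop("need at least one full day of readings")
  daily <- data.frame(
    date = as.Date(names(tapply(series$temp_c, date, mean)), tz = "UTC"),
    mean = as.numeric(tapply(series$temp_c, date, mean)),
    min = as.numeric(tapply(series$temp_c, date, min)),
    max = as.numeric(tapply(series$temp_c, date, max))
  )
  daily$range <- daily$max - daily$min
  imax <- which.max(series$temp_c)
  summer <- daily[format(daily$date, "%m") %in% c("06", "07", "08"), ,
                  drop = FALSE]
  structure(list(
    max_temp = series$temp_c[imax],
    max_timestamp = series$timestamp[imax],
    annual_range = max(series$temp_c) - min(series$temp_c),
    summer_max_daily_range = if (nrow(summer)) max(summer$range) else NA_real_,
    daily = daily, n_days = nrow(daily), n_readings = nrow(series)
  ), class = "habitat_summary")
}

#' @export
print.habitat_summary <- function(x, ...) {
  cat(sprintf(
    "Habitat temperature summary: %d readings over %d days\n  max %.1f C at %s; annual range %.1f C; max summer daily range %s C\n",
    x$n_readings, x$n_days, x$max_temp, format(x$max_timestamp),
    ifelse(is.na(x$summer_max_daily_range), "NA",
           sprintf("%.1f", x$summer_max_daily_range))))
  invisible(x)
}

#' Summarize critical thermal maxima by population and treatment
#'
#' Group mean, SEM and n of CTmax (temperature at loss of equilibrium), plus
#' each treatment's difference from the population's ambient treatment
#' (plasticity deltas). Hypothesis testing is left to the user.
#'
#' @param records Data frame with `population`, `treatment`, `ctmax_c`.
#' @param ambient Named character vector mapping population to its ambient
#'   treatment label; unnamed populations default to their first treatment
#'   (in order of appearance).
#' @return Data frame: `population`, `treatment`, `mean`, `sem`, `n`,
#'   `is_ambient`, `delta_vs_ambient`.
#' @export
ctmax_summary <- function(records, ambient = character(0)) {
  stopifnot_cols(records, c("population", "treatment", "ctmax_c"), "records")
  records <- records[!is.na(records$ctmax_c), , drop = FALSE]
  if (nrow(records) == 0) stop("no CTmax values")
  rows <- lapply(split(records, records$population), function(g) {
    amb <- if (g$population[1] %in% names(ambient)) {
      ambient[[g$population[1]]]
    } else {
      g$treatment[1]
    }
    per <- lapply(split(g, g$treatment), function(h) {
      data.frame(population = h$population[1], treatment = h$treatment[1],
                 mean = mean(h$ctmax_c), sem = sem(h$ctmax_c),
                 n = nrow(h), stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    per$is_ambient <- per$treatment == amb
    base <- per$mean[per$is_ambient][1]
    per$delta_vs_ambient <- per$mean - base
    per
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Thermal safety margin
#'
#' TSM = mean ambient-acclimatized CTmax minus the maximum measured stream
#' temperature. Positive values are the warming buffer before lethal limits
#' are reached.
#'
#' @param ctmax_ambient Mean CTmax at ambient holding temperatures (degrees C).
#' @param max_stream_temp Maximum measured stream temperature (degrees C).
#' @return TSM in degrees C (vectorized).
#' @export
compute_tsm <- function(ctmax_ambient, max_stream_temp) {
  ctmax_ambient - max_stream_temp
}

#' Functional warming tolerance
#'
#' FWT = T_FAS3 minus the maximum measured stream temperature. Negative
#' values mean the habitat already exceeds the temperature at which a
#' factorial aerobic scope of 3 remains available.
#'
#' @param t_fas3 Temperature where the fitted FAS line crosses 3 (degrees C);
#'   NA when the fit left it undefined.
#' @param max_stream_temp Maximum measured stream temperature (degrees C).
#' @return FWT in degrees C (vectorized; NA propagates).
#' @export
compute_fwt <- function(t_fas3, max_stream_temp) {
  t_fas3 - max_stream_temp
}

#' Assemble a per-population vulnerability report
#'
#' Combines thermal-performance parameters, ambient CTmax and habitat
#' maxima into one table with TSM and FWT. Fields from invalid upstream
#' fits stay NA.
#'
#' @param populations Character vector of population labels.
#' @param t_opt,t_pej_lower,t_pej_upper,t_fas3 Thermal-performance
#'   parameters per population (NA where undefined).
#' @param ctmax_ambient Mean ambient CTmax per population.
#' @param max_stream_temp Maximum stream temperature per population.
#' @return Data frame with one row per population and columns `population`,
#'   `t_opt`, `t_pej_lower`, `t_pej_upper`, `t_fas3`, `ctmax_ambient`,
#'   `max_stream_temp`, `tsm`, `fwt`.
#' @export
vulnerability_report <- function(populations, t_opt, t_pej_lower,
                                 t_pej_upper, t_fas3, ctmax_ambient,
                                 max_stream_temp) {
  data.frame(
    population = populations,
    t_opt = t_opt, t_pej_lower = t_pej_lower, t_pej_upper = t_pej_upper,
    t_fas3 = t_fas3, ctmax_ambient = ctmax_ambient,
    max_stream_temp = max_stream_temp,
    tsm = compute_tsm(ctmax_ambient, max_stream_temp),
    fwt = compute_fwt(t_fas3, max_stream_temp),
    stringsAsFactors = FALSE
  )
}

#' Published thermal-vulnerability reference values
#'
#' Loads the bundled population-level reference table for four Oregon
#' summer steelhead populations (field study): T_opt, pejus temperatures,
#' T_FAS3, mean ambient CTmax, maximum recorded stream temperature, and the
#' published TSM and FWT, plus the group mean MMR/RMR/AAS/FAS rows used in
#' the worked examples.
#'
#' @param which `"vulnerability"` (per-population thermal metrics) or
#'   `"scope"` (per-treatment group means of MMR, RMR, AAS, FAS).
#' @return A data frame.
#' @export
steelhead_reference <- function(which = c("vulnerability", "scope")) {
  which <- match.arg(which)
  file <- switch(which,
                 vulnerability = "steelhead_vulnerability.csv",
                 scope = "steelhead_scope_summary.csv")
  path <- system.file("extdata", file, package = "thermalscope")
  if (path == "") stop("bundled reference data not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
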