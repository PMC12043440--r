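# Run configuration (YAML) and tabular I/O for the three input dialects:
# respirometry traces, fish metadata, and habitat logger exports.

#' Default run configuration
#'
#' All quality-control and analysis constants with their standard defaults:
#' R^2 cutoff 0.9, fish-exclusion fraction 0.25, minimum 3 cycles per RMR
#' bin, 240-minute settling discard, scaling exponents 0.72 (RMR) and 0.74
#' (MMR), 120-second MMR window, and the recovery-solver settings. Nothing
#' in the computation paths hard-codes these values; they always flow from
#' the configuration.
#'
#' @return A nested named list; see the fields in the source for the full
#'   set. `paths` is NULL (simulate the default scenario) unless input CSV
#'   paths are supplied.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    qc = list(
      r2_min = 0.9,
      max_fail_fraction = 0.25,
      min_bin_n = 3L,
      settle_discard_min = 240,
      runs_test = FALSE,
      runs_alpha = 0.01
    ),
    scaling = list(
      b_rmr = 0.72,
      b_mmr = 0.74,
      estimate_from_data = FALSE
    ),
    mmr = list(window_s = 120),
    scope = list(chase_bin_fallback = FALSE),
    recovery = list(
      t_split_min = 20,
      max_time_min = 600,
      interpretation = "available"
    ),
    blank_slope = 0,
    ambient_treatments = list(),
    paths = NULL,
    scenario = "default"
  )
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user, keep.null = TRUE)
}

#' Write a run configuration to a YAML file
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

parse_iso_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%m/%d/%y %I:%M:%S %p", "%m/%d/%Y %H:%M"))
  if (anyNA(out)) stop("unparseable timestamps in input")
  out
}

#' Read a respirometry trace CSV
#'
#' Expected columns: `fish_id`, `cycle_id`, `phase` (measure/flush),
#' `timestamp` (ISO-8601), `o2_mg_per_l`, `temp_c`.
#' @param path CSV path.
#' @return Trace data frame with parsed timestamps.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("fish_id", "cycle_id", "phase", "timestamp",
                       "o2_mg_per_l", "temp_c"), basename(path))
  df$timestamp <- parse_iso_time(df$timestamp)
  df
}

#' Write a respirometry trace CSV
#' @param trace Trace data frame.
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  trace$timestamp <- format(trace$timestamp, "%Y-%m-%dT%H:%M:%OS1",
                            tz = "UTC")
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a fish metadata CSV
#'
#' Expected columns: `fish_id`, `population`, `treatment`, `mass_kg`,
#' `chamber_volume_l`, `chase_temp_c`, `ctmax_c` (optional values may be NA).
#' @param path CSV path.
#' @return Metadata data frame.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("fish_id", "population", "treatment", "mass_kg",
                       "chamber_volume_l", "chase_temp_c"), basename(path))
  if (!"ctmax_c" %in% names(df)) df$ctmax_c <- NA_real_
  df
}

#' Write a fish metadata CSV
#' @param metadata Metadata data frame.
#' @param path Output path.
#' @export
write_metadata_csv <- function(metadata, path) {
  cols <- c("fish_id", "population", "treatment", "mass_kg",
            "chamber_volume_l", "chase_temp_c", "ctmax_c")
  utils::write.csv(metadata[, intersect(cols, names(metadata))], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a habitat temperature-logger CSV
#'
#' Tolerates logger-export preamble rows (plot titles, serial numbers): the
#' first row whose fields contain both a timestamp-like and a
#' temperature-like header is taken as the header. Column names are matched
#' loosely (`timestamp`/`date`...`, `temp`...).
#'
#' @param path CSV path.
#' @return Data frame with `timestamp` (POSIXct) and `temp_c`.
#' @export
read_habitat_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  is_header <- vapply(lines, function(l) {
    f <- tolower(strsplit(l, ",")[[1]])
    any(grepl("time|date", f)) && any(grepl("temp", f))
  }, logical(1))
  if (!any(is_header)) stop("no header row with timestamp and temperature columns found")
  skip <- which(is_header)[1] - 1L
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                        check.names = FALSE)
  tcol <- grep("time|date", tolower(names(df)))[1]
  ccol <- grep("temp", tolower(names(df)))[1]
  if (is.na(tcol) || is.na(ccol)) stop("could not locate timestamp/temperature columns")
  out <- data.frame(timestamp = parse_iso_time(df[[tcol]]),
                    temp_c = as.numeric(df[[ccol]]))
  out[order(out$timestamp), , drop = FALSE]
}

#' Write a habitat temperature CSV
#' @param series Data frame with `timestamp`, `temp_c`.
#' @param path Output path.
#' @export
write_habitat_csv <- function(series, path) {
  series$timestamp <- format(series$timestamp, "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read a post-exercise recovery series CSV
#'
#' Expected columns: `fish_id`, `time_min` (minutes since MMR), `mo2`.
#' @param path CSV path.
#' @return Recovery data frame.
#' @export
read_recovery_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("fish_id", "time_min", "mo2"), basename(path))
  df
}

#' Write a post-exercise recovery series CSV
#' @param recovery Recovery data frame.
#' @param path Output path.
#' @export
write_recovery_csv <- function(recovery, path) {
  utils::write.csv(recovery, path, row.names = FALSE)
  invisible(path)
}

#' Validate input files against the expected schemas
#'
#' Per-file column, type and plausibility checks: errors for missing or
#' non-numeric required columns, warnings for out-of-range temperatures
#' (outside -5 to 45 degrees C) and for mass columns that look like grams
#' (values above 1 where kilograms are expected).
#'
#' @param paths Named list with any of `traces`, `postchase`, `metadata`,
#'   `habitat`, `recovery`.
#' @return Data frame with columns `file`, `level` (`"error"`/`"warning"`/
#'   `"ok"`), `message`; one `ok` row per clean file.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  note <- function(file, level, message) {
    report[[length(report) + 1]] <<- data.frame(
      file = file, level = level, message = message, stringsAsFactors = FALSE)
  }
  check_numeric <- function(df, cols, file) {
    ok <- TRUE
    for (cl in cols) {
      if (!cl %in% names(df)) {
        note(file, "error", sprintf("missing required column '%s'", cl))
        ok <- FALSE
      } else if (!is.numeric(df[[cl]])) {
        note(file, "error", sprintf("column '%s' must be numeric", cl))
        ok <- FALSE
      }
    }
    ok
  }
  try_read <- function(path, reader, file) {
    tryCatch(reader(path), error = function(e) {
      note(file, "error", conditionMessage(e))
      NULL
    })
  }

  if (!is.null(paths$metadata)) {
    file <- basename(paths$metadata)
    df <- try_read(paths$metadata, function(p)
      utils::read.csv(p, stringsAsFactors = FALSE), file)
    if (!is.null(df)) {
      needed <- c("fish_id", "population", "treatment", "mass_kg",
                  "chamber_volume_l", "chase_temp_c")
      miss <- setdiff(needed, names(df))
      for (cl in miss) note(file, "error", sprintf("missing required column '%s'", cl))
      if (!length(miss)) {
        check_numeric(df, c("mass_kg", "chamber_volume_l", "chase_temp_c"), file)
        if (is.numeric(df$mass_kg) && any(df$mass_kg > 1, na.rm = TRUE)) {
          note(file, "warning",
               "mass_kg values above 1: masses may be in grams, kilograms expected")
        }
        if (is.numeric(df$chase_temp_c) &&
            any(df$chase_temp_c < -5 | df$chase_temp_c > 45, na.rm = TRUE)) {
          note(file, "warning", "chase_temp_c outside the plausible -5..45 C range")
        }
      }
    }
  }
  for (nm in c("traces", "postchase")) {
    if (is.null(paths[[nm]])) next
    file <- basename(paths[[nm]])
    df <- try_read(paths[[nm]], read_trace_csv, file)
    if (!is.null(df)) {
      check_numeric(df, c("o2_mg_per_l", "temp_c"), file)
      if (any(df$temp_c < -5 | df$temp_c > 45, na.rm = TRUE)) {
        note(file, "warning", "temp_c outside the plausible -5..45 C range")
      }
      if (any(df$o2_mg_per_l < 0, na.rm = TRUE)) {
        note(file, "warning", "negative O2 concentrations")
      }
    }
  }
  for (hp in unlist(paths$habitat)) {
    file <- basename(hp)
    df <- try_read(hp, read_habitat_csv, file)
    if (!is.null(df) && any(df$temp_c < -5 | df$temp_c > 45, na.rm = TRUE)) {
      note(file, "warning", "temp_c outside the plausible -5..45 C range")
    }
  }
  if (!is.null(paths$recovery)) {
    file <- basename(paths$recovery)
    df <- try_read(paths$recovery, read_recovery_csv, file)
    if (!is.null(df)) check_numeric(df, c("time_min", "mo2"), file)
  }

  files <- basename(unlist(paths))
  out <- if (length(report)) do.call(rbind, report) else
    data.frame(file = character(0), level = character(0),
               message = character(0), stringsAsFactors = FALSE)
  for (f in files) {
    if (!f %in% out$file[out$level %in% c("error", "warning")]) {
      out <- rbind(out, data.frame(file = f, level = "ok",
                                   message = "schema checks passed",
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
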