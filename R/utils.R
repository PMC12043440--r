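#' @keywords internal
"_PACKAGE"

# Round half away from zero (19.5 -> 20, -19.5 -> -20). base::round() rounds
# half to even, which would bin 0.5-degree cycle means inconsistently.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Closed-form OLS of y on x. Returns slope, intercept, r2.
# r2 is NA when y has zero variance (degenerate fit).
ols_line <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  den <- n * sxx - sx * sx
  if (den <= 0) stop("zero variance in predictor: cannot fit a slope")
  slope <- (n * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / n
  ss_tot <- sum((y - sy / n)^2)
  if (ss_tot <= 0) {
    r2 <- NA_real_
  } else {
    resid <- y - intercept - slope * x
    r2 <- 1 - sum(resid^2) / ss_tot
  }
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
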