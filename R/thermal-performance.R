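# Thermal performance of aerobic scope: quadratic TPC for AAS (T_opt,
# T_pejus), linear FAS-temperature relationship (T_FAS3), and the
# exponential RMR-temperature response.

#' Fit a quadratic thermal performance curve to absolute aerobic scope
#'
#' Least-squares quadratic AAS = c0 + c1 T + c2 T^2 on individual-fish
#' points (never group means). For a concave fit (c2 < 0) the optimum is
#' T_opt = -c1 / (2 c2) with peak AAS evaluated there, and the pejus
#' temperatures - the bounds of the region where at least 80% of peak AAS
#' remains available - are T_opt +/- sqrt(0.2 peak / |c2|). Curvature with
#' |c2| below `c2_tol` is treated as flat: the fit is flagged invalid and no
#' optimum or pejus temperatures are produced.
#'
#' @param temp_c Chase temperatures (degrees C), one per fish.
#' @param aas Absolute aerobic scope values (mg O2 kg^-1 h^-1).
#' @param c2_tol Minimum |c2| for a usable curvature (default 1e-6).
#' @return An object of class `tpc_fit`: coefficients `c0`, `c1`, `c2`,
#'   `valid`, `t_opt`, `peak`, `t_pej` (length-2, lower/upper), `r2`, `n`,
#'   `temp_range`, and the underlying `lm` fit.
#' @seealso [predict.tpc_fit()], [fit_fas_line()]
#' @export
fit_aas_tpc <- function(temp_c, aas, c2_tol = 1e-6) {
  if (length(temp_c) != length(aas)) stop("inputs must have equal length")
  ok <- !is.na(temp_c) & !is.na(aas)
  temp_c <- temp_c[ok]; aas <- aas[ok]
  if (length(unique(temp_c)) < 3) {
    stop("need at least 3 distinct temperatures for a quadratic fit")
  }
  fit <- stats::lm(aas ~ temp_c + I(temp_c^2))
  cf <- unname(stats::coef(fit))
  c0 <- cf[1]; c1 <- cf[2]; c2 <- cf[3]
  valid <- is.finite(c2) && c2 < -c2_tol
  if (valid) {
    t_opt <- -c1 / (2 * c2)
    peak <- c0 + c1 * t_opt + c2 * t_opt^2
    half_width <- sqrt(0.2 * peak / abs(c2))
    t_pej <- c(t_opt - half_width, t_opt + half_width)
  } else {
    t_opt <- NA_real_; peak <- NA_real_; t_pej <- c(NA_real_, NA_real_)
  }
  structure(list(
    coefficients = c(c0 = c0, c1 = c1, c2 = c2),
    valid = valid, t_opt = t_opt, peak = peak, t_pej = t_pej,
    r2 = suppressWarnings(summary(fit)$r.squared), n = length(aas),
    temp_range = range(temp_c), lm = fit
  ), class = "tpc_fit")
}

#' @export
coef.tpc_fit <- function(object, ...) object$coefficients

#' Predict AAS from a fitted thermal performance curve
#' @param object A `tpc_fit`.
#' @param temp_c Temperatures (degrees C) at which to evaluate the curve.
#' @param ... Unused.
#' @export
predict.tpc_fit <- function(object, temp_c, ...) {
  cf <- object$coefficients
  cf[["c0"]] + cf[["c1"]] * temp_c + cf[["c2"]] * temp_c^2
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("Quadratic thermal performance curve for AAS (n =", x$n, "fish)\n")
  cat(sprintf("  AAS = %.4g + %.4g T + %.4g T^2   (R^2 = %.3f)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3], x$r2))
  if (x$valid) {
    cat(sprintf("  T_opt = %.2f C, peak AAS = %.2f, T_pej = [%.2f, %.2f] C\n",
                x$t_opt, x$peak, x$t_pej[1], x$t_pej[2]))
  } else {
    cat("  curvature not concave: flat TPC, no T_opt / T_pej extracted\n")
  }
  invisible(x)
}

#' Fit the linear FAS-temperature relationship and locate T_FAS3
#'
#' Ordinary least squares of factorial aerobic scope on temperature across
#' individual fish: FAS = b0 + b1 T. For a declining relationship (b1 < 0),
#' T_FAS3 = (3 - b0) / b1 is the temperature at which the fitted line
#' crosses FAS = 3 (the threshold for digestion with concurrent activity).
#' A non-negative slope leaves T_FAS3 undefined (flagged, no error). When
#' T_FAS3 falls outside the tested temperature span the result is flagged
#' as an extrapolation.
#'
#' @param temp_c Chase temperatures (degrees C), one per fish.
#' @param fas Factorial aerobic scope values.
#' @return An object of class `fas_fit`: `b0`, `b1`, `t_fas3` (NA when the
#'   slope is non-negative), `defined`, `extrapolated`, `r2`, `n`,
#'   `temp_range`, and the underlying `lm` fit.
#' @export
fit_fas_line <- function(temp_c, fas) {
  if (length(temp_c) != length(fas)) stop("inputs must have equal length")
  ok <- !is.na(temp_c) & !is.na(fas)
  temp_c <- temp_c[ok]; fas <- fas[ok]
  if (length(unique(temp_c)) < 2) {
    stop("need at least 2 distinct temperatures for a linear fit")
  }
  fit <- stats::lm(fas ~ temp_c)
  cf <- unname(stats::coef(fit))
  b0 <- cf[1]; b1 <- cf[2]
  defined <- is.finite(b1) && b1 < 0
  t_fas3 <- if (defined) (3 - b0) / b1 else NA_real_
  extrapolated <- defined &&
    (t_fas3 < min(temp_c) || t_fas3 > max(temp_c))
  if (extrapolated) {
    warning(sprintf(
      "T_FAS3 (%.1f C) lies outside the tested span [%.1f, %.1f] C: extrapolation",
      t_fas3, min(temp_c), max(temp_c)))
  }
  structure(list(
    b0 = b0, b1 = b1, t_fas3 = t_fas3, defined = defined,
    extrapolated = extrapolated, r2 = suppressWarnings(summary(fit)$r.squared),
    n = length(fas), temp_range = range(temp_c), lm = fit
  ), class = "fas_fit")
}

#' @export
coef.fas_fit <- function(object, ...) c(b0 = object$b0, b1 = object$b1)

#' Predict FAS from a fitted FAS-temperature line
#' @param object A `fas_fit`.
#' @param temp_c Temperatures (degrees C).
#' @param ... Unused.
#' @export
predict.fas_fit <- function(object, temp_c, ...) {
  object$b0 + object$b1 * temp_c
}

#' @export
print.fas_fit <- function(x, ...) {
  cat("Linear FAS-temperature fit (n =", x$n, "fish)\n")
  cat(sprintf("  FAS = %.4g %+.4g T   (R^2 = %.3f)\n", x$b0, x$b1, x$r2))
  if (x$defined) {
    cat(sprintf("  T_FAS3 = %.2f C%s\n", x$t_fas3,
                if (x$extrapolated) "  [extrapolated beyond tested span]" else ""))
  } else {
    cat("  slope not negative: T_FAS3 undefined\n")
  }
  invisible(x)
}

#' Fit the exponential RMR-temperature response
#'
#' Log-linear least squares ln(RMR) = a + k T across temperature bins (a
#' fixed-effects description of the exponential rise of resting metabolism
#' with temperature). Returns the thermal coefficient k and the derived
#' Q10 = exp(10 k).
#'
#' @param temp_c Temperatures (degrees C).
#' @param rmr RMR values (mg O2 kg^-1 h^-1); must be positive.
#' @return List of class `rmr_exp_fit`: `intercept` (log scale), `k`,
#'   `q10`, `r2`, `n`.
#' @export
fit_rmr_exponential <- function(temp_c, rmr) {
  if (length(temp_c) != length(rmr)) stop("inputs must have equal length")
  if (any(rmr <= 0)) stop("RMR values must be positive for a log-linear fit")
  if (length(unique(temp_c)) < 2) stop("need at least 2 distinct temperatures")
  fit <- ols_line(temp_c, log(rmr))
  structure(list(intercept = fit$intercept, k = fit$slope,
                 q10 = exp(10 * fit$slope), r2 = fit$r2, n = length(rmr)),
            class = "rmr_exp_fit")
}

#' @export
print.rmr_exp_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential RMR-temperature fit: ln(RMR) = %.4g + %.4g T (Q10 = %.2f, R^2 = %.3f, n = %d)\n",
    x$intercept, x$k, x$q10, x$r2, x$n))
  invisible(x)
}
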