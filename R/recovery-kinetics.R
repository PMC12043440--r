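# Post-exercise recovery kinetics: group-level biexponential MO2 decay,
# MO2(t) = A exp(alpha t) + B exp(beta t) + RMR, and per-fish recovery-time
# solvers (Time_AAS80, Time_FAS3) by bisection to 0.1-second precision.

# Curve-peeling starting values: log-linear fit to the tail (t >= t_split)
# for the slow phase, then a log-linear fit of the fast-phase residual.
peel_start <- function(t, y, rmr, t_split) {
  slow <- t >= t_split & y > rmr
  B0 <- 1; beta0 <- -0.02
  if (sum(slow) >= 2 && length(unique(t[slow])) >= 2) {
    f <- ols_line(t[slow], log(y[slow] - rmr))
    if (is.finite(f$slope) && f$slope < 0) {
      beta0 <- f$slope; B0 <- exp(f$intercept)
    }
  }
  res <- y - B0 * exp(beta0 * t) - rmr
  fast <- t < t_split & res > 0
  A0 <- max(y) - rmr - B0; alpha0 <- min(5 * beta0, -0.1)
  if (sum(fast) >= 2 && length(unique(t[fast])) >= 2) {
    f <- ols_line(t[fast], log(res[fast]))
    if (is.finite(f$slope) && f$slope < 0) {
      alpha0 <- f$slope; A0 <- exp(f$intercept)
    }
  }
  amp <- max(max(y) - rmr, 1e-2)
  c(A = max(A0, 0.05 * amp), alpha = min(alpha0, beta0 * 1.5),
    B = max(B0, 0.05 * amp), beta = beta0)
}

#' Fit a biexponential post-exercise recovery model
#'
#' Nonlinear least squares for MO2(t) = A exp(alpha t) + B exp(beta t) + RMR
#' on MO2 observations pooled across the fish of one population x
#' temperature group, with the asymptote fixed at the group mean resting
#' rate. Parameters are initialized by curve peeling and estimated by
#' bounded Levenberg-Marquardt (A, B >= 0; alpha, beta < 0), with jittered
#' restarts on failure; phases are ordered so alpha < beta (the first phase
#' is the fast one).
#'
#' @param time_min Minutes since the maximum (MMR at t = 0).
#' @param mo2 MO2 observations (mg O2 kg^-1 h^-1, scaled), pooled across fish.
#' @param rmr_group Fixed asymptote: mean RMR_chase of the group.
#' @param t_split Peeling split between fast and slow phases (minutes).
#' @param max_restarts Jittered restarts before giving up.
#' @param label Optional group label carried on the fit.
#' @param n_fish Optional number of fish pooled (metadata only).
#' @return Object of class `recovery_fit` with elements `A`, `alpha`, `B`,
#'   `beta`, `rmr`, `n_points`, `n_fish`, `label`, `rss`, `converged`, and
#'   the underlying `nls` object.
#' @export
fit_recovery <- function(time_min, mo2, rmr_group, t_split = 20,
                         max_restarts = 5, label = NULL, n_fish = NA_integer_) {
  if (length(time_min) != length(mo2)) stop("inputs must have equal length")
  if (any(time_min < 0)) stop("time_min must be >= 0 (MMR at t = 0)")
  if (length(time_min) < 8) stop("need at least 8 (time, MO2) points")
  dat <- data.frame(t = time_min, y = mo2)
  start <- peel_start(dat$t, dat$y, rmr_group, t_split)
  lower <- c(A = 0, alpha = -50, B = 0, beta = -50)
  upper <- c(A = Inf, alpha = -1e-8, B = Inf, beta = -1e-8)

  fit <- NULL
  for (attempt in 0:max_restarts) {
    st <- start
    if (attempt > 0) {
      jit <- with_seed(attempt, stats::runif(4, 0.5, 1.8))
      st <- c(A = st[["A"]] * jit[1], alpha = st[["alpha"]] * jit[2],
              B = st[["B"]] * jit[3], beta = st[["beta"]] * jit[4])
    }
    st["alpha"] <- min(st[["alpha"]], st[["beta"]] * 1.01 - 1e-6)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ A * exp(alpha * t) + B * exp(beta * t) + rmr_group,
        data = dat, start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  single <- FALSE
  if (is.null(fit)) {
    # nested single-phase limit: when one amplitude sits on its zero bound
    # the paired rate is unidentifiable and the full model can be singular;
    # fall back to A exp(alpha t) + rmr
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ A * exp(alpha * t) + rmr_group,
        data = dat, start = list(A = start[["B"]], alpha = start[["beta"]]),
        lower = c(A = 0, alpha = -50), upper = c(A = Inf, alpha = -1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    single <- !is.null(fit)
  }
  if (is.null(fit)) {
    stop("biexponential fit failed to converge after bounded restarts")
  }
  cf <- stats::coef(fit)
  if (single) {
    cf <- c(A = cf[["A"]], alpha = cf[["alpha"]], B = 0,
            beta = cf[["alpha"]] / 2)
  }
  # phase labels are interchangeable in the model: order so alpha < beta
  if (cf[["alpha"]] > cf[["beta"]]) {
    cf <- c(A = cf[["B"]], alpha = cf[["beta"]],
            B = cf[["A"]], beta = cf[["alpha"]])
  }
  structure(list(
    A = cf[["A"]], alpha = cf[["alpha"]], B = cf[["B"]], beta = cf[["beta"]],
    rmr = rmr_group, n_points = nrow(dat), n_fish = n_fish, label = label,
    rss = sum(stats::residuals(fit)^2), converged = TRUE, nls = fit
  ), class = "recovery_fit")
}

#' @export
coef.recovery_fit <- function(object, ...) {
  c(A = object$A, alpha = object$alpha, B = object$B, beta = object$beta,
    rmr = object$rmr)
}

#' Predict MO2 from a fitted recovery model
#' @param object A `recovery_fit`.
#' @param time_min Minutes since MMR.
#' @param rmr Optional replacement asymptote (an individual fish's
#'   RMR_chase); defaults to the group asymptote the model was fit with.
#' @param ... Unused.
#' @export
predict.recovery_fit <- function(object, time_min, rmr = object$rmr, ...) {
  biexp_rate(time_min, object$A, object$alpha, object$B, object$beta, rmr)
}

#' @export
print.recovery_fit <- function(x, ...) {
  if (!is.null(x$label)) cat("Group:", x$label, "\n")
  cat(sprintf(
    "Biexponential recovery fit (n = %d points%s)\n  MO2(t) = %.3f e^(%.4f t) + %.3f e^(%.4f t) + %.3f\n",
    x$n_points,
    if (is.na(x$n_fish)) "" else sprintf(", %d fish", x$n_fish),
    x$A, x$alpha, x$B, x$beta, x$rmr))
  cat(sprintf("  MO2(0) = %.3f, RSS = %.4g\n", x$A + x$B + x$rmr, x$rss))
  invisible(x)
}

# Solve A e^(alpha t) + B e^(beta t) + rmr = threshold for t >= 0 by
# bisection; the curve is strictly decreasing, so the crossing is unique.
# Returns minutes rounded to the nearest 0.1 second, or a not-reached flag.
solve_recovery_time <- function(fit, rmr, threshold, max_time_min = 600) {
  f <- function(t) biexp_rate(t, fit$A, fit$alpha, fit$B, fit$beta, rmr)
  if (threshold <= rmr) {
    return(list(time_min = NA_real_, reached = FALSE, threshold = threshold))
  }
  if (f(0) <= threshold) {
    return(list(time_min = 0, reached = TRUE, threshold = threshold))
  }
  if (f(max_time_min) > threshold) {
    return(list(time_min = NA_real_, reached = FALSE, threshold = threshold))
  }
  lo <- 0; hi <- max_time_min
  while (hi - lo > 1e-4) {                 # converge well below 0.1 s
    mid <- (lo + hi) / 2
    if (f(mid) > threshold) lo <- mid else hi <- mid
  }
  list(time_min = round((lo + hi) / 2 * 600) / 600, reached = TRUE,
       threshold = threshold)
}

#' Time until 80% of aerobic scope is available (Time_AAS80)
#'
#' Solves the group recovery model - with the asymptote replaced by the
#' individual fish's RMR_chase - for the time at which MO2 has fallen to
#' the level where 80% of the fish's AAS is available again. Under the
#' default interpretation that level is MO2* = RMR_chase + 0.2 AAS
#' (MMR - MO2 = 0.8 AAS); `interpretation = "literal"` instead uses
#' MO2* = 0.8 AAS. Times are rounded to the nearest 0.1 second and may
#' extend beyond the measured record; a fish already below the threshold at
#' t = 0 gets 0.
#'
#' @param fit A `recovery_fit`.
#' @param rmr_chase The fish's own RMR at the chase temperature.
#' @param aas The fish's absolute aerobic scope.
#' @param interpretation Threshold convention (see Details).
#' @param max_time_min Solver bracket upper end (minutes); beyond it the
#'   threshold is reported as not reached.
#' @return List with `time_min`, `reached`, `threshold`.
#' @export
solve_time_aas80 <- function(fit, rmr_chase, aas,
                             interpretation = c("available", "literal"),
                             max_time_min = 600) {
  interpretation <- match.arg(interpretation)
  threshold <- switch(interpretation,
                      available = rmr_chase + 0.2 * aas,
                      literal = 0.8 * aas)
  solve_recovery_time(fit, rmr_chase, threshold, max_time_min)
}

#' Time until a factorial aerobic scope of 3 is available (Time_FAS3)
#'
#' Solves the group recovery model (asymptote replaced by the fish's
#' RMR_chase) for the time at which MMR / MO2 = 3, i.e. MO2* = MMR / 3.
#' When MMR / 3 does not exceed the fish's RMR_chase the threshold is
#' unreachable and the not-reached flag is returned (the warm-temperature
#' "n/a" case).
#'
#' @inheritParams solve_time_aas80
#' @param mmr The fish's maximum metabolic rate.
#' @return List with `time_min`, `reached`, `threshold`.
#' @export
solve_time_fas3 <- function(fit, rmr_chase, mmr, max_time_min = 600) {
  solve_recovery_time(fit, rmr_chase, mmr / 3, max_time_min)
}
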