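# Residual-activity kinetics: assay slopes -> activities -> residual %
# series -> censoring of >100% "overstabilization" points -> first-order
# inactivation fit A_R(t) = A_R0 * exp(-k t) by Levenberg-Marquardt.

#' Volumetric enzyme activity from an absorbance slope
#'
#' Converts the NADH absorbance slope of a plate assay into activity
#' `A = slope * 1e6 / (epsilon * d)` in umol min^-1 dm^-3, where epsilon is
#' the NADH extinction coefficient at 340 nm and d the optical path length
#' of a well.
#'
#' @param slope Absorbance change per minute (min^-1).
#' @param epsilon Extinction coefficient (cm^2 mmol^-1), default 6220.
#' @param path_length Optical path (cm), default 0.61 for a 96-well plate.
#' @return Activity in umol min^-1 dm^-3.
#' @export
activity_from_slope <- function(slope, epsilon = 6220, path_length = 0.61) {
  if (any(epsilon <= 0) || any(path_length <= 0))
    stop("epsilon and path_length must be positive")
  slope * 1e6 / (epsilon * path_length)
}

#' Construct a residual-activity time series
#'
#' @param times Days since time zero (time zero is defined as 20 min after
#'   preparing the enzyme stock in the solvent); non-negative, strictly
#'   increasing.
#' @param residual Residual activity in % of the time-zero activity.
#' @param label Enzyme-by-solvent identifier.
#' @return Object of class `activity_series`.
#' @export
activity_series <- function(times, residual, label = "") {
  if (length(times) != length(residual))
    stop("times and residual must have the same length")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(residual)))
    stop("residual values must be finite")
  structure(list(times = as.numeric(times), residual = as.numeric(residual),
                 label = as.character(label)),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("activity series '%s': %d points over %.3g days\n",
              x$label, length(x$times), max(x$times)))
  invisible(x)
}

#' Residual-activity series from raw activities
#'
#' Expresses each activity as a percentage of the time-zero activity; the
#' time-zero entry is exactly 100 by definition.
#'
#' @param times Days since time zero.
#' @param activities Raw activities (any consistent unit).
#' @param t0_activity Activity at time zero (> 0).
#' @param label Series identifier.
#' @return An [activity_series()].
#' @export
residual_series <- function(times, activities, t0_activity, label = "") {
  if (!is.numeric(t0_activity) || length(t0_activity) != 1L || t0_activity <= 0)
    stop("t0_activity must be a single positive number")
  residual <- 100 * activities / t0_activity
  residual[times == 0] <- 100
  activity_series(times, residual, label = label)
}

#' Censor residual activities exceeding 100%
#'
#' Early residual activities in DES often overshoot 100% before decaying
#' ("overstabilization"); for a first-order model these points are omitted.
#' The time-zero point (exactly 100 by definition) is always retained.
#'
#' @param series An [activity_series()].
#' @param policy `"drop_over_100"` removes points with residual > 100 at
#'   t > 0; `"keep_all"` is a no-op.
#' @return The censored [activity_series()], with attributes `censored_n`
#'   (points removed) and `unfittable` (TRUE when fewer than 3 points
#'   remain).
#' @export
censor_series <- function(series, policy = c("drop_over_100", "keep_all")) {
  stopifnot(inherits(series, "activity_series"))
  policy <- match.arg(policy)
  if (policy == "keep_all") {
    attr(series, "censored_n") <- 0L
    attr(series, "unfittable") <- length(series$times) < 3L
    return(series)
  }
  drop <- series$residual > 100 & series$times > 0
  out <- activity_series(series$times[!drop], series$residual[!drop],
                         label = series$label)
  attr(out, "censored_n") <- sum(drop)
  attr(out, "unfittable") <- length(out$times) < 3L
  out
}

#' Fit the first-order inactivation model
#'
#' Nonlinear least squares of `A_R(t) = A_R0 * exp(-k t)` (k >= 0) by the
#' Levenberg-Marquardt algorithm, initialized from a log-linear regression
#' on the strictly positive residuals, with jittered restarts on failure.
#' Times are in days; k is reported both per day and per hour (k_per_h =
#' k_per_day / 24) since rate constants are conventionally quoted per hour
#' while sampling runs over days.
#'
#' A series that is zero from the second point onward decays faster than
#' the sampling cadence can resolve; rather than fail, the fit returns the
#' resolution-ceiling sentinel k = 51 h^-1 with flag
#' `"faster_than_resolvable"`.
#'
#' @param series An [activity_series()] (typically after [censor_series()]).
#' @param fix_intercept Fix A_R0 at 100 instead of fitting it. The default
#'   fits both parameters; the fixed-intercept mode is for sensitivity
#'   checks.
#' @param max_restarts Jittered re-initializations before giving up.
#' @return Object of class `inactivation_fit`: `k_per_day`, `k_per_h`,
#'   `A_R0`, `t_half_days`, `k_stderr_per_day`, `n_used`, `flags`.
#' @export
fit_first_order <- function(series, fix_intercept = FALSE, max_restarts = 5L) {
  stopifnot(inherits(series, "activity_series"))
  t <- series$times
  y <- series$residual
  n <- length(t)
  need <- if (fix_intercept) 2L else 3L
  if (n < need)
    stop("need at least ", need, " points to fit, got ", n)

  flags <- character(0)
  # all-zero beyond the first point: decay faster than the cadence resolves
  if (n >= 2L && all(y[-1L] == 0)) {
    k_h <- 51
    k_d <- k_h * 24
    return(structure(list(k_per_day = k_d, k_per_h = k_h,
                          A_R0 = y[1L], t_half_days = log(2) / k_d,
                          k_stderr_per_day = NA_real_, n_used = n,
                          flags = "faster_than_resolvable",
                          label = series$label),
                     class = "inactivation_fit"))
  }

  pos <- y > 0
  if (sum(pos) >= 2L) {
    lf <- stats::lm(log(y[pos]) ~ t[pos])
    k0 <- max(-unname(stats::coef(lf)[2L]), 1e-6)
    A0 <- exp(unname(stats::coef(lf)[1L]))
  } else {
    k0 <- 1
    A0 <- max(y, 1)
  }

  df <- data.frame(t = t, y = y)
  fit <- NULL
  for (attempt in 0:max_restarts) {
    jit <- if (attempt == 0) c(1, 1) else exp(stats::rnorm(2, 0, 0.3 * attempt))
    start_k <- k0 * jit[1L]
    start_A <- A0 * jit[2L]
    fit <- tryCatch({
      if (fix_intercept) {
        minpack.lm::nlsLM(y ~ 100 * exp(-k * t), data = df,
                          start = list(k = start_k), lower = c(k = 0),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200, ftol = 1e-10, ptol = 1e-10))
      } else {
        minpack.lm::nlsLM(y ~ A0 * exp(-k * t), data = df,
                          start = list(A0 = start_A, k = start_k),
                          lower = c(A0 = 0, k = 0),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200, ftol = 1e-10, ptol = 1e-10))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("first-order fit failed to converge after ", max_restarts,
         " restarts for '", series$label, "'")

  co <- stats::coef(fit)
  k_d <- unname(co[["k"]])
  A_R0 <- if (fix_intercept) 100 else unname(co[["A0"]])
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  if (k_d <= 0) flags <- c(flags, "no_decay")
  structure(list(k_per_day = k_d, k_per_h = k_d / 24, A_R0 = A_R0,
                 t_half_days = if (k_d > 0) log(2) / k_d else Inf,
                 k_stderr_per_day = se, n_used = n, flags = flags,
                 label = series$label),
            class = "inactivation_fit")
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf("first-order inactivation fit '%s':\n", x$label))
  cat(sprintf("  k = %.4g day^-1 (%.4g h^-1), A_R0 = %.4g%%, t1/2 = %.4g days, n = %d\n",
              x$k_per_day, x$k_per_h, x$A_R0, x$t_half_days, x$n_used))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Half-life of a first-order decay
#'
#' `t_1/2 = ln 2 / k`, returned in days regardless of the unit k is quoted
#' in: per-day rate constants divide ln 2 directly, per-hour rate constants
#' give hours which are converted to days explicitly (avoiding silent 24x
#' errors).
#'
#' @param k Rate constant, or an [inactivation_fit] (whose per-day k is
#'   used).
#' @param unit `"per_day"` or `"per_h"`, the unit `k` is expressed in.
#' @return Half-life in days; `Inf` for k = 0.
#' @export
half_life <- function(k, unit = c("per_day", "per_h")) {
  if (inherits(k, "inactivation_fit")) {
    k <- k$k_per_day
    unit <- "per_day"
  }
  unit <- match.arg(unit)
  if (any(k < 0)) stop("k must be non-negative")
  hl <- ifelse(k > 0, log(2) / k, Inf)
  if (unit == "per_h") hl <- hl / 24
  hl
}

#' Fit a table of residual-activity series
#'
#' Applies [censor_series()] and [fit_first_order()] per label of a long
#' table, the shape the stability screen produces.
#'
#' @param data Data frame with columns `label`, `time_days`,
#'   `residual_percent`.
#' @param policy Censoring policy, see [censor_series()].
#' @param fix_intercept Passed to [fit_first_order()].
#' @return Data frame: label, k_per_h, k_per_day, k_stderr_per_day, A_R0,
#'   t_half_days, n_used, censored_n, flags.
#' @export
fit_kinetics_table <- function(data, policy = "drop_over_100",
                               fix_intercept = FALSE) {
  need <- c("label", "time_days", "residual_percent")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(data, data$label), function(d) {
    d <- d[order(d$time_days), ]
    s <- activity_series(d$time_days, d$residual_percent, label = d$label[1L])
    s <- censor_series(s, policy = policy)
    if (isTRUE(attr(s, "unfittable")))
      return(data.frame(label = d$label[1L], k_per_h = NA_real_,
                        k_per_day = NA_real_, k_stderr_per_day = NA_real_,
                        A_R0 = NA_real_, t_half_days = NA_real_,
                        n_used = length(s$times),
                        censored_n = attr(s, "censored_n"),
                        flags = "unfittable", stringsAsFactors = FALSE))
    f <- fit_first_order(s, fix_intercept = fix_intercept)
    data.frame(label = f$label, k_per_h = f$k_per_h, k_per_day = f$k_per_day,
               k_stderr_per_day = f$k_stderr_per_day, A_R0 = f$A_R0,
               t_half_days = f$t_half_days, n_used = f$n_used,
               censored_n = attr(s, "censored_n"),
               flags = paste(f$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
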