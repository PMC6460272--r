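# First-order UV-inactivation kinetics: Nt = N0 * exp(-k * x), where x is
# exposure time (minutes, "time" mode) or total fluence T*b*H0*t ("fluence"
# mode).  The survival constant k is estimated by ordinary least squares on
# the log scale; k = -slope (time mode) or -slope / (T*b*H0) (fluence mode).
#
# The source equations for the pointwise solutions are printed with
# typographical errors (a spurious e^{-t} factor and a garbled inversion for
# t); the algebraically consistent inversion of the exponential decay law is
# implemented instead: k = -ln(Nt/N0) / x and t = ln(N0/Nt) / k.

#' Expected surviving population under first-order decay
#'
#' Evaluates \eqn{N_t = N_0 e^{-k t}} (time mode) or
#' \eqn{N_t = N_0 e^{-k H(t)}} with \eqn{H(t) = T b H_0 t} (fluence mode).
#'
#' @param n0 Initial (control) population, CFU (> 0).
#' @param k Survival constant (> 0); per minute in time mode, per fluence
#'   unit in fluence mode.
#' @param t Exposure time in minutes (>= 0); may be a vector.
#' @param mode `"time"` or `"fluence"`.
#' @param config An [irradiance_config()]; required in fluence mode.
#' @return Expected CFU, same length as `t`; equals `n0` at `t = 0` and is
#'   strictly decreasing in `t`.
#' @examples
#' predict_survival(2e7, 0.035, t = c(0, 15, 30, 45, 60))
#' @export
predict_survival <- function(n0, k, t, mode = c("time", "fluence"),
                             config = NULL) {
  mode <- check_mode(match.arg(mode))
  check_scalar_number(n0, "n0", 0, strict_lower = TRUE)
  check_scalar_number(k, "k", 0, strict_lower = TRUE)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    validation_error("'t' must be finite and non-negative")
  x <- if (mode == "fluence") {
    if (is.null(config))
      validation_error("fluence mode requires 'config'")
    total_fluence(config, t)
  } else t
  n0 * exp(-k * x)
}

#' Half-life of a population under first-order decay
#'
#' Time for the surviving population to halve: \eqn{t_{1/2} = \ln 2 / k}.
#' For the reported survival constant k = 0.035/min this is 19.80 min, i.e.
#' 0.33 hr.
#'
#' @param k Survival constant per minute (> 0).
#' @return Half-life in minutes.
#' @examples
#' half_life(0.035)        # 19.80 min
#' half_life(0.035) / 60   # 0.33 hr
#' @export
half_life <- function(k) {
  check_scalar_number(k, "k", 0, strict_lower = TRUE)
  log(2) / k
}

#' Exposure time needed to reduce the population to a threshold
#'
#' Inverts the first-order decay law: time mode returns
#' \eqn{\ln(N_0/N_t)/k}; fluence mode returns \eqn{\ln(N_0/N_t)/(k T b H_0)}.
#' Satisfies the round trip
#' `predict_survival(n0, k, time_to_threshold(...)) == nt`.
#'
#' The threshold must be strictly positive: under exponential decay the time
#' to reach zero survivors is infinite, so extinction questions should be
#' posed as "time to fewer than one CFU" (`nt = 1`).
#'
#' @param k Survival constant (> 0); per-minute in time mode.
#' @param n0 Initial population, CFU (> 0).
#' @param nt Threshold population, CFU, with `0 < nt < n0`.
#' @param mode `"time"` or `"fluence"`.
#' @param config An [irradiance_config()]; required in fluence mode.
#' @return Time in minutes.
#' @examples
#' time_to_threshold(0.035, n0 = 2e7, nt = 1e7)  # one half-life, 19.80 min
#' time_to_threshold(0.035, n0 = 2e7, nt = 1)    # ~480 min to the last CFU
#' @export
time_to_threshold <- function(k, n0, nt, mode = c("time", "fluence"),
                              config = NULL) {
  mode <- check_mode(match.arg(mode))
  check_scalar_number(k, "k", 0, strict_lower = TRUE)
  check_scalar_number(n0, "n0", 0, strict_lower = TRUE)
  if (!is.numeric(nt) || length(nt) != 1L || !is.finite(nt) || nt <= 0)
    validation_error(
      "'nt' must be > 0: extinction time is infinite under first-order decay")
  if (nt >= n0)
    validation_error("'nt' must be below 'n0': the model cannot grow")
  denom <- if (mode == "fluence") {
    if (is.null(config))
      validation_error("fluence mode requires 'config'")
    k * fluence_factor(config)
  } else k
  log(n0 / nt) / denom
}

#' Fit the first-order survival model to a series
#'
#' Ordinary least squares of \eqn{y_i = \ln(N_i / N_0)} against exposure time
#' (time mode) or total fluence (fluence mode).  Both slope and intercept are
#' fitted, so `r2` is the conventional coefficient of determination of the
#' log-linear regression.  `slope` is always reported in natural-log units
#' per minute; the survival constant is `k = -slope` (time mode, per minute)
#' or `k = -slope / (T b H0)` (fluence mode, per fluence unit).
#'
#' Zero counts are excluded (their logarithm is undefined; no substitution
#' constant is applied because any choice biases the slope) and recorded in
#' `excluded_zero_times`.  A non-negative fitted slope is reported with the
#' `non_decaying` flag set; `k` and `half_life_min` are then `NA`.
#'
#' @param series A [survival_series()].
#' @param config An [irradiance_config()]; required in fluence mode.
#' @param mode `"time"` (default: fluence absorbed into k, units /min) or
#'   `"fluence"`.
#' @return An object of class `"kinetics_fit"` with elements `k`, `slope`,
#'   `intercept`, `r2`, `half_life_min`, `mode`, `n_points_used`,
#'   `excluded_zero_times`, `non_decaying`.
#' @examples
#' s <- survival_series(c(0, 15, 30, 45, 60), c(200, 118, 70, 41, 24))
#' fit_survival(s)
#' @export
fit_survival <- function(series, config = NULL, mode = c("time", "fluence")) {
  mode <- check_mode(match.arg(mode))
  if (!inherits(series, "survival_series"))
    validation_error("'series' must be a survival_series")
  if (mode == "fluence" && is.null(config))
    validation_error("fluence mode requires 'config'")

  keep <- series$counts > 0
  times <- series$times[keep]
  counts <- series$counts[keep]
  excluded <- series$times[!keep]
  if (length(times) < 2L)
    numeric_error(sprintf(
      "need >= 2 positive-count observations to fit (have %d after excluding zero counts)",
      length(times)))

  x <- if (mode == "fluence") total_fluence(config, times) else times
  y <- log(counts / series$n0)
  fit <- lm(y ~ x)
  slope_x <- unname(coef(fit)[2])   # per x-unit (min or fluence unit)
  intercept <- unname(coef(fit)[1])
  r2 <- if (all(y == y[1])) {
    # zero total variance: a flat series is reproduced exactly
    1
  } else suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm

  # `slope` is always reported in natural-log units per minute; in fluence
  # mode k = -slope / (T*b*H0) is the per-fluence-unit survival constant
  ff <- if (mode == "fluence") fluence_factor(config) else 1
  slope <- slope_x * ff
  non_decaying <- slope >= 0
  k <- if (non_decaying) NA_real_ else -slope_x
  hl <- if (non_decaying) NA_real_ else log(2) / -slope

  structure(
    list(k = k, slope = slope, intercept = intercept, r2 = r2,
         half_life_min = hl, mode = mode,
         n_points_used = length(times),
         excluded_zero_times = as.numeric(excluded),
         non_decaying = non_decaying),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, digits = 4, ...) {
  cat(sprintf("First-order survival fit (%s mode)\n", x$mode))
  cat(sprintf("  slope (ln CFU per min): %s   r2: %s\n",
              format(x$slope, digits = digits),
              format(x$r2, digits = digits)))
  if (isTRUE(x$non_decaying)) {
    cat("  non-decaying series: survival constant not defined\n")
  } else {
    cat(sprintf("  survival constant k: %s %s\n",
                format(x$k, digits = digits),
                if (x$mode == "time") "/min" else "per fluence unit"))
    cat(sprintf("  half-life: %s min (%s hr)\n",
                format(x$half_life_min, digits = digits),
                format(x$half_life_min / 60, digits = digits)))
  }
  cat(sprintf("  points used: %d", x$n_points_used))
  if (length(x$excluded_zero_times))
    cat(sprintf("  (zero-count times excluded: %s)",
                paste(x$excluded_zero_times, collapse = ", ")))
  cat("\n")
  invisible(x)
}
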