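# Survival series: paired exposure times and CFU counts plus a control count.

#' Construct a survival series
#'
#' A survival series pairs strictly increasing exposure times (minutes) with
#' non-negative integer CFU counts, together with the unirradiated control
#' population `n0`.  When `n0` is omitted the series must start at time 0 and
#' that count is taken as an observation of the control population.
#'
#' @param times Numeric vector of exposure times in minutes, strictly
#'   increasing, first may be 0.
#' @param counts Integer-valued vector of CFU counts, same length as `times`.
#' @param n0 Positive control population (CFU).  Defaults to the count at
#'   `t = 0` when that row is present.
#' @param max_count Plate-countability ceiling; counts above it are rejected.
#' @return An object of class `"survival_series"`.
#' @examples
#' survival_series(c(0, 15, 30, 45, 60), c(200, 118, 70, 41, 24))
#' @export
survival_series <- function(times, counts, n0 = NULL, max_count = 1e9) {
  if (!is.numeric(times) || !is.numeric(counts))
    validation_error("'times' and 'counts' must be numeric")
  if (length(times) != length(counts))
    validation_error("'times' and 'counts' must have equal length")
  if (length(times) < 1L)
    validation_error("a survival series needs at least one observation")
  if (any(!is.finite(times)) || any(times < 0))
    validation_error("'times' must be finite and non-negative")
  if (any(diff(times) <= 0))
    validation_error("'times' must be strictly increasing")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad))
    validation_error(sprintf(
      "counts must be non-negative integers; offending row(s): %s",
      paste(bad, collapse = ", ")))
  if (!is.numeric(max_count) || length(max_count) != 1L || is.na(max_count) ||
      max_count <= 0)
    validation_error("'max_count' must be a single positive number (Inf allowed)")
  over <- which(counts > max_count)
  if (length(over))
    validation_error(sprintf(
      "count exceeds plate-countability ceiling %g at row(s): %s",
      max_count, paste(over, collapse = ", ")))
  if (is.null(n0)) {
    if (times[1] != 0)
      validation_error(
        "'n0' is required when the series has no t = 0 observation")
    if (counts[1] <= 0)
      validation_error("the t = 0 count used as 'n0' must be positive")
    n0 <- as.numeric(counts[1])
  }
  check_scalar_number(n0, "n0", 0, strict_lower = TRUE)
  structure(list(times = as.numeric(times), counts = as.numeric(counts),
                 n0 = n0),
            class = "survival_series")
}

#' @export
print.survival_series <- function(x, ...) {
  cat(sprintf("Survival series: %d observations, n0 = %g CFU\n",
              length(x$times), x$n0))
  print(data.frame(time_min = x$times, cfu = x$counts), row.names = FALSE)
  invisible(x)
}

#' @export
length.survival_series <- function(x) length(x$times)

#' @export
as.data.frame.survival_series <- function(x, ...) {
  data.frame(time_min = x$times, cfu = x$counts)
}
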