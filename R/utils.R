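# Time-unit handling: all kinetics run in seconds internally; user-facing
# functions accept explicit units only (a bare number with no unit is an error
# for half-lives and durations, since silent unit guesses corrupt rate
# constants by orders of magnitude).

.time_units <- c(us = 1e-6, ms = 1e-3, s = 1, min = 60, h = 3600, d = 86400)

#' Convert a duration to seconds
#'
#' @param x Numeric duration value(s).
#' @param unit One of `"us"`, `"ms"`, `"s"`, `"min"`, `"h"`, `"d"`.
#' @return Numeric vector of seconds.
#' @examples
#' to_seconds(3.05, "min")
#' @export
to_seconds <- function(x, unit) {
  if (missing(unit) || is.null(unit) || !is.character(unit) || length(unit) != 1L) {
    abort("`unit` must be given explicitly (one of: us, ms, s, min, h, d).",
          class = "radonaero_invalid_input")
  }
  if (!unit %in% names(.time_units)) {
    abort(paste0("Unknown time unit '", unit, "'."),
          class = "radonaero_invalid_input")
  }
  if (!is.numeric(x)) {
    abort("Duration must be numeric.", class = "radonaero_invalid_input")
  }
  x * .time_units[[unit]]
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort(paste0("`", what, "` must be non-negative and non-missing."),
          class = "radonaero_invalid_input")
  }
  invisible(x)
}

geomean <- function(x) exp(mean(log(x)))
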