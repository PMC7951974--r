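#' @keywords internal
"_PACKAGE"

# Shared argument checks. These raise classed conditions so callers (and the
# CLI) can distinguish user parameter errors from internal failures.

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("spikesig_param_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("spikesig_format_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("'", name, "' must be a single finite number")
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_param("'", name, "' = ", x, " is outside its allowed range")
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      abs(x - round(x)) > 1e-8 || x < min) {
    stop_param("'", name, "' must be an integer >= ", min)
  }
  as.integer(round(x))
}

check_seed <- function(x, name = "seed") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      abs(x - round(x)) > 1e-8) {
    stop_param("'", name, "' must be a single integer")
  }
  as.integer(round(x))
}

#' Standardize a trace to zero mean and unit variance
#'
#' Subtracts the mean and divides by the standard deviation with a small
#' guard (`1e-8`) in the denominator so constant traces map to zero instead
#' of producing `NaN`. Every trace is standardized this way before it is
#' framed and fed to the network, which makes simulated and real recordings
#' commensurate regardless of their raw fluorescence units.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
standardize_trace <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop_param("'x' must be a non-empty numeric vector")
  }
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s)) s <- 0
  (x - mean(x)) / (s + 1e-8)
}
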