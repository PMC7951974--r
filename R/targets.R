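# Training targets: discrete spike counts, optionally smoothed with a
# Gaussian window to densify the supervision signal.

#' Gaussian target-smoothing specification
#'
#' The discrete spike target is optionally convolved with a symmetric
#' Gaussian window to make it less sparse for training. The window is
#' parameterized by its width and standard deviation in samples; the
#' default (11, 5) corresponds to a 110 ms window at 100 Hz.
#'
#' @param width Odd positive window width in samples (default 11).
#' @param std Positive standard deviation in samples (default 5).
#' @param enabled If `FALSE`, [smooth_targets()] returns the counts cast to
#'   reals unchanged.
#' @return An object of class `gaussian_target_spec`.
#' @export
gaussian_target_spec <- function(width = 11L, std = 5, enabled = TRUE) {
  width <- check_count(width, "width", min = 1L)
  if (width %% 2L == 0L) stop_param("'width' must be odd, got ", width)
  structure(
    list(width = width,
         std = check_number(std, "std", lower = 0, strict_lower = TRUE),
         enabled = isTRUE(enabled)),
    class = "gaussian_target_spec")
}

#' Unit-sum discretized Gaussian window
#'
#' Symmetric window `g[k] = exp(-((k - c)/std)^2 / 2)` for
#' `k = 0, ..., width-1` with `c = (width-1)/2`, normalized to sum to one
#' so convolution preserves total spike mass.
#'
#' @param width Odd positive width in samples.
#' @param std Positive standard deviation in samples.
#' @return Numeric vector of length `width` summing to 1.
#' @export
gaussian_window <- function(width, std) {
  spec <- gaussian_target_spec(width = width, std = std)
  k <- seq_len(spec$width) - 1L
  centre <- (spec$width - 1L) / 2
  g <- exp(-0.5 * ((k - centre) / spec$std)^2)
  g / sum(g)
}

#' Smooth a spike-count train into a training target
#'
#' Same-length discrete convolution of the counts with the unit-sum
#' Gaussian window (zero-padded edges), or the counts cast to reals when
#' smoothing is disabled. Because the window sums to one, total spike mass
#' is preserved for spikes at least `(width-1)/2` samples from either edge.
#'
#' @param spikes Non-negative spike counts.
#' @param spec A [gaussian_target_spec()].
#' @return Numeric target sequence, same length as `spikes`.
#' @export
smooth_targets <- function(spikes, spec = gaussian_target_spec()) {
  stopifnot(inherits(spec, "gaussian_target_spec"))
  if (any(!is.finite(spikes)) || any(spikes < 0)) {
    stop_param("'spikes' must be finite and non-negative")
  }
  x <- as.numeric(spikes)
  if (!spec$enabled) return(x)
  g <- gaussian_window(spec$width, spec$std)
  n <- length(x)
  half <- (spec$width - 1L) / 2
  # explicit shifted-sum "same" convolution: exact arithmetic, stays
  # non-negative (an FFT route would leave ~1e-17 negative residue)
  y <- numeric(n)
  for (j in seq_along(g)) {
    shift <- j - 1L - half  # contribution of x[t - shift] to y[t]
    src_lo <- max(1L, 1L - shift)
    src_hi <- min(n, n - shift)
    if (src_lo <= src_hi) {
      idx <- src_lo:src_hi
      y[idx + shift] <- y[idx + shift] + g[j] * x[idx]
    }
  }
  y
}
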