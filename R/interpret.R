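# Interpretability: per-layer total responses to an input trace and
# cumulative frequency responses of the learned filters.

#' Layer-wise total responses to a trace
#'
#' Feeds the trace through the network and records, for every layer, the
#' post-activation channel sum per frame: one value per input sample
#' (hop 1, centered framing). The final entry is the spike estimate
#' itself, so the last response always equals `s2s_forward()` exactly.
#'
#' @param params An `s2s_params` object (trained or untrained).
#' @param trace Finite numeric fluorescence trace.
#' @param standardize Standardize the trace first (default `TRUE`),
#'   matching [s2s_forward()].
#' @return Named list of numeric vectors (`analysis`, `hidden_1` ...,
#'   `output`), each the length of the trace.
#' @export
layer_responses <- function(params, trace, standardize = TRUE) {
  stopifnot(inherits(params, "s2s_params"))
  if (length(trace) < 1L || any(!is.finite(trace))) {
    stop_param("'trace' must be non-empty and finite")
  }
  x <- if (standardize) standardize_trace(trace) else as.numeric(trace)
  fr <- frame_signal(x, params$config$w_seq)
  acts <- forward_layers(params, fr$frames)
  out <- list(analysis = rowSums(acts$analysis))
  for (i in seq_along(acts$hidden)) {
    out[[paste0("hidden_", i)]] <- rowSums(acts$hidden[[i]])
  }
  out$output <- overlap_add(acts$synthesis, fr$pad_left, length(x))
  out
}

#' Analysis and synthesis filters as time-domain kernels
#'
#' `analysis_kernels` returns the analysis filters (one per row, length
#' `w_seq`); `synthesis_kernels` returns the rows of the synthesis map,
#' each a length-`w_seq` time signal emitted per unit activation of the
#' corresponding last-layer feature.
#'
#' @param params An `s2s_params` object.
#' @return Numeric matrix, one kernel per row.
#' @export
analysis_kernels <- function(params) {
  stopifnot(inherits(params, "s2s_params"))
  t(params$W_in)
}

#' @rdname analysis_kernels
#' @export
synthesis_kernels <- function(params) {
  stopifnot(inherits(params, "s2s_params"))
  params$W_out
}

#' Cumulative frequency response of a filter bank
#'
#' Sums the magnitude spectra of the kernels (zero-padded to `n_freq`
#' points) over the filter bank and returns the non-negative half-spectrum
#' on a Hz grid from 0 to `fs / 2`. The cumulative response is additive
#' over filters by construction.
#'
#' @param kernels Matrix with one kernel per row (or list of equal-length
#'   numeric vectors); at least one kernel.
#' @param fs Sampling rate in Hz (default 100).
#' @param n_freq DFT size (default 1024); must be at least the kernel
#'   length.
#' @return An object of class `frequency_response`: list with `freqs`
#'   (Hz, strictly increasing) and `magnitude` (summed `|DFT|`, >= 0).
#' @export
filter_frequency_response <- function(kernels, fs = 100, n_freq = 1024L) {
  if (is.list(kernels)) kernels <- do.call(rbind, kernels)
  if (!is.matrix(kernels) || nrow(kernels) < 1L) {
    stop_param("'kernels' must contain at least one kernel")
  }
  n_freq <- check_count(n_freq, "n_freq", min = 1L)
  len <- ncol(kernels)
  if (n_freq < len) stop_param("n_freq must be >= the kernel length")
  fs <- check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  n_half <- n_freq %/% 2L
  magnitude <- numeric(n_half + 1L)
  for (i in seq_len(nrow(kernels))) {
    z <- stats::fft(c(kernels[i, ], numeric(n_freq - len)))
    magnitude <- magnitude + Mod(z[seq_len(n_half + 1L)])
  }
  structure(list(freqs = (0:n_half) * fs / n_freq, magnitude = magnitude),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  pk <- which.max(x$magnitude)
  cat(sprintf(
    "Cumulative filter frequency response: %d points in [0, %g] Hz, peak at %.3g Hz\n",
    length(x$freqs), max(x$freqs), x$freqs[pk]))
  invisible(x)
}
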