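# The analysis-synthesis (signal-to-signal) network.
#
# A fluorescence trace is cut into overlapping frames of w_seq samples at
# hop 1 (centered zero padding). Each frame passes through an analysis
# layer (nFilt inner products + bias, ReLU), a stack of time-distributed
# dense hidden layers (ReLU), and a bias-free linear synthesis map that
# emits w_seq output samples per frame. Per-frame outputs are overlap-added
# with per-sample coverage normalization, yielding a spike-signal estimate
# of exactly the input length.

#' Network architecture configuration
#'
#' Hyper-parameters of the analysis-synthesis network. The analysis kernel
#' width equals the frame length `w_seq` and both hops are fixed at one
#' sample; the synthesis layer emits `w_seq` samples per frame from the
#' last feature vector (its kernel width equals the last hidden width, or
#' `n_filt` when there are no hidden layers).
#'
#' @param w_seq Frame length in samples (default 100, i.e. 1 s at 100 Hz).
#' @param n_filt Number of analysis filters (default 30).
#' @param n_hidden Number of hidden layers, 0 to 3 (default 3).
#' @param n_units Integer vector of hidden-layer widths, length `n_hidden`
#'   (default all 30).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `s2s_config`.
#' @export
s2s_config <- function(w_seq = 100L, n_filt = 30L, n_hidden = 3L,
                       n_units = rep(30L, n_hidden), seed = 1L) {
  w_seq <- check_count(w_seq, "w_seq", min = 1L)
  n_filt <- check_count(n_filt, "n_filt", min = 1L)
  n_hidden <- check_count(n_hidden, "n_hidden", min = 0L)
  if (n_hidden > 3L) stop_param("'n_hidden' must be between 0 and 3")
  if (n_hidden == 0L) {
    n_units <- integer(0)
  } else {
    if (length(n_units) != n_hidden) {
      stop_param("'n_units' must have length n_hidden = ", n_hidden)
    }
    n_units <- vapply(seq_len(n_hidden), function(i) {
      check_count(n_units[i], paste0("n_units[", i, "]"), min = 1L)
    }, integer(1))
  }
  structure(
    list(w_seq = w_seq, n_filt = n_filt, n_hidden = n_hidden,
         n_units = n_units, seed = check_seed(seed)),
    class = "s2s_config")
}

#' @export
print.s2s_config <- function(x, ...) {
  hid <- if (x$n_hidden == 0L) "none" else paste(x$n_units, collapse = "-")
  cat(sprintf(
    "S2S config: frames of %d samples (hop 1), %d analysis filters, hidden layers: %s, %d parameters\n",
    x$w_seq, x$n_filt, hid, count_parameters(x)))
  invisible(x)
}

# width of the feature vector entering the synthesis map
last_feature_width <- function(config) {
  if (config$n_hidden == 0L) config$n_filt else config$n_units[config$n_hidden]
}

#' Count trainable parameters
#'
#' `(w_seq * n_filt + n_filt)` for the analysis layer, `fan_in * width +
#' width` per hidden layer, and `last_width * w_seq` for the bias-free
#' synthesis map. The defaults give 8820; the one-hidden-layer and
#' zero-hidden-layer variants give 6960 and 6030.
#'
#' @param config An [s2s_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "s2s_config"))
  total <- config$w_seq * config$n_filt + config$n_filt
  fan_in <- config$n_filt
  for (i in seq_len(config$n_hidden)) {
    total <- total + fan_in * config$n_units[i] + config$n_units[i]
    fan_in <- config$n_units[i]
  }
  total + last_feature_width(config) * config$w_seq
}

glorot_uniform <- function(fan_in, fan_out, nrow, ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize network parameters
#'
#' Weights are drawn from a variance-scaled (Glorot) uniform distribution
#' seeded by `config$seed`; biases start at zero. The synthesis map has no
#' bias. Identical seeds give bit-identical parameters.
#'
#' @param config An [s2s_config()].
#' @return An object of class `s2s_params`: list with `W_in`
#'   (`w_seq x n_filt`), `b_in`, `hidden` (list of `W`/`b` pairs), `W_out`
#'   (`last_width x w_seq`), and the `config`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "s2s_config"))
  set.seed(config$seed)
  W_in <- glorot_uniform(config$w_seq, config$n_filt,
                         config$w_seq, config$n_filt)
  b_in <- numeric(config$n_filt)
  hidden <- vector("list", config$n_hidden)
  fan_in <- config$n_filt
  for (i in seq_len(config$n_hidden)) {
    w <- config$n_units[i]
    hidden[[i]] <- list(W = glorot_uniform(fan_in, w, fan_in, w),
                        b = numeric(w))
    fan_in <- w
  }
  lastw <- last_feature_width(config)
  W_out <- glorot_uniform(lastw, config$w_seq, lastw, config$w_seq)
  structure(list(W_in = W_in, b_in = b_in, hidden = hidden, W_out = W_out,
                 config = config),
            class = "s2s_params")
}

#' @export
print.s2s_params <- function(x, ...) {
  cat("S2S network parameters\n")
  print(x$config)
  invisible(x)
}

# the weight arrays in a fixed order, for optimizers and introspection
weight_arrays <- function(params) {
  out <- list(W_in = params$W_in, b_in = params$b_in)
  for (i in seq_along(params$hidden)) {
    out[[paste0("W_h", i)]] <- params$hidden[[i]]$W
    out[[paste0("b_h", i)]] <- params$hidden[[i]]$b
  }
  out$W_out <- params$W_out
  out
}

set_weight_arrays <- function(params, arrays) {
  params$W_in <- arrays$W_in
  params$b_in <- arrays$b_in
  for (i in seq_along(params$hidden)) {
    params$hidden[[i]]$W <- arrays[[paste0("W_h", i)]]
    params$hidden[[i]]$b <- arrays[[paste0("b_h", i)]]
  }
  params$W_out <- arrays$W_out
  params
}

#' Cut a signal into unit-hop frames
#'
#' The signal is zero-padded with `floor((w-1)/2)` samples on the left and
#' `w - 1 - pad_left` on the right, then cut into exactly `length(x)`
#' frames of `w` samples at hop 1, so frame `i` is centered on sample `i`.
#'
#' @param x Numeric signal, length >= 1.
#' @param w Frame length in samples (> 0).
#' @param hop Frame hop; only 1 is supported.
#' @return List with `frames` (a `length(x) x w` matrix, one frame per
#'   row) and `pad_left`.
#' @export
frame_signal <- function(x, w, hop = 1L) {
  w <- check_count(w, "w", min = 1L)
  if (check_count(hop, "hop", min = 1L) != 1L) {
    stop_param("only hop = 1 is supported")
  }
  n <- length(x)
  if (n < 1L) stop_param("'x' must have length >= 1")
  pad_left <- (w - 1L) %/% 2L
  pad_right <- w - 1L - pad_left
  xp <- c(numeric(pad_left), as.numeric(x), numeric(pad_right))
  frames <- matrix(0, n, w)
  for (j in seq_len(w)) frames[, j] <- xp[j:(j + n - 1L)]
  list(frames = frames, pad_left = pad_left)
}

# number of frames covering each position of the padded axis
ola_coverage <- function(n_frames, w) {
  p <- seq_len(n_frames + w - 1L)
  pmin(p, w, n_frames, n_frames + w - p)
}

#' Overlap-add per-frame outputs into one signal
#'
#' Frame `f`'s `w` samples are accumulated at padded positions
#' `[f, f + w - 1]`; every padded sample is divided by the number of frames
#' covering it (coverage normalization removes edge amplitude bias), and
#' the padded margins are cropped to return exactly `out_len` samples
#' starting after `pad_left`.
#'
#' @param frame_outputs Matrix with one frame per row (or list of
#'   equal-length numeric vectors).
#' @param pad_left Left padding used when framing.
#' @param out_len Desired output length (>= 1).
#' @return Numeric vector of length `out_len`.
#' @export
overlap_add <- function(frame_outputs, pad_left, out_len) {
  if (is.list(frame_outputs)) {
    lens <- lengths(frame_outputs)
    if (length(unique(lens)) != 1L) {
      stop_param("inconsistent frame lengths")
    }
    frame_outputs <- do.call(rbind, frame_outputs)
  }
  if (!is.matrix(frame_outputs) || nrow(frame_outputs) < 1L) {
    stop_param("'frame_outputs' must contain at least one frame")
  }
  out_len <- check_count(out_len, "out_len", min = 1L)
  pad_left <- check_count(pad_left, "pad_left", min = 0L)
  n <- nrow(frame_outputs)
  w <- ncol(frame_outputs)
  if (pad_left + out_len > n + w - 1L) {
    stop_param("out_len + pad_left exceeds the reconstructed axis")
  }
  acc <- numeric(n + w - 1L)
  for (j in seq_len(w)) {
    idx <- j:(j + n - 1L)
    acc[idx] <- acc[idx] + frame_outputs[, j]
  }
  y <- acc / ola_coverage(n, w)
  y[(pad_left + 1L):(pad_left + out_len)]
}

# forward pass over a frame matrix, keeping per-layer activations
forward_layers <- function(params, frames) {
  n <- nrow(frames)
  Z <- frames %*% params$W_in
  Z <- sweep(Z, 2L, params$b_in, "+")
  A <- pmax(Z, 0)
  hidden_acts <- vector("list", length(params$hidden))
  H <- A
  for (i in seq_along(params$hidden)) {
    Zi <- H %*% params$hidden[[i]]$W
    Zi <- sweep(Zi, 2L, params$hidden[[i]]$b, "+")
    H <- pmax(Zi, 0)
    hidden_acts[[i]] <- H
  }
  S <- H %*% params$W_out
  list(analysis = A, hidden = hidden_acts, synthesis = S)
}

#' Run the network on a fluorescence trace
#'
#' The trace is standardized (see [standardize_trace()]), framed at hop 1,
#' passed through analysis, hidden and synthesis layers, and the per-frame
#' outputs are overlap-added into a spike-signal estimate of exactly the
#' input length. Deterministic given the parameters.
#'
#' @param params An [build_network()] object (trained or not).
#' @param trace Finite numeric fluorescence trace, length >= 1.
#' @param standardize Standardize the trace first (default `TRUE`); set to
#'   `FALSE` when the input is already standardized.
#' @return An object of class `spike_estimate`: list with `values` (the
#'   estimate) and `source_length`.
#' @export
s2s_forward <- function(params, trace, standardize = TRUE) {
  stopifnot(inherits(params, "s2s_params"))
  if (length(trace) < 1L || any(!is.finite(trace))) {
    stop_param("'trace' must be non-empty and finite")
  }
  x <- if (standardize) standardize_trace(trace) else as.numeric(trace)
  fr <- frame_signal(x, params$config$w_seq)
  acts <- forward_layers(params, fr$frames)
  values <- overlap_add(acts$synthesis, fr$pad_left, length(x))
  structure(list(values = values, source_length = length(x)),
            class = "spike_estimate")
}

#' @export
print.spike_estimate <- function(x, ...) {
  cat(sprintf("Spike estimate: %d samples, range [%.4g, %.4g]\n",
              x$source_length, min(x$values), max(x$values)))
  invisible(x)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single-file serialized container holding the
#' parameters (with their embedded config) plus any extra metadata; it
#' round-trips bit-exactly.
#'
#' @param params An `s2s_params` object.
#' @param path Checkpoint file path.
#' @param extra Optional named list stored alongside the parameters.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns a list with `params` and `extra`.
#' @export
save_checkpoint <- function(params, path, extra = list()) {
  stopifnot(inherits(params, "s2s_params"))
  saveRDS(list(params = params, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  path <- as.character(path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read checkpoint '", path, "': ", conditionMessage(e))
  })
  if (!is.list(obj) || !inherits(obj$params, "s2s_params")) {
    stop("'", path, "' is not a spikesig checkpoint")
  }
  obj
}
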