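# Synthetic paired (spike train, fluorescence trace) recordings.
#
# The generator emulates the statistical structure of benchmark calcium
# imaging data at 100 Hz: sparse Poisson spiking with occasional short
# bursts, a fast-rise / slow-decay indicator transient per spike, a slow
# sinusoidal baseline drift, and additive white noise.

#' Configuration for the synthetic calcium-trace simulator
#'
#' Defines one neuron's simulation conditions. The defaults describe a
#' cortical-like regime: 60 s of recording at 100 Hz, a mean firing rate of
#' 0.8 Hz where one spike in five triggers a short burst, a GCaMP/OGB-like
#' transient (50 ms rise, 500 ms decay) of unit amplitude, moderate white
#' noise (sd 0.2 relative to the unit transient peak) and a slow sinusoidal
#' baseline drift.
#'
#' @param duration_s Recording duration in seconds (> 0).
#' @param fs Sampling rate in Hz (default 100). `fs * duration_s` must be a
#'   whole number of samples.
#' @param rate_hz Mean rate of the underlying Poisson process in Hz (>= 0).
#' @param burst_prob Probability in \[0, 1\] that a spike triggers a burst of
#'   follow-on spikes.
#' @param burst_len_mean Mean number of extra spikes per burst (>= 0); the
#'   extra spikes land one per sample in the samples immediately after the
#'   triggering spike.
#' @param amp Fluorescence amplitude of a single spike's transient (> 0).
#' @param tau_rise_s Rise time constant of the transient kernel in seconds.
#' @param tau_decay_s Decay time constant in seconds; must exceed
#'   `tau_rise_s` so the transient shape is well defined.
#' @param noise_sigma Standard deviation of additive iid Gaussian noise.
#' @param drift_amp Amplitude of the sinusoidal baseline drift (>= 0).
#' @param drift_period_s Period of the drift in seconds (> 0).
#' @param seed Integer seed; all randomness in the simulator derives from it.
#' @return An object of class `sim_config`.
#' @seealso [simulate_recording()], [make_benchmark()]
#' @export
sim_config <- function(duration_s = 60, fs = 100, rate_hz = 0.8,
                       burst_prob = 0.2, burst_len_mean = 1.5, amp = 1,
                       tau_rise_s = 0.05, tau_decay_s = 0.5,
                       noise_sigma = 0.2, drift_amp = 0.1,
                       drift_period_s = 60, seed = 1L) {
  cfg <- list(
    duration_s = check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE),
    fs = check_number(fs, "fs", lower = 0, strict_lower = TRUE),
    rate_hz = check_number(rate_hz, "rate_hz", lower = 0),
    burst_prob = check_number(burst_prob, "burst_prob", lower = 0, upper = 1),
    burst_len_mean = check_number(burst_len_mean, "burst_len_mean", lower = 0),
    amp = check_number(amp, "amp", lower = 0, strict_lower = TRUE),
    tau_rise_s = check_number(tau_rise_s, "tau_rise_s", lower = 0, strict_lower = TRUE),
    tau_decay_s = check_number(tau_decay_s, "tau_decay_s", lower = 0, strict_lower = TRUE),
    noise_sigma = check_number(noise_sigma, "noise_sigma", lower = 0),
    drift_amp = check_number(drift_amp, "drift_amp", lower = 0),
    drift_period_s = check_number(drift_period_s, "drift_period_s", lower = 0, strict_lower = TRUE),
    seed = check_seed(seed)
  )
  n <- cfg$fs * cfg$duration_s
  if (abs(n - round(n)) > 1e-9 || round(n) < 1) {
    stop_param("fs * duration_s must be a positive integer number of samples")
  }
  if (cfg$tau_decay_s <= cfg$tau_rise_s) {
    stop_param("tau_decay_s must be greater than tau_rise_s")
  }
  cfg$n_samples <- as.integer(round(n))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulator config: %.4g s at %g Hz (%d samples), rate %.3g Hz, burst p=%.2g (mean %.2g extra)\n",
    x$duration_s, x$fs, x$n_samples, x$rate_hz, x$burst_prob, x$burst_len_mean))
  cat(sprintf(
    "  transient: amp %.3g, tau_rise %.3g s, tau_decay %.3g s; noise sd %.3g; drift %.3g / %.3g s; seed %d\n",
    x$amp, x$tau_rise_s, x$tau_decay_s, x$noise_sigma, x$drift_amp,
    x$drift_period_s, x$seed))
  invisible(x)
}

#' Sample a spike-count train
#'
#' Draws per-sample spike counts from a homogeneous Poisson process with
#' rate `rate_hz`. Each base event then independently triggers, with
#' probability `burst_prob`, a burst of `Poisson(burst_len_mean)` follow-on
#' spikes placed one per sample in the immediately following samples
#' (truncated at the end of the recording). Follow-on spikes do not trigger
#' further bursts. Bit-exact reproducible for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed to use; defaults to `config$seed`. Pass `NULL` to draw
#'   from the current RNG state.
#' @return Integer vector of spike counts, length `fs * duration_s`.
#' @export
sample_spike_train <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(check_seed(seed))
  n <- config$n_samples
  counts <- stats::rpois(n, config$rate_hz / config$fs)
  if (config$burst_prob > 0 && config$burst_len_mean > 0) {
    base <- counts
    for (i in which(base > 0L)) {
      for (ev in seq_len(base[i])) {
        if (stats::runif(1) < config$burst_prob) {
          extra <- stats::rpois(1, config$burst_len_mean)
          if (extra > 0L) {
            pos <- i + seq_len(extra)
            pos <- pos[pos <= n]
            counts[pos] <- counts[pos] + 1L
          }
        }
      }
    }
  }
  as.integer(counts)
}

#' Discretized calcium indicator kernel
#'
#' Unit-peak transient `k(t) = (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`
#' for `t >= 0`, sampled at `fs` and truncated at `10 * tau_decay` (the
#' tail beyond the truncation is below 5e-5 of the peak). The peak is
#' normalized on the sampling grid, so a single unit spike attains its
#' amplitude exactly at one sample.
#'
#' @param tau_rise_s,tau_decay_s Time constants in seconds.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of kernel samples.
#' @export
calcium_kernel <- function(tau_rise_s, tau_decay_s, fs) {
  if (tau_decay_s <= tau_rise_s) stop_param("tau_decay_s must exceed tau_rise_s")
  len <- as.integer(ceiling(10 * tau_decay_s * fs)) + 1L
  t <- (seq_len(len) - 1L) / fs
  k <- (1 - exp(-t / tau_rise_s)) * exp(-t / tau_decay_s)
  k / max(k)
}

#' Render a fluorescence trace from a spike train
#'
#' Forward model: the spike counts are convolved with the unit-peak
#' indicator kernel scaled by `amp`, a sinusoidal baseline drift with a
#' random phase is added, and iid Gaussian noise is superimposed:
#' `trace(t) = drift(t) + sum_i n_i * amp * k(t - t_i) + eps(t)`.
#'
#' @param spikes Non-negative integer spike counts per sample, length
#'   `fs * duration_s`.
#' @param config A [sim_config()].
#' @param seed Seed for drift phase and noise; defaults to
#'   `config$seed + 1` so the trace noise is independent of the spike draw.
#'   Pass `NULL` to draw from the current RNG state.
#' @return Numeric fluorescence trace, same length as `spikes`.
#' @export
render_fluorescence <- function(spikes, config,
                                seed = if (is.null(config$seed)) NULL else config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  if (length(spikes) != n) {
    stop_param("length(spikes) = ", length(spikes),
               " does not match fs * duration_s = ", n)
  }
  if (any(!is.finite(spikes)) || any(spikes < 0) ||
      any(abs(spikes - round(spikes)) > 1e-9)) {
    stop_param("'spikes' must be non-negative integer counts")
  }
  spikes <- as.numeric(spikes)
  kern <- calcium_kernel(config$tau_rise_s, config$tau_decay_s, config$fs)
  full <- stats::convolve(spikes, rev(kern), type = "open")
  signal <- config$amp * full[seq_len(n)]
  if (!is.null(seed)) set.seed(check_seed(seed))
  # phase and noise are always drawn so the RNG stream does not depend on
  # whether drift/noise amplitudes are zero
  phase <- stats::runif(1, 0, 2 * pi)
  tt <- (seq_len(n) - 1L) / config$fs
  drift <- config$drift_amp * sin(2 * pi * tt / config$drift_period_s + phase)
  eps <- stats::rnorm(n, 0, config$noise_sigma)
  signal + drift + eps
}

#' Simulate one paired recording
#'
#' @param config A [sim_config()].
#' @param dataset_id,neuron_id Labels carried into the [recording()].
#' @return A [recording()] whose `trace` and `spikes` were generated from
#'   `config` (attached as attribute `"sim_config"`).
#' @export
simulate_recording <- function(config, dataset_id = "sim", neuron_id = "0") {
  spikes <- sample_spike_train(config)
  trace <- render_fluorescence(spikes, config)
  rec <- recording(trace, spikes, dataset_id = dataset_id,
                   neuron_id = neuron_id, fs = config$fs)
  attr(rec, "sim_config") <- config
  rec
}

#' Write a synthetic benchmark in the spikefinder CSV dialect
#'
#' Simulates `n_neurons` independent recordings (neuron `j` uses seed
#' `config$seed + j`, so the set is reproducible and any column can be
#' regenerated in isolation) and writes a `calcium.csv` / `spikes.csv` pair
#' with one neuron per column.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param config A [sim_config()]; per-neuron seeds are derived from
#'   `config$seed`.
#' @param out_dir Output directory, created if missing.
#' @return Named list with elements `calcium` and `spikes`: the file paths.
#' @export
make_benchmark <- function(n_neurons, config, out_dir) {
  n_neurons <- check_count(n_neurons, "n_neurons", min = 1L)
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory '", out_dir, "'")
  }
  traces <- vector("list", n_neurons)
  spikes <- vector("list", n_neurons)
  for (j in seq_len(n_neurons)) {
    cfg_j <- config
    cfg_j$seed <- config$seed + j
    rec <- simulate_recording(cfg_j, neuron_id = as.character(j - 1L))
    traces[[j]] <- rec$trace
    spikes[[j]] <- as.numeric(rec$spikes)
  }
  names(traces) <- names(spikes) <- as.character(seq_len(n_neurons) - 1L)
  calcium_path <- file.path(out_dir, "calcium.csv")
  spikes_path <- file.path(out_dir, "spikes.csv")
  write_column_csv(traces, calcium_path)
  write_column_csv(spikes, spikes_path)
  list(calcium = calcium_path, spikes = spikes_path)
}
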