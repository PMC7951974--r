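---
title: "Estimating spike signals from calcium fluorescence with an analysis-synthesis network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spike signals from calcium fluorescence with an analysis-synthesis network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesig)
```

## The problem

Calcium imaging reports neuronal activity only indirectly: each action
potential drives a calcium influx that a fluorescent indicator (GCaMP, OGB)
converts into a slow transient — tens of milliseconds of rise, hundreds of
milliseconds of decay — on top of baseline drift and shot noise. Recovering
the underlying spike train from the fluorescence trace is the spike
inference problem. `spikesig` solves it with a small supervised network
that converts the fluorescence *signal* into a spike *signal* of the same
length and sampling rate (100 Hz throughout), rather than classifying one
sample at a time.

## The model

The network is an analysis–synthesis chain applied to overlapping frames
of the standardized trace:

1. **Framing.** The trace is standardized (zero mean, unit variance, with
   an `1e-8` guard), zero-padded symmetrically, and cut into one frame of
   `w_seq = 100` samples (1 s) per input sample — hop 1, so frame $t$ is
   centered on sample $t$.
2. **Analysis layer.** Each frame is projected onto `n_filt = 30` learned
   kernels of length 100 (plus biases), followed by a ReLU.
3. **Time-distributed hidden layers.** Up to three dense layers of 30
   units, applied identically to every frame, each followed by a ReLU.
4. **Synthesis layer.** A bias-free linear map from the last 30-dimensional
   feature vector to 100 output samples per frame.
5. **Overlap-add.** Frame outputs are accumulated at their frame positions,
   every sample is divided by the number of frames covering it, and the
   padded margins are cropped, giving an estimate exactly as long as the
   input.

With three hidden layers this totals
$(100{\times}30{+}30) + 3\,(30{\times}30{+}30) + (30{\times}100) = 8820$
trainable scalars; one hidden layer gives 6960 and none gives 6030
(`count_parameters()` and the allocated weight arrays agree by
construction and by test).

Two conventions in this chain are design choices rather than forced by the
architecture. Framing uses *centered* zero padding, and overlap-add divides
by per-sample coverage: the training cost is scale-invariant (below), so
these choices only affect edge behavior, and coverage normalization removes
the amplitude bias that plain summation would create at the edges. The
synthesis map is interpreted as a per-frame linear map onto `w_seq` samples
(equivalently a stride-1 transposed convolution), the only reading
consistent with a bias-free `30 x 100` final parameter block and a
same-length output.

## Training objective and schedule

Training maximizes Pearson's correlation between the network output and
the target spike signal: the loss is $-r$ with
$r = \mathrm{cov}(\hat{s}, s)\,/\,((\sigma_{\hat{s}}+\epsilon)
(\sigma_{s}+\epsilon))$, $\epsilon = 10^{-8}$. Correlation is invariant
under positive affine transforms of either argument, so the network is
free to choose its own output scale; the epsilon guard keeps constant
chunks finite instead of special-casing them.

The target is the discrete spike-count train, optionally convolved with a
unit-sum Gaussian window — default width 11 samples, standard deviation 5
samples (110 ms at 100 Hz) — to densify the supervision. Unit-sum
normalization preserves total spike mass for interior spikes; since the
cost is scale-invariant, the normalization only fixes reported amplitudes.

Optimization is Adam at a starting learning rate of 0.001 on batches of 20
chunks. Recordings are split 80/20 at the recording level (no neuron
contributes to both sets), standardized once per recording, and sliced
into non-overlapping 1000-sample (10 s) chunks; a trailing chunk shorter
than one frame is dropped. The loss is computed per chunk and averaged
over the batch, keeping per-sequence correlation semantics. Early stopping
watches the mean validation-chunk loss with a patience of 6 epochs and
restores the best-validation weights; patience on the best value so far is
used rather than a literal "stop when the loss increases once", which
fires spuriously under stochastic batching. Weights are initialized with
variance-scaled (Glorot) uniform draws from the model seed; every source
of randomness (simulation, split, shuffling, initialization) is seeded, so
a run is bit-reproducible on a single-threaded BLAS.

Chunks of 10 s are a compromise: long enough to span many transients so a
per-chunk correlation is meaningful, short enough that a batch of 20 is
memory-trivial and gradient noise regularizes. Whether a training "sample"
should be a chunk, a frame, or a whole recording is underdetermined;
chunks were chosen and the batch size applies to chunks.

## Evaluation protocol

Evaluation follows the spikefinder challenge protocol: estimate and
ground truth are summed into 40 ms bins (factor 4 from 100 Hz to 25 Hz;
factor 1 evaluates at the native rate), and each recording is scored with

* **Pearson correlation** (primary) of the binned sequences,
* **Spearman rank correlation** (tie-adjusted ranks), and
* **ROC-AUC** for detecting whether a bin contains at least one spike,
  using the binned estimate as the score, with tied scores given half
  credit (the tie-adjusted Mann–Whitney identity).

Binning uses summation for both signals — spike bins must represent
counts, and the correlation metrics are scale-invariant so sum versus
mean is immaterial for the estimate — and a trailing partial bin is
dropped rather than padded. A recording whose binned estimate or truth is
constant has no defined correlation (or a single AUC class); it is
excluded from that metric's average with a warning rather than scored
zero. Dataset means are unweighted means over recordings and the grand
mean is the unweighted mean over dataset means, matching the challenge's
dataset-wise reporting.

## The synthetic benchmark

Real benchmark data cannot ship with the package, so the `sim` module
generates recordings with the statistical structure the method assumes:
Poisson spiking at `rate_hz` where each spike triggers, with probability
`burst_prob`, a burst of `Poisson(burst_len_mean)` follow-on spikes in the
immediately following samples (so per-sample counts exceeding one occur,
as in real data); a fluorescence forward model that convolves the counts
with a unit-peak difference-of-exponentials transient
$k(t) = (1-e^{-t/\tau_r})\,e^{-t/\tau_d}$ (defaults $\tau_r = 50$ ms,
$\tau_d = 500$ ms, truncated at $10\tau_d$ where the tail is below
$5\times10^{-5}$ of peak); a sinusoidal baseline drift with random phase;
and white Gaussian noise.

The package's study conditions are the generator defaults: 20 neurons
$\times$ 60 s at 100 Hz, rate 0.8 Hz, burst probability 0.2 with 1.5
extra spikes on average, unit transient amplitude, noise sd 0.2, drift
amplitude 0.1 with a 60 s period. On this benchmark the trained
three-hidden-layer network reaches a held-out grand Pearson around 0.77
at 25 Hz versus roughly 0.19 for its untrained initialization, and the
tests assert that margin; the acceptance script recomputes these numbers
from scratch.

What the simulator does **not** emulate matters for interpreting results:

* **Exact spike timing.** Transients are placed exactly at spike samples.
  Real recordings carry timing jitter between electrophysiological truth
  and imaging frames, which is precisely the regime where smoothing the
  discrete target helps. On the synthetic benchmark the *discrete* target
  consequently outscores the Gaussian (11, 5) target on binned Pearson
  (about 0.92 vs 0.77 held out): the Gaussian-trained network reproduces
  its smoothed target almost perfectly (validation chunk correlation
  0.97), but a 110 ms smear spreads each event across ~3 evaluation bins.
  The package supports both target modes; on real data the smoothed
  target is the recommended default, and on the clean simulator the
  discrete target wins by construction.
* **A validation plateau.** The synthetic task is cleanly learnable, so
  the validation loss keeps creeping down (~$10^{-4}$/epoch) long past
  the point where real-data training plateaus; patience-6 early stopping
  therefore typically does *not* fire within 50 epochs here, even though
  on real noisy benchmarks this schedule converges quickly. Training is
  capped at `max_epochs = 100`.
* Indicator nonlinearity, per-dataset scan-rate and zoom differences, and
  2-photon movie artifacts are out of scope.

## Numerical choices and degenerate inputs

* Standardization guards division by zero with `1e-8`; a constant trace
  maps to zeros.
* The loss epsilon keeps zero-variance chunks finite; such chunks are
  retained in training.
* Framing of a length-1 signal yields one fully padded frame; forward
  output length always equals input length (asserted for lengths 1
  through 5000).
* Spike CSV cells must be within `1e-6` of a non-negative integer; ragged
  columns may be padded only at the bottom, and an interior empty cell is
  treated as corruption, never interpolated — safer for ground truth.
* Calcium/spike column pairs differing by at most 2 samples are trimmed
  to the shorter length (a 10–20 ms trim is invisible to the metrics);
  larger mismatches are errors.
* CSV floats are written with 17 significant digits so write-then-read is
  the identity at double precision.

## Interpretability

`layer_responses()` feeds a trace through the network and returns each
layer's post-activation channel sum per frame (the "total response"; sum
is the literal reading of that phrase), ending with the spike estimate
itself. `filter_frequency_response()` zero-pads each kernel to a 1024-point
DFT (a resolution choice) and sums magnitude spectra over the filter bank,
for the analysis kernels and for the rows of the synthesis map treated as
length-100 time signals. On trained networks the analysis response
concentrates at low frequencies where the indicator transient lives, while
synthesis filters develop structure at spike time-scales; these are
qualitative observations for reporting, not test assertions.

## Worked example

```{r example, eval = FALSE}
library(spikesig)

# a small synthetic benchmark: 8 neurons x 60 s at 100 Hz
paths <- make_benchmark(8, sim_config(seed = 42), "bench")
recs <- pair_recordings(read_column_csv(paths$calcium, "calcium"),
                        read_column_csv(paths$spikes, "spikes"),
                        dataset_id = "synthetic")

fit <- fit_s2s(s2s_config(seed = 7), train_config(seed = 1), recs)
print(fit$history)

heldout <- split_train_val(recs, 0.2, seed = 1)$val
ests <- lapply(heldout, function(r) s2s_forward(fit$params, r$trace))
evaluate_estimates(ests, heldout)
```

The printed result reports per-recording Pearson/Spearman/AUC at 25 Hz
and their dataset and grand means. The same pipeline is scriptable from a
shell through the installed `cli/spikesig` entry point (`simulate`,
`train`, `predict`, `evaluate`, `inspect`).

## Known limitations

* Trained and evaluated entirely at 100 Hz input / 25 or 100 Hz
  evaluation; other rates require resampling upstream.
* The estimate is a real-valued spike *signal* (a rate-like quantity up
  to scale), not a thresholded event train.
* Single-neuron traces only; no joint multi-neuron model, no recurrent
  layers, no contextual dataset inputs.
* Conclusions drawn from the synthetic benchmark transfer to real data
  only to the extent the simulator's assumptions (exact timing,
  stationary kernel, Gaussian noise) hold there; see above.
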