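# The spikefinder evaluation protocol: bin estimate and ground truth to
# the evaluation rate (40 ms bins by default), then score each recording
# with Pearson, Spearman and ROC-AUC, aggregating dataset-wise.

#' Evaluation configuration
#'
#' @param native_fs Sampling rate of the signals in Hz (default 100).
#' @param eval_fs Evaluation rate in Hz; must divide `native_fs`. The
#'   default 25 Hz corresponds to 40 ms bins; 100 Hz evaluates at the
#'   native resolution (bin factor 1).
#' @return An object of class `eval_config` with the derived bin `factor`.
#' @export
eval_config <- function(native_fs = 100, eval_fs = 25) {
  native_fs <- check_number(native_fs, "native_fs", lower = 0, strict_lower = TRUE)
  eval_fs <- check_number(eval_fs, "eval_fs", lower = 0, strict_lower = TRUE)
  factor <- native_fs / eval_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop_param("native_fs must be divisible by eval_fs")
  }
  structure(list(native_fs = native_fs, eval_fs = eval_fs,
                 factor = as.integer(round(factor))),
            class = "eval_config")
}

#' Sum a signal into fixed-width bins
#'
#' `output[i] = sum(x[(i-1)*factor + 1 : i*factor])`; a trailing remainder
#' of fewer than `factor` samples is dropped, so the output has
#' `floor(length(x) / factor)` bins. Factor 1 is the identity.
#'
#' @param x Numeric signal.
#' @param factor Integer bin width in samples (>= 1).
#' @return Numeric vector of bin sums.
#' @export
bin_signal <- function(x, factor) {
  factor <- check_count(factor, "factor", min = 1L)
  n_bins <- length(x) %/% factor
  if (n_bins == 0L) return(numeric(0))
  if (factor == 1L) return(as.numeric(x)[seq_len(n_bins)])
  colSums(matrix(as.numeric(x)[seq_len(n_bins * factor)], factor, n_bins))
}

#' Pearson product-moment correlation
#'
#' @param a,b Equal-length numeric vectors, length >= 2, both non-constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_corr <- function(a, b) {
  check_metric_inputs(a, b)
  stats::cor(a, b, method = "pearson")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie-adjusted ranks.
#'
#' @param a,b Equal-length numeric vectors, length >= 2, both non-constant.
#' @return Rank correlation coefficient in `[-1, 1]`.
#' @export
spearman_corr <- function(a, b) {
  check_metric_inputs(a, b)
  stats::cor(a, b, method = "spearman")
}

check_metric_inputs <- function(a, b) {
  if (length(a) != length(b)) stop_param("inputs must have equal length")
  if (length(a) < 2L) stop_param("inputs must have length >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_param("inputs must be finite")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_param("correlation undefined for a constant input")
  }
  invisible(TRUE)
}

#' ROC area under the curve with tie handling
#'
#' Probability that a randomly chosen positive bin scores above a randomly
#' chosen negative bin, counting ties as one half:
#' `P(s+ > s-) + P(s+ = s-)/2`. Computed via the tie-adjusted rank-sum
#' (Mann-Whitney) identity.
#'
#' @param scores Numeric scores, one per bin.
#' @param labels Binary labels (`0`/`1` or logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop_param("scores and labels must have equal length")
  }
  if (any(!is.finite(scores))) stop_param("scores must be finite")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_param("AUC undefined: labels contain a single class")
  }
  r <- rank(scores)  # average ranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate spike estimates against ground truth
#'
#' Both the estimate and the ground-truth spike counts are summed into
#' `native_fs / eval_fs`-sample bins; each recording is scored with
#' Pearson, Spearman (on the binned sequences) and ROC-AUC (label: bin
#' contains at least one spike, score: binned estimate). A recording whose
#' binned estimate or ground truth is constant is excluded from the
#' affected metric's averages with a warning. Dataset means are unweighted
#' means over their recordings, and the grand mean is the unweighted mean
#' over dataset means.
#'
#' @param estimates List of [s2s_forward()] outputs (or plain numeric
#'   vectors), matched one-to-one with `recordings`.
#' @param recordings List of [recording()] objects.
#' @param cfg An [eval_config()].
#' @return An object of class `eval_result`: `per_recording` and
#'   `per_dataset` data frames plus the `grand` named vector
#'   (pearson, spearman, auc).
#' @export
evaluate_estimates <- function(estimates, recordings, cfg = eval_config()) {
  stopifnot(inherits(cfg, "eval_config"))
  if (length(estimates) != length(recordings)) {
    stop_param("estimates and recordings must have equal length")
  }
  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    est <- estimates[[i]]
    if (inherits(est, "spike_estimate")) est <- est$values
    if (length(est) != length(rec$spikes)) {
      stop_param("recording ", rec$neuron_id, ": estimate length ",
                 length(est), " does not match ground truth length ",
                 length(rec$spikes))
    }
    be <- bin_signal(est, cfg$factor)
    bs <- bin_signal(rec$spikes, cfg$factor)
    metric <- function(f, ...) {
      tryCatch(f(...), error = function(e) {
        warning("recording ", rec$dataset_id, "/", rec$neuron_id,
                " excluded from a metric: ", conditionMessage(e),
                call. = FALSE)
        NA_real_
      })
    }
    rows[[i]] <- data.frame(
      dataset_id = rec$dataset_id, neuron_id = rec$neuron_id,
      pearson = metric(pearson_corr, be, bs),
      spearman = metric(spearman_corr, be, bs),
      auc = metric(roc_auc, be, bs > 0),
      stringsAsFactors = FALSE)
  }
  per_recording <- do.call(rbind, rows)
  agg <- function(df) {
    c(pearson = mean(df$pearson, na.rm = TRUE),
      spearman = mean(df$spearman, na.rm = TRUE),
      auc = mean(df$auc, na.rm = TRUE))
  }
  datasets <- unique(per_recording$dataset_id)
  per_dataset <- do.call(rbind, lapply(datasets, function(d) {
    stats <- agg(per_recording[per_recording$dataset_id == d, ])
    data.frame(dataset_id = d, pearson = stats["pearson"],
               spearman = stats["spearman"], auc = stats["auc"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  grand <- c(pearson = mean(per_dataset$pearson),
             spearman = mean(per_dataset$spearman),
             auc = mean(per_dataset$auc))
  structure(list(per_recording = per_recording, per_dataset = per_dataset,
                 grand = grand, eval_fs = cfg$eval_fs),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Evaluation at %g Hz over %d recordings (%d datasets)\n",
              x$eval_fs, nrow(x$per_recording), nrow(x$per_dataset)))
  cat(sprintf("  grand means: Pearson %.4f, Spearman %.4f, AUC %.4f\n",
              x$grand["pearson"], x$grand["spearman"], x$grand["auc"]))
  invisible(x)
}

# delimited metrics report: per-recording rows, dataset rows, grand row
format_eval_report <- function(result) {
  stopifnot(inherits(result, "eval_result"))
  fmt <- function(scope, id, p, s, a) {
    sprintf("%s\t%s\t%.6f\t%.6f\t%.6f", scope, id, p, s, a)
  }
  lines <- c("scope\tid\tpearson\tspearman\tauc")
  pr <- result$per_recording
  for (i in seq_len(nrow(pr))) {
    lines <- c(lines, fmt("recording",
                          paste0(pr$dataset_id[i], "/", pr$neuron_id[i]),
                          pr$pearson[i], pr$spearman[i], pr$auc[i]))
  }
  pd <- result$per_dataset
  for (i in seq_len(nrow(pd))) {
    lines <- c(lines, fmt("dataset", pd$dataset_id[i], pd$pearson[i],
                          pd$spearman[i], pd$auc[i]))
  }
  c(lines, fmt("grand", "all", result$grand["pearson"],
               result$grand["spearman"], result$grand["auc"]))
}
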