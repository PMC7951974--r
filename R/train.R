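# Training: Pearson-correlation loss, recording-level train/validation
# split, chunked batches, Adam, and patience-based early stopping with
# best-weights restoration.

#' Training configuration
#'
#' @param learning_rate Adam starting learning rate (default 0.001).
#' @param batch_size Chunks per optimization step (default 20).
#' @param patience Epochs without validation improvement before stopping
#'   (default 6).
#' @param max_epochs Upper bound on epochs (default 100).
#' @param chunk_len Training-chunk length in samples (default 1000, i.e.
#'   10 s at 100 Hz); must be at least the frame length.
#' @param val_fraction Fraction of recordings held out for validation,
#'   strictly between 0 and 1 (default 0.2).
#' @param seed Integer seed for the split and epoch shuffling.
#' @param target_spec A [gaussian_target_spec()] for the training targets.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 20L,
                         patience = 6L, max_epochs = 100L, chunk_len = 1000L,
                         val_fraction = 0.2, seed = 1L,
                         target_spec = gaussian_target_spec()) {
  stopifnot(inherits(target_spec, "gaussian_target_spec"))
  structure(
    list(learning_rate = check_number(learning_rate, "learning_rate",
                                      lower = 0, strict_lower = TRUE),
         batch_size = check_count(batch_size, "batch_size", min = 1L),
         patience = check_count(patience, "patience", min = 1L),
         max_epochs = check_count(max_epochs, "max_epochs", min = 1L),
         chunk_len = check_count(chunk_len, "chunk_len", min = 1L),
         val_fraction = check_number(val_fraction, "val_fraction", lower = 0,
                                     upper = 1, strict_lower = TRUE,
                                     strict_upper = TRUE),
         seed = check_seed(seed),
         target_spec = target_spec),
    class = "train_config")
}

#' Negative Pearson correlation loss
#'
#' Returns `-r` where `r = cov(pred, target) / ((sd(pred) + eps) *
#' (sd(target) + eps))` with `eps = 1e-8`. Minimizing this loss maximizes
#' the Pearson correlation between the network's estimate and the target
#' spike signal; the epsilon guard keeps constant sequences finite.
#'
#' @param pred,target Equal-length numeric sequences, length >= 2.
#' @return Scalar loss in `[-1, 1]` up to the tiny epsilon-induced slack.
#' @export
correlation_loss <- function(pred, target) {
  correlation_loss_grad(pred, target)$loss
}

# loss plus its gradient in pred, shared by training
correlation_loss_grad <- function(pred, target) {
  if (length(pred) != length(target)) {
    stop_param("pred and target must have equal length (",
               length(pred), " vs ", length(target), ")")
  }
  n <- length(pred)
  if (n < 2L) stop_param("sequences must have length >= 2")
  eps <- 1e-8
  pc <- pred - mean(pred)
  tc <- target - mean(target)
  sp <- sqrt(sum(pc^2) / (n - 1))
  st <- sqrt(sum(tc^2) / (n - 1))
  cv <- sum(pc * tc) / (n - 1)
  r <- cv / ((sp + eps) * (st + eps))
  grad <- -(tc / ((n - 1) * (sp + eps) * (st + eps)))
  if (sp > 0) {
    grad <- grad + cv * pc / ((n - 1) * sp * (sp + eps)^2 * (st + eps))
  }
  list(loss = -r, grad = grad)
}

#' Cut recordings into fixed-length training chunks
#'
#' Each recording's trace is standardized once at the recording level,
#' its spike train is smoothed into the training target, and both are
#' sliced into non-overlapping consecutive chunks of `chunk_len` samples.
#' A final chunk shorter than `min_len` (the frame length) is dropped;
#' chunks with zero target variance are retained (the loss epsilon guard
#' handles them).
#'
#' @param recordings List of [recording()] objects.
#' @param chunk_len Chunk length in samples.
#' @param min_len Minimum usable chunk length (default 100 = `w_seq`).
#' @param target_spec A [gaussian_target_spec()].
#' @param standardize Standardize each recording's trace first (default
#'   `TRUE`).
#' @return List of chunks: each a list with `trace`, `target`, `spikes`,
#'   `dataset_id`, `neuron_id`.
#' @export
chunk_recordings <- function(recordings, chunk_len, min_len = 100L,
                             target_spec = gaussian_target_spec(),
                             standardize = TRUE) {
  chunk_len <- check_count(chunk_len, "chunk_len", min = 1L)
  min_len <- check_count(min_len, "min_len", min = 1L)
  if (chunk_len < min_len) stop_param("chunk_len must be >= min_len")
  out <- list()
  for (rec in recordings) {
    stopifnot(inherits(rec, "recording"))
    tr <- if (standardize) standardize_trace(rec$trace) else rec$trace
    tg <- smooth_targets(rec$spikes, target_spec)
    n <- length(tr)
    starts <- seq.int(1L, n, by = chunk_len)
    for (s in starts) {
      e <- min(s + chunk_len - 1L, n)
      if (e - s + 1L >= min_len) {
        out[[length(out) + 1L]] <- list(
          trace = tr[s:e], target = tg[s:e], spikes = rec$spikes[s:e],
          dataset_id = rec$dataset_id, neuron_id = rec$neuron_id)
      }
    }
  }
  out
}

#' Split recordings into training and validation sets
#'
#' The split is at the recording level, so no part of one neuron's data
#' appears in both sets. The validation set holds
#' `max(1, round(val_fraction * N))` recordings (never all of them);
#' deterministic for a fixed seed.
#'
#' @param recordings List of at least two [recording()] objects.
#' @param val_fraction Validation fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `val`.
#' @export
split_train_val <- function(recordings, val_fraction = 0.2, seed = 1L) {
  n <- length(recordings)
  if (n < 2L) stop_param("need at least 2 recordings to split")
  val_fraction <- check_number(val_fraction, "val_fraction", lower = 0,
                               upper = 1, strict_lower = TRUE,
                               strict_upper = TRUE)
  set.seed(check_seed(seed))
  n_val <- min(max(1L, as.integer(round(val_fraction * n))), n - 1L)
  perm <- sample.int(n)
  val_idx <- perm[seq_len(n_val)]
  list(train = recordings[setdiff(perm, val_idx)],
       val = recordings[sort(val_idx)])
}

# loss and parameter gradients for one chunk (trace already standardized)
chunk_loss_grad <- function(params, frames, pad_left, target) {
  n <- length(target)
  acts <- forward_layers(params, frames)
  y <- overlap_add(acts$synthesis, pad_left, n)
  lg <- correlation_loss_grad(y, target)

  w <- params$config$w_seq
  cov <- ola_coverage(n, w)
  gpad <- numeric(n + w - 1L)
  idx <- (pad_left + 1L):(pad_left + n)
  gpad[idx] <- lg$grad / cov[idx]
  # transpose of overlap-add: dS[i, j] = gpad[i + j - 1]
  dS <- matrix(0, n, w)
  for (j in seq_len(w)) dS[, j] <- gpad[j:(j + n - 1L)]

  n_hidden <- length(params$hidden)
  H_last <- if (n_hidden > 0L) acts$hidden[[n_hidden]] else acts$analysis
  grads <- list(W_out = crossprod(H_last, dS))
  dH <- dS %*% t(params$W_out)
  for (i in rev(seq_len(n_hidden))) {
    Hi <- acts$hidden[[i]]
    dZ <- dH * (Hi > 0)
    prev <- if (i > 1L) acts$hidden[[i - 1L]] else acts$analysis
    grads[[paste0("W_h", i)]] <- crossprod(prev, dZ)
    grads[[paste0("b_h", i)]] <- colSums(dZ)
    dH <- dZ %*% t(params$hidden[[i]]$W)
  }
  dZ1 <- dH * (acts$analysis > 0)
  grads$W_in <- crossprod(frames, dZ1)
  grads$b_in <- colSums(dZ1)
  list(loss = lg$loss, grads = grads)
}

#' Training history
#'
#' Returned by [fit_s2s()]: per-epoch training and validation losses, the
#' epoch whose parameters were kept, and whether patience stopped training
#' before `max_epochs`.
#'
#' @name train_history
NULL

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf(
    "Training history: %d epochs, best validation loss %.4f at epoch %d%s\n",
    length(x$val_loss), x$val_loss[x$best_epoch], x$best_epoch,
    if (x$stopped_early) " (early stop)" else ""))
  invisible(x)
}

#' Fit the network on paired recordings
#'
#' Recordings are split 80/20 at the recording level, chunked, and the
#' network is trained with Adam (starting learning rate and batch size from
#' `tcfg`) on the negative Pearson correlation between the estimate and the
#' smoothed spike target, computed per chunk and averaged over the batch.
#' After each epoch the mean validation-chunk loss is computed; training
#' stops when it has not improved for `patience` consecutive epochs (or at
#' `max_epochs`), and the parameters of the best-validation epoch are
#' returned. Fully deterministic for fixed seeds on a single-threaded run.
#'
#' @param config An [s2s_config()].
#' @param tcfg A [train_config()].
#' @param recordings List of at least two [recording()] objects.
#' @param quiet Suppress the per-epoch progress line (default `TRUE`).
#' @return List with `params` (an `s2s_params` at the best epoch) and
#'   `history` (a `train_history`).
#' @export
fit_s2s <- function(config, tcfg, recordings, quiet = TRUE) {
  stopifnot(inherits(config, "s2s_config"), inherits(tcfg, "train_config"))
  if (tcfg$chunk_len < config$w_seq) {
    stop_param("chunk_len must be at least w_seq")
  }
  split <- split_train_val(recordings, tcfg$val_fraction, tcfg$seed)
  train_chunks <- chunk_recordings(split$train, tcfg$chunk_len,
                                   min_len = config$w_seq,
                                   target_spec = tcfg$target_spec)
  val_chunks <- chunk_recordings(split$val, tcfg$chunk_len,
                                 min_len = config$w_seq,
                                 target_spec = tcfg$target_spec)
  if (length(train_chunks) == 0L) stop_param("no usable training chunks")

  prep <- function(ch) {
    fr <- frame_signal(ch$trace, config$w_seq)
    list(frames = fr$frames, pad_left = fr$pad_left, target = ch$target)
  }
  train_prep <- lapply(train_chunks, prep)
  val_prep <- lapply(val_chunks, prep)

  params <- build_network(config)
  arrays <- weight_arrays(params)
  skeleton <- utils::as.relistable(arrays)
  theta <- unlist(skeleton, use.names = FALSE)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L

  val_loss_of <- function(params) {
    if (length(val_prep) == 0L) return(NA_real_)
    mean(vapply(val_prep, function(p) {
      acts <- forward_layers(params, p$frames)
      y <- overlap_add(acts$synthesis, p$pad_left, length(p$target))
      correlation_loss(y, p$target)
    }, numeric(1)))
  }

  set.seed(tcfg$seed + 1L)
  n_tr <- length(train_prep)
  train_hist <- numeric(0)
  val_hist <- numeric(0)
  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  since_best <- 0L
  stopped_early <- FALSE

  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(n_tr)
    epoch_losses <- numeric(n_tr)
    pos <- 1L
    while (pos <= n_tr) {
      batch <- ord[pos:min(pos + tcfg$batch_size - 1L, n_tr)]
      pos <- pos + tcfg$batch_size
      gsum <- NULL
      for (ci in batch) {
        p <- train_prep[[ci]]
        res <- chunk_loss_grad(params, p$frames, p$pad_left, p$target)
        epoch_losses[ci] <- res$loss
        gvec <- unlist(res$grads[names(arrays)], use.names = FALSE)
        gsum <- if (is.null(gsum)) gvec else gsum + gvec
      }
      g <- gsum / length(batch)
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^step)
      vhat <- v / (1 - beta2^step)
      theta <- theta - tcfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      params <- set_weight_arrays(params, utils::relist(theta, skeleton))
    }
    train_hist[epoch] <- mean(epoch_losses)
    val_hist[epoch] <- val_loss_of(params)
    if (!quiet) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      train_hist[epoch], val_hist[epoch]))
    }
    score <- if (is.na(val_hist[epoch])) train_hist[epoch] else val_hist[epoch]
    if (score < best_val) {
      best_val <- score
      best_theta <- theta
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= tcfg$patience) {
        stopped_early <- TRUE
        break
      }
    }
  }

  params <- set_weight_arrays(params, utils::relist(best_theta, skeleton))
  history <- structure(
    list(train_loss = train_hist, val_loss = val_hist,
         best_epoch = best_epoch, stopped_early = stopped_early,
         n_train_chunks = length(train_prep),
         n_val_chunks = length(val_prep)),
    class = "train_history")
  list(params = params, history = history)
}
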