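# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and stats::cor) so they can serve as cross-checks.

naive_pearson <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# average ranks computed by pairwise counting
naive_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

naive_spearman <- function(a, b) {
  naive_pearson(naive_rank(a), naive_rank(b))
}

# exhaustive positive/negative pair enumeration with half-credit ties
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# sliding window over the centred zero-padded signal
naive_frames <- function(x, w) {
  n <- length(x)
  pad_left <- floor((w - 1) / 2)
  xp <- c(rep(0, pad_left), x, rep(0, w - 1 - pad_left))
  out <- matrix(0, n, w)
  for (i in seq_len(n)) out[i, ] <- xp[i:(i + w - 1)]
  list(frames = out, pad_left = pad_left)
}

# accumulate frame f at padded positions [f, f+w-1], divide by coverage
naive_ola <- function(frames, pad_left, out_len) {
  n <- nrow(frames)
  w <- ncol(frames)
  acc <- rep(0, n + w - 1)
  cov <- rep(0, n + w - 1)
  for (f in seq_len(n)) {
    for (j in seq_len(w)) {
      acc[f + j - 1] <- acc[f + j - 1] + frames[f, j]
      cov[f + j - 1] <- cov[f + j - 1] + 1
    }
  }
  (acc / cov)[(pad_left + 1):(pad_left + out_len)]
}

# per-frame loop through the network, explicit inner products
naive_forward <- function(params, x) {
  cfg <- params$config
  fr <- naive_frames(x, cfg$w_seq)
  n <- length(x)
  outs <- matrix(0, n, cfg$w_seq)
  for (i in seq_len(n)) {
    v <- fr$frames[i, ]
    a <- pmax(as.numeric(v %*% params$W_in) + params$b_in, 0)
    h <- a
    for (layer in params$hidden) {
      h <- pmax(as.numeric(h %*% layer$W) + layer$b, 0)
    }
    outs[i, ] <- as.numeric(h %*% params$W_out)
  }
  naive_ola(outs, fr$pad_left, n)
}

# per-event superposition of the indicator transient
naive_superposition <- function(spikes, kernel, amp) {
  n <- length(spikes)
  y <- rep(0, n)
  for (i in which(spikes > 0)) {
    for (j in seq_along(kernel)) {
      t <- i + j - 1
      if (t <= n) y[t] <- y[t] + spikes[i] * amp * kernel[j]
    }
  }
  y
}

random_tiny_config <- function() {
  n_hidden <- sample(0:3, 1)
  s2s_config(w_seq = sample(3:12, 1), n_filt = sample(1:4, 1),
             n_hidden = n_hidden,
             n_units = if (n_hidden > 0) sample(1:4, n_hidden, replace = TRUE)
                       else integer(0),
             seed = sample.int(10000, 1))
}
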