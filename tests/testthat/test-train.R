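test_that("correlation loss matches the textbook Pearson formula", {
  set.seed(20)
  x <- rnorm(50)
  expect_equal(correlation_loss(x, x), -1, tolerance = 1e-6)
  expect_equal(correlation_loss(x, -x), 1, tolerance = 1e-6)

  for (rep in 1:20) {
    a <- rnorm(50)
    b <- rnorm(50)
    expect_equal(correlation_loss(a, b), -naive_pearson(a, b),
                 tolerance = 1e-7)
  }
  expect_error(correlation_loss(rnorm(5), rnorm(6)),
               class = "spikesig_param_error")
  expect_error(correlation_loss(1, 1), class = "spikesig_param_error")
})

test_that("correlation loss is invariant under positive affine transforms", {
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(40)
    y <- rnorm(40)
    a <- runif(1, 0.1, 10)
    b <- rnorm(1)
    expect_equal(correlation_loss(a * x + b, y), correlation_loss(x, y),
                 tolerance = 1e-6)
    expect_equal(correlation_loss(x, a * y + b), correlation_loss(x, y),
                 tolerance = 1e-6)
  }
  # constant sequences stay finite through the epsilon guard
  expect_true(is.finite(correlation_loss(rep(1, 10), rnorm(10))))
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(22)
  pred <- rnorm(30)
  target <- rnorm(30)
  g <- spikesig:::correlation_loss_grad(pred, target)$grad
  h <- 1e-6
  for (i in c(1, 7, 30)) {
    up <- pred; up[i] <- up[i] + h
    dn <- pred; dn[i] <- dn[i] - h
    num <- (correlation_loss(up, target) - correlation_loss(dn, target)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("chunking follows the drop rule and the slicing oracle", {
  rec <- recording(rnorm(2500), rpois(2500, 0.01), "d", "n")
  chunks <- chunk_recordings(list(rec), 1000, min_len = 100)
  expect_length(chunks, 3)
  expect_identical(lengths(lapply(chunks, `[[`, "trace")),
                   c(1000L, 1000L, 500L))

  short <- recording(rnorm(50), integer(50))
  expect_length(chunk_recordings(list(short), 1000, min_len = 100), 0)

  # boundaries equal a naive slicing loop on the standardized trace
  tr <- standardize_trace(rec$trace)
  tg <- smooth_targets(rec$spikes, gaussian_target_spec())
  for (i in seq_along(chunks)) {
    idx <- ((i - 1) * 1000 + 1):min(i * 1000, 2500)
    expect_equal(chunks[[i]]$trace, tr[idx], tolerance = 0)
    expect_equal(chunks[[i]]$target, tg[idx], tolerance = 0)
  }
})

test_that("the train/validation split is a seeded recording-level partition", {
  recs <- lapply(1:10, function(i) {
    recording(rnorm(200), rpois(200, 0.02), "d", as.character(i))
  })
  sp <- split_train_val(recs, 0.2, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$val, 2)

  sp2 <- split_train_val(recs, 0.2, seed = 3)
  expect_identical(vapply(sp$val, `[[`, "", "neuron_id"),
                   vapply(sp2$val, `[[`, "", "neuron_id"))

  ids <- sort(c(vapply(sp$train, `[[`, "", "neuron_id"),
                vapply(sp$val, `[[`, "", "neuron_id")))
  expect_identical(ids, sort(vapply(recs, `[[`, "", "neuron_id")))

  expect_error(split_train_val(recs[1], 0.2, 1),
               class = "spikesig_param_error")
})

test_that("training is deterministic and returns the best-validation epoch", {
  cfg <- sim_config(duration_s = 20, seed = 60)
  recs <- lapply(1:4, function(i) {
    c2 <- cfg; c2$seed <- cfg$seed + i
    simulate_recording(c2, neuron_id = as.character(i))
  })
  mcfg <- s2s_config(n_hidden = 1, seed = 2)
  tcfg <- train_config(max_epochs = 4, chunk_len = 500, batch_size = 4,
                       seed = 9)
  f1 <- fit_s2s(mcfg, tcfg, recs)
  f2 <- fit_s2s(mcfg, tcfg, recs)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  expect_identical(f1$params$W_in, f2$params$W_in)

  h <- f1$history
  expect_lte(h$best_epoch, length(h$val_loss))
  expect_lte(h$val_loss[h$best_epoch], h$val_loss[1])
  expect_true(all(is.finite(h$train_loss)))

  expect_error(fit_s2s(mcfg, train_config(chunk_len = 50), recs),
               class = "spikesig_param_error")
})

test_that("a short training run reduces the loss on its own data", {
  cfg <- sim_config(duration_s = 30, noise_sigma = 0.05, seed = 70)
  recs <- lapply(1:5, function(i) {
    c2 <- cfg; c2$seed <- cfg$seed + i
    simulate_recording(c2, neuron_id = as.character(i))
  })
  tcfg <- train_config(max_epochs = 10, chunk_len = 1000, seed = 4)
  f <- fit_s2s(s2s_config(n_hidden = 1, seed = 3), tcfg, recs)
  h <- f$history
  expect_lt(h$val_loss[length(h$val_loss)], h$val_loss[1] - 0.1)
})
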