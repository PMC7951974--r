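test_that("binning sums fixed-width windows and drops the remainder", {
  expect_equal(bin_signal(1:8, 4), c(10, 26))
  expect_equal(bin_signal(1:10, 4), c(10, 26))  # trailing 2 samples dropped
  expect_equal(bin_signal(rnorm(5), 6), numeric(0))

  x <- rnorm(40)
  expect_equal(bin_signal(x, 1), x)              # identity
  expect_equal(sum(bin_signal(x, 4)), sum(x))    # conservation
  expect_equal(bin_signal(bin_signal(x, 4), 1), bin_signal(x, 4))

  expect_error(bin_signal(x, 0), class = "spikesig_param_error")
})

test_that("correlation metrics match brute-force oracles on random inputs", {
  set.seed(30)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    a <- sample(0:4, n, replace = TRUE) + rnorm(n, 0, 0.3)  # ties likely
    b <- sample(0:3, n, replace = TRUE)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    expect_equal(pearson_corr(a, b), naive_pearson(a, b), tolerance = 1e-12)
    expect_equal(spearman_corr(a, b), naive_spearman(a, b),
                 tolerance = 1e-12)
  }
  x <- rnorm(30)
  expect_equal(pearson_corr(x, 2 * x + 3), 1, tolerance = 1e-12)
  expect_equal(spearman_corr(x, exp(x)), 1, tolerance = 1e-12)
  expect_equal(spearman_corr(x, -x), -1, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)),
               class = "spikesig_param_error")
  expect_error(spearman_corr(rnorm(5), rep(2, 5)),
               class = "spikesig_param_error")
})

test_that("AUC equals exhaustive pair counting with tie credit", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 0, 1)), 0.5)

  set.seed(31)
  for (rep in 1:100) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels), naive_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rnorm(5), rep(1, 5)), class = "spikesig_param_error")
})

test_that("metrics are invariant to positive rescaling of the estimate", {
  set.seed(32)
  est <- rexp(200)
  spikes <- rpois(200, 0.2)
  labels <- bin_signal(spikes, 4) > 0
  be <- bin_signal(est, 4)
  bs <- bin_signal(spikes, 4)
  for (a in c(0.01, 3, 1000)) {
    expect_equal(pearson_corr(a * be, bs), pearson_corr(be, bs),
                 tolerance = 1e-12)
    expect_equal(spearman_corr(a * be, bs), spearman_corr(be, bs),
                 tolerance = 1e-12)
    expect_equal(roc_auc(a * be, labels), roc_auc(be, labels),
                 tolerance = 1e-12)
  }
})

test_that("evaluation aggregates dataset-wise then grand", {
  set.seed(33)
  mk <- function(dataset, id) {
    spikes <- rpois(400, 0.1)
    recording(rnorm(400), spikes, dataset, id)
  }
  recs <- list(mk("d1", "a"), mk("d2", "b"), mk("d2", "c"), mk("d2", "d"))
  # noisy copies of the truth as estimates
  ests <- lapply(recs, function(r) r$spikes + rnorm(400, 0, 0.4))
  res <- evaluate_estimates(ests, recs, eval_config())

  # hand-computed dataset-then-grand mean
  per <- res$per_recording
  d1 <- mean(per$pearson[per$dataset_id == "d1"])
  d2 <- mean(per$pearson[per$dataset_id == "d2"])
  expect_equal(unname(res$grand["pearson"]), mean(c(d1, d2)),
               tolerance = 1e-12)

  # perfect estimates score 1 everywhere
  perfect <- evaluate_estimates(lapply(recs, function(r) as.numeric(r$spikes)),
                                recs, eval_config())
  expect_equal(unname(perfect$grand), c(1, 1, 1), tolerance = 1e-12)
  expect_true(all(perfect$per_recording$auc == 1))

  # native-rate path: factor 1
  res100 <- evaluate_estimates(ests, recs, eval_config(eval_fs = 100))
  expect_equal(unname(res100$per_recording$pearson[1]),
               pearson_corr(ests[[1]], recs[[1]]$spikes), tolerance = 1e-12)

  expect_error(eval_config(eval_fs = 30), class = "spikesig_param_error")
  expect_error(evaluate_estimates(ests[1:2], recs),
               class = "spikesig_param_error")
})

test_that("recordings with constant binned signals are excluded with a warning", {
  recs <- list(recording(rnorm(100), integer(100), "d", "silent"),
               recording(rnorm(100), rpois(100, 0.3), "d", "active"))
  ests <- lapply(recs, function(r) r$spikes + rnorm(100, 0, 0.1))
  warns <- capture_warnings(res <- evaluate_estimates(ests, recs))
  expect_match(warns, "excluded", all = TRUE)
  expect_true(is.na(res$per_recording$pearson[1]))
  expect_false(is.na(res$per_recording$pearson[2]))
  # the grand mean still reflects the scorable recording
  expect_true(is.finite(res$grand["pearson"]))
})
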