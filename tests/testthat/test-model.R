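actual_scalar_count <- function(params) {
  n <- length(params$W_in) + length(params$b_in) + length(params$W_out)
  for (layer in params$hidden) n <- n + length(layer$W) + length(layer$b)
  n
}

test_that("parameter accounting matches the allocated weights for 0-3 hidden layers", {
  expect_identical(count_parameters(s2s_config(n_hidden = 1, n_units = 30L)),
                   6960L)
  expect_identical(count_parameters(s2s_config(n_hidden = 0)), 6030L)
  expect_identical(count_parameters(s2s_config(n_hidden = 3)), 8820L)

  for (nh in 0:3) {
    cfg <- s2s_config(n_hidden = nh,
                      n_units = if (nh > 0) sample(5:40, nh) else integer(0),
                      seed = nh + 1)
    expect_identical(actual_scalar_count(build_network(cfg)),
                     count_parameters(cfg))
  }
})

test_that("initialization is seeded and structured as configured", {
  cfg <- s2s_config(seed = 123)
  p1 <- build_network(cfg)
  p2 <- build_network(cfg)
  expect_identical(p1$W_in, p2$W_in)
  expect_identical(p1$W_out, p2$W_out)
  expect_true(all(is.finite(unlist(lapply(p1$hidden, unlist)))))

  p0 <- build_network(s2s_config(n_hidden = 0))
  expect_length(p0$hidden, 0)
  expect_identical(dim(p0$W_out), c(30L, 100L))
})

test_that("framing pads symmetrically and matches the sliding-window oracle", {
  # degenerate single sample: one frame, all padding
  fr1 <- frame_signal(5, 100)
  expect_identical(dim(fr1$frames), c(1L, 100L))
  expect_equal(sum(fr1$frames != 0), 1)
  expect_equal(fr1$frames[1, fr1$pad_left + 1], 5)

  expect_identical(nrow(frame_signal(rnorm(500), 100)$frames), 500L)

  set.seed(8)
  for (rep in 1:20) {
    x <- rnorm(sample(1:60, 1))
    w <- sample(1:20, 1)
    got <- frame_signal(x, w)
    want <- naive_frames(x, w)
    expect_identical(got$pad_left, as.integer(want$pad_left))
    expect_equal(got$frames, want$frames, tolerance = 0)
  }
  expect_error(frame_signal(rnorm(5), 0), class = "spikesig_param_error")
})

test_that("overlap-add normalizes coverage and matches brute force", {
  # all-zero frames reconstruct silence
  expect_equal(overlap_add(matrix(0, 5, 3), 1, 5), rep(0, 5))

  # hand-checkable case: constant frames give a constant signal
  fr <- matrix(1, 4, 2)
  expect_equal(overlap_add(fr, 0, 4), naive_ola(fr, 0, 4))

  set.seed(9)
  for (rep in 1:30) {
    n <- sample(1:25, 1)
    w <- sample(1:12, 1)
    fr <- matrix(rnorm(n * w), n, w)
    pad_left <- (w - 1) %/% 2
    expect_equal(overlap_add(fr, pad_left, n), naive_ola(fr, pad_left, n),
                 tolerance = 1e-12)
  }
  expect_error(overlap_add(list(c(1, 2), c(1, 2, 3)), 0, 2),
               class = "spikesig_param_error")
})

test_that("forward pass matches the per-frame loop oracle and keeps length", {
  cfg <- s2s_config(seed = 4)
  params <- build_network(cfg)
  for (len in c(1, 99, 100, 101, 5000)) {
    est <- s2s_forward(params, rnorm(len))
    expect_length(est$values, len)
    expect_true(all(is.finite(est$values)))
  }

  set.seed(10)
  x <- rnorm(300)
  est <- s2s_forward(params, x, standardize = FALSE)
  expect_equal(est$values, naive_forward(params, x), tolerance = 1e-9)

  # zeroed parameters give a zero estimate (linear, bias-free synthesis)
  pz <- params
  pz$W_out[] <- 0
  expect_equal(s2s_forward(pz, x)$values, rep(0, 300))

  expect_error(s2s_forward(params, c(1, NA, 3)),
               class = "spikesig_param_error")
})

test_that("forward is shift-covariant away from the edges", {
  params <- build_network(s2s_config(seed = 14))
  set.seed(15)
  x <- rnorm(600)
  k <- 37
  y1 <- s2s_forward(params, x, standardize = FALSE)$values
  y2 <- s2s_forward(params, c(numeric(k), x), standardize = FALSE)$values
  interior <- 150:450  # >= w_seq from both edges of either signal
  expect_equal(y2[interior + k], y1[interior], tolerance = 1e-10)
})

test_that("checkpoints round-trip bit-exactly", {
  params <- build_network(s2s_config(seed = 77))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(params, path, extra = list(note = "fit"))
  back <- load_checkpoint(path)
  expect_identical(back$params$W_in, params$W_in)
  expect_identical(back$params$config, params$config)
  expect_identical(back$extra$note, "fit")

  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
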