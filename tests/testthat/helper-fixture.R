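# Shared synthetic benchmark fixture and trained models, built lazily and
# cached for the whole test run. Conditions: 20 neurons x 60 s at 100 Hz
# with the simulator defaults (rate 0.8 Hz, noise sd 0.2); fixture seed 42,
# model seed 7, training seed 1.

fixture_cache <- new.env(parent = emptyenv())

fixture_recordings <- function() {
  if (is.null(fixture_cache$recs)) {
    dir <- file.path(tempdir(), "spikesig-fixture")
    paths <- make_benchmark(20, sim_config(seed = 42), dir)
    fixture_cache$recs <- pair_recordings(
      read_column_csv(paths$calcium, "calcium"),
      read_column_csv(paths$spikes, "spikes"),
      dataset_id = "synthetic")
  }
  fixture_cache$recs
}

fixture_heldout <- function() {
  split_train_val(fixture_recordings(), 0.2, 1)$val
}

fixture_fit <- function(variant = c("gauss3", "disc3", "gauss0")) {
  variant <- match.arg(variant)
  key <- paste0("fit_", variant)
  if (is.null(fixture_cache[[key]])) {
    cfg <- switch(variant,
                  gauss3 = s2s_config(seed = 7),
                  disc3 = s2s_config(seed = 7),
                  gauss0 = s2s_config(seed = 7, n_hidden = 0))
    spec <- if (variant == "disc3") gaussian_target_spec(enabled = FALSE)
            else gaussian_target_spec()
    tcfg <- train_config(seed = 1, target_spec = spec)
    fixture_cache[[key]] <- fit_s2s(cfg, tcfg, fixture_recordings())
  }
  fixture_cache[[key]]
}

heldout_grand <- function(params, eval_fs = 25) {
  val <- fixture_heldout()
  ests <- lapply(val, function(r) s2s_forward(params, r$trace))
  evaluate_estimates(ests, val, eval_config(eval_fs = eval_fs))$grand
}
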