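# a quickly trained small autoencoder shared by the analysis tests
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- generate_fixtures(fixture_spec(size = 8, n_images = 16, seed = 1))
      ds <- encode_dataset(fx$images, eta = 0, seed = 1)
      cfg <- train_config(epochs = 15, seed = 1, learning_rate = 0.05,
                          learning_rate_pulses = 0.05,
                          nonpulse_init_multiplier = 0,
                          pulse_init_multiplier = 1)
      fit <- train_autoencoder(autoencoder_spec(64, 4), ds$inputs,
                               ds$targets, cfg)
      cache <<- list(fit = fit, ds = ds)
    }
    cache
  }
})

test_that("reconstruction error agrees with a direct per-image evaluation", {
  tf <- trained_fixture()
  net <- tf$fit$network; ds <- tf$ds; cfg <- tf$fit$config
  err <- reconstruction_error(net, ds$inputs, ds$targets, cfg)
  manual <- mean(vapply(seq_len(nrow(ds$inputs)), function(i) {
    out <- forward_pass(net, ds$inputs[i, ])$spikes[[3]]
    latency_loss(ds$targets[i, ], out, cfg$latency, cfg$surrogate) /
      sum(is.finite(ds$targets[i, ]))
  }, numeric(1)))
  expect_equal(err, manual)
  expect_gte(err, 0)
  # all-white targets carry no informative pixels: error is zero
  blank <- matrix(NO_SPIKE, 2, 64)
  expect_equal(reconstruction_error(net, blank, blank, cfg), 0)
  expect_error(reconstruction_error(net, ds$inputs[0, ], ds$targets[0, ],
                                    cfg), "empty")
})

test_that("spike histograms conserve the number of emitted spikes", {
  tf <- trained_fixture()
  net <- tf$fit$network; ds <- tf$ds
  sd_ <- spike_distribution(net, ds$inputs, breaks = 15)
  n <- nrow(ds$inputs)
  for (nm in c("layer1", "layer2")) {
    s <- sd_[[nm]]
    expect_identical(sum(s$counts), as.integer(s$n_spikes))
    size <- if (nm == "layer1") 4L else 64L
    expect_identical(s$n_spikes + s$n_silent, size * n)
  }
  expect_identical(sd_$layer1$pulse_times, net$layers[[1]]$pulse_times)

  # a silenced network produces an empty output histogram
  mute <- net
  mute$layers[[2]]$weights[] <- -abs(mute$layers[[2]]$weights) - 1
  sd2 <- spike_distribution(mute, ds$inputs[1:4, ])
  expect_identical(sum(sd2$layer2$counts), 0L)
  expect_identical(sd2$layer2$n_spikes, 0L)
})

test_that("weight summaries split classes correctly on a fresh network", {
  spec <- autoencoder_spec(100, 8, n_pulses = 10)
  net <- init_network(spec, nonpulse_multiplier = -2, pulse_multiplier = 3,
                      seed = 6)
  wd <- weight_distribution(net)
  expect_identical(nrow(wd), 4L)  # 2 layers x 2 classes
  expect_true(all(wd$q10 <= wd$q50 & wd$q50 <= wd$q90))
  # means within 3 standard errors of multiplier * sigma per class
  for (r in seq_len(nrow(wd))) {
    lay <- wd$layer[r]
    fan_in <- spec$layer_sizes[lay] + spec$n_pulses[lay]
    sigma <- sqrt(2 / (fan_in + spec$layer_sizes[lay + 1]))
    mult <- if (wd$class[r] == "regular") -2 else 3
    expect_lt(abs(wd$mean[r] - mult * sigma), 3 * sigma / sqrt(wd$n[r]))
  }
  # accounting: summarised weights = all parameters minus pulse times
  expect_identical(as.integer(sum(wd$n)),
                   param_count(spec) - sum(spec$n_pulses))
})

test_that("embeddings have one row per example and the silent sentinel", {
  tf <- trained_fixture()
  net <- tf$fit$network; ds <- tf$ds
  emb1 <- embed_dataset(net, ds$inputs)
  emb2 <- embed_dataset(net, ds$inputs)
  expect_identical(dim(emb1), c(16L, 4L))
  expect_identical(emb1, emb2)
  expect_true(all(emb1[is.finite(emb1)] >= 0))

  # interpolating two embeddings decodes to a valid image
  a <- emb1[1, ]; b <- emb1[2, ]
  for (lam in c(0, 0.25, 0.5, 1)) {
    mix <- lam * a + (1 - lam) * b
    px <- decode_embedding(net, mix, l = tf$fit$config$latency)
    expect_identical(length(px), 64L)
    expect_true(all(px >= 0 & px <= 1))
  }
})

test_that("the CLI drives the full pipeline reproducibly", {
  dir <- withr::local_tempdir()
  fx_prefix <- file.path(dir, "fx")
  run_cli(c("generate-fixtures", "--size", "8", "--n-images", "12",
            "--seed", "5", "--out", fx_prefix))
  expect_true(file.exists(paste0(fx_prefix, "-images.idx")))
  expect_identical(read_idx(paste0(fx_prefix, "-labels.idx"))[1:4], 0:3)

  cfg_path <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(epochs = 3, seed = 2, hidden = 3, n_pulses = 4,
                            eta = 0.2),
                       cfg_path, auto_unbox = TRUE)
  run_dir <- file.path(dir, "run")
  run_cli(c("train", "--config", cfg_path,
            "--data", paste0("idx:", fx_prefix, "-images.idx"),
            "--out", run_dir))
  expect_true(file.exists(file.path(run_dir, "model.json")))
  hist1 <- read.csv(file.path(run_dir, "history.csv"))
  expect_identical(nrow(hist1), 3L)
  expect_true(file.exists(file.path(run_dir, "run-config.json")))

  # rerunning the same config reproduces the loss history exactly
  run_dir2 <- file.path(dir, "run2")
  run_cli(c("train", "--config", cfg_path,
            "--data", paste0("idx:", fx_prefix, "-images.idx"),
            "--out", run_dir2))
  expect_identical(hist1, read.csv(file.path(run_dir2, "history.csv")))

  out_csv <- file.path(dir, "rec.csv")
  rec <- run_cli(c("reconstruct", "--model", file.path(run_dir, "model.json"),
                   "--data", paste0("idx:", fx_prefix, "-images.idx"),
                   "--out", out_csv))
  expect_true(file.exists(out_csv))
  expect_gte(rec$error, 0)

  emb_csv <- file.path(dir, "emb.csv")
  emb <- run_cli(c("embed", "--model", file.path(run_dir, "model.json"),
                   "--data", paste0("idx:", fx_prefix, "-images.idx"),
                   "--out", emb_csv))
  expect_identical(dim(emb), c(12L, 3L))
  expect_match(readLines(emb_csv, n = 1), "did not spike")

  ana_dir <- file.path(dir, "analysis")
  run_cli(c("analyze", "--model", file.path(run_dir, "model.json"),
            "--data", paste0("idx:", fx_prefix, "-images.idx"),
            "--out", ana_dir))
  expect_true(file.exists(file.path(ana_dir, "weight-distribution.csv")))
  expect_true(file.exists(file.path(ana_dir, "spike-distribution.csv")))

  expect_error(run_cli(character(0)), "usage")
  expect_error(run_cli(c("train", "--data", "nonsense:path")), "idx:|fixture:")
  expect_error(run_cli(c("embed", "--data", "fixture:size=8")), "--model")
})
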