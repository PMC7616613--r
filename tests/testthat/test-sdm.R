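test_that("the denoiser honours its shape contract and rejects bad configs", {
  cfg <- denoiser_config(image_size = 16, base_channels = 4,
                         channel_multipliers = c(1, 2),
                         timestep_embedding_dim = 8, seed = 1)
  den <- build_denoiser(cfg)
  y <- matrix(rnorm(256), 16, 16)
  out <- sdm_predict(den, y, 3, tiny_label_map(16))
  expect_identical(dim(out$eps), c(16L, 16L))
  expect_identical(dim(out$v), c(16L, 16L))
  expect_true(all(out$v > 0 & out$v < 1))
  expect_error(denoiser_config(image_size = 15, channel_multipliers = c(1, 2)),
               "divisible")
  expect_error(denoiser_config(n_label_classes = 1), "n_label_classes")
  expect_error(sdm_predict(den, matrix(0, 8, 8), 1, NULL), "grid")
})

test_that("conditioning and timestep embedding are live", {
  cfg <- denoiser_config(image_size = 16, base_channels = 8,
                         channel_multipliers = c(1, 2),
                         timestep_embedding_dim = 16, seed = 5)
  den <- build_denoiser(cfg)
  # zero-initialised residual branches make the raw output degenerate; train
  # a couple of steps so the probe sees a non-trivial function
  ds <- make_phantom_dataset(2, image_size = 16, profile = flat_profile(),
                             seed = 3)
  sched <- cosine_schedule(50)
  den <- train_sdm(ds, sched, steps = 30, batch_size = 4, model = den,
                   seed = 8)$model
  lm <- tiny_label_map(16)
  y <- matrix(rnorm(256), 16, 16)
  base <- sdm_predict(den, y, 5, lm)
  # permuting class identities must change the prediction
  perm <- as_label_map(matrix(c(0L, 2L, 1L, 3L, 4L)[unclass(lm) + 1L], 16, 16))
  permuted <- sdm_predict(den, y, 5, perm)
  expect_gt(max(abs(base$eps - permuted$eps)), 1e-8)
  # distinct timesteps give distinct outputs
  other_t <- sdm_predict(den, y, 40, lm)
  expect_gt(max(abs(base$eps - other_t$eps)), 1e-8)
})

test_that("training records state, decreases the simple loss and errors on empty data", {
  ds <- make_phantom_dataset(3, image_size = 16, profile = flat_profile(),
                             seed = 12)
  sched <- cosine_schedule(50)
  cfg <- denoiser_config(image_size = 16, base_channels = 8,
                         channel_multipliers = c(1, 2),
                         timestep_embedding_dim = 16, seed = 2)
  one <- train_sdm(ds, sched, steps = 1, batch_size = 2, config = cfg, seed = 4)
  expect_identical(nrow(one$history), 1L)
  expect_identical(one$model$step, 1L)
  fit <- train_sdm(ds, sched, steps = 300, batch_size = 4, config = cfg, seed = 4)
  expect_lt(mean(tail(fit$history$simple_term, 50)),
            mean(head(fit$history$simple_term, 50)))
  expect_true(all(diff(fit$history$lr) < 0))
  expect_error(train_sdm(list(), sched, steps = 1), "empty")
  expect_error(train_sdm(ds, sched, steps = 10, view = "2C", config = cfg,
                         seed = 1), NA)
})

test_that("the KL weight default matches the hybrid-objective configuration", {
  expect_equal(hybrid_loss_config()$kl_weight, 0.001)
  expect_error(hybrid_loss_config(-1), "kl_weight")
})

test_that("checkpoints round-trip bit-for-bit", {
  ds <- make_phantom_dataset(2, image_size = 16, profile = flat_profile(),
                             seed = 7)
  sched <- cosine_schedule(20)
  cfg <- denoiser_config(image_size = 16, base_channels = 4,
                         channel_multipliers = c(1, 2),
                         timestep_embedding_dim = 8, seed = 9)
  fit <- train_sdm(ds, sched, steps = 25, batch_size = 2, config = cfg, seed = 1)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, p)
  reloaded <- load_checkpoint(p)
  y <- matrix(rnorm(256), 16, 16)
  lm <- ds$samples[[1]]$label_map
  a <- sdm_predict(fit$model, y, 7, lm)
  b <- sdm_predict(reloaded, y, 7, lm)
  expect_identical(a, b)
  samp_a <- ddpm_sample(fit$model, lm, sched, rng_seed = 3)
  samp_b <- ddpm_sample(reloaded, lm, sched, rng_seed = 3)
  expect_identical(samp_a, samp_b)
})
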