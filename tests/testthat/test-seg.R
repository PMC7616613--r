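test_that("dice matches hand-computed values and conventions", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, 1 - a), 0.0)
  pred <- matrix(0, 4, 4); pred[1, 1:4] <- 1          # |pred| = 4
  gt <- matrix(0, 4, 4); gt[1, 3:4] <- 1; gt[2, 1:2] <- 1  # |gt| = 4, overlap 2
  expect_equal(dice(pred, gt), 0.5)
  zeros <- matrix(0, 3, 3)
  expect_equal(dice(zeros, zeros), 1.0)               # both-empty convention
  expect_error(dice(a, matrix(0, 3, 3)), "grid")
})

test_that("dice is symmetric and invariant under joint pixel permutation", {
  set.seed(31)
  for (i in 1:20) {
    a <- matrix(runif(36) > 0.6, 6, 6)
    b <- matrix(runif(36) > 0.4, 6, 6)
    expect_identical(dice(a, b), dice(b, a))
    perm <- sample(36)
    expect_identical(dice(a, b),
                     dice(matrix(a[perm], 6, 6), matrix(b[perm], 6, 6)))
  }
})

test_that("structure masks follow the epicardium-union convention", {
  lm <- tiny_label_map(16)
  expect_identical(structure_mask(lm, "lv_epi"),
                   unclass(lm) == 1L | unclass(lm) == 2L)
  expect_error(structure_mask(lm, "aorta"), "unknown structure")
})

test_that("a one-pair overfit run reaches near-perfect training Dice", {
  ds <- make_phantom_dataset(1, image_size = 16, profile = flat_profile(),
                             seed = 3)
  pair <- ds$samples[1]
  cfg <- seg_config(n_layers = 2, input_size = 16, channels = c(8, 16),
                    epochs = 250, batch_size = 1, seed = 2)
  fit <- train_segmenter(pair, pair, cfg, seed = 4)
  rep <- evaluate_segmenter(fit, pair)
  expect_gt(min(rep$rows$dice), 0.99)
})

test_that("degenerate training requests are rejected", {
  ds <- make_phantom_dataset(1, image_size = 16, seed = 5)
  cfg0 <- seg_config(n_layers = 2, input_size = 16, channels = c(4, 8),
                     epochs = 0)
  expect_error(train_segmenter(ds$samples, ds$samples, cfg0), "epochs")
  expect_error(train_segmenter(list(), ds$samples,
                               seg_config(n_layers = 2, input_size = 16,
                                          channels = c(4, 8))), "empty")
  bad_cfg <- seg_config(n_layers = 2, input_size = 16, channels = c(4, 8),
                        n_classes = 3)
  expect_error(train_segmenter(ds$samples, ds$samples, bad_cfg), "classes")
  expect_error(seg_config(n_layers = 1), "n_layers")
  expect_error(seg_config(n_layers = 4, input_size = 36), "divisible")
})

test_that("evaluation reports exact scores for oracle and degenerate segmenters", {
  ds <- make_phantom_dataset(2, image_size = 16, seed = 6)
  test <- ds$samples
  oracle <- local({
    i <- 0
    function(image) { i <<- i + 1; test[[i]]$label_map }
  })
  rep <- evaluate_segmenter(oracle, test)
  expect_true(all(rep$rows$dice == 1))
  expect_true(all(rep$summary$sd_dice == 0))
  allbg <- function(image) as_label_map(matrix(0L, 16, 16))
  rep0 <- evaluate_segmenter(allbg, test)
  expect_true(all(rep0$rows$dice == 0))
  expect_false(any(rep0$rows$flagged_empty))
})

test_that("summaries are recomputable from the rows to 1e-12", {
  ds <- make_phantom_dataset(2, image_size = 16, seed = 8)
  jitter_seg <- function(image) {
    lm <- unclass(ds$samples[[1]]$label_map)
    as_label_map(lm)
  }
  rep <- evaluate_segmenter(jitter_seg, ds$samples)
  for (nm in unique(rep$rows$label_name)) {
    sub <- rep$rows$dice[rep$rows$label_name == nm]
    expect_equal(rep$summary$mean_dice[rep$summary$label_name == nm],
                 mean(sub), tolerance = 1e-12)
    expect_equal(rep$summary$sd_dice[rep$summary$label_name == nm],
                 stats::sd(sub), tolerance = 1e-12)
  }
  for (cid in unique(rep$rows$case_id)) {
    expect_equal(rep$per_case$case_mean[rep$per_case$case_id == cid],
                 mean(rep$rows$dice[rep$rows$case_id == cid]),
                 tolerance = 1e-12)
  }
})

test_that("evaluation refuses overlapping train/test manifests", {
  ds <- make_phantom_dataset(1, image_size = 16, seed = 9)
  seg <- function(image) ds$samples[[1]]$label_map
  tm <- tibble::tibble(case_id = c(1, 2, 3))
  te <- tibble::tibble(case_id = c(3, 4))
  expect_error(evaluate_segmenter(seg, ds$samples, train_manifest = tm,
                                  test_manifest = te), "overlap")
  expect_silent(evaluate_segmenter(seg, ds$samples,
                                   train_manifest = tibble::tibble(case_id = 1:2),
                                   test_manifest = tibble::tibble(case_id = 3:4)))
})

test_that("fitted segmenters carry the training-manifest hash into reports", {
  ds <- make_phantom_dataset(1, image_size = 16, profile = flat_profile(),
                             seed = 10)
  cfg <- seg_config(n_layers = 2, input_size = 16, channels = c(4, 8),
                    epochs = 2, batch_size = 2, seed = 1)
  fit <- train_segmenter(ds$samples, ds$samples, cfg, seed = 2,
                         train_manifest = ds$manifest)
  expect_match(fit$train_manifest_hash, "^[0-9a-f]{32}$")
  rep <- evaluate_segmenter(fit, ds$samples)
  expect_identical(rep$train_manifest_hash, fit$train_manifest_hash)
  # checkpoint round-trip preserves predictions and provenance
  p <- withr::local_tempfile(fileext = ".rds")
  save_seg_checkpoint(fit, p)
  re <- load_seg_checkpoint(p)
  expect_identical(re$train_manifest_hash, fit$train_manifest_hash)
  expect_identical(seg_predict(re$model, ds$samples[[1]]$image),
                   seg_predict(fit$model, ds$samples[[1]]$image))
})
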