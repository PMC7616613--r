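test_that("identity-range parameters reproduce the input bit-exactly", {
  lm <- make_label_map(phantom_geometry(64))
  for (d in 1:3) {
    out <- random_affine_elastic(lm, identity_augmentation(seed = d), d)
    expect_identical(unclass(out), unclass(lm))
  }
})

test_that("nearest-neighbour resampling never introduces new classes", {
  lm <- make_label_map(phantom_geometry(48))
  ap <- augmentation_params(seed = 3)
  classes_in <- unique(as.vector(lm))
  for (d in 1:50) {
    out <- random_affine_elastic(lm, ap, d)
    expect_true(all(unique(as.vector(out)) %in% classes_in))
  }
})

test_that("draws are reproducible from (seed, source, draw) and independent across keys", {
  lm <- make_label_map(phantom_geometry(32))
  ap <- augmentation_params(seed = 5)
  a <- random_affine_elastic(lm, ap, draw_index = 2, source_key = 9)
  b <- random_affine_elastic(lm, ap, draw_index = 2, source_key = 9)
  expect_identical(a, b)
  c_ <- random_affine_elastic(lm, ap, draw_index = 3, source_key = 9)
  d_ <- random_affine_elastic(lm, ap, draw_index = 2, source_key = 10)
  expect_false(identical(a, c_))
  expect_false(identical(a, d_))
})

test_that("class areas stay within scale-range bounds plus elastic slack", {
  lm <- make_label_map(phantom_geometry(64))
  ap <- augmentation_params(seed = 8)
  # output->source mapping scales areas by 1/s^2 for s in (0.8, 1.05)
  lo <- (1 / 1.05^2) * 0.75
  hi <- (1 / 0.8^2) * 1.25
  counts_in <- table(factor(as.vector(lm), levels = 0:4))
  for (d in 1:60) {
    out <- random_affine_elastic(lm, ap, d)
    counts_out <- table(factor(as.vector(out), levels = 0:4))
    for (k in c("1", "2", "3")) {   # anatomy classes, away from borders
      ratio <- counts_out[[k]] / counts_in[[k]]
      expect_gt(ratio, lo); expect_lt(ratio, hi)
    }
  }
})

test_that("the sector label fills thresholded non-anatomy pixels only", {
  lm <- make_label_map(phantom_geometry(48))
  anatomy <- as_label_map(matrix(ifelse(unclass(lm) %in% 1:3, unclass(lm), 0L),
                                 48, 48))
  img <- render_pseudo_ultrasound(lm, echogenicity_profile(), rng_seed = 2)
  # all-zero image: nothing exceeds the threshold
  zero <- structure(matrix(0, 48, 48), class = c("echo_image", "matrix", "array"))
  expect_identical(unclass(add_sector_label(zero, anatomy, 0.5)),
                   unclass(anatomy))
  # uniform image of 1, empty map: everything becomes sector
  ones <- structure(matrix(1, 48, 48), class = c("echo_image", "matrix", "array"))
  empty <- as_label_map(matrix(0L, 48, 48))
  expect_true(all(add_sector_label(ones, empty, 0.5) == echo_classes()[["sector"]]))
  # brute-force pixel scan on a phantom
  out <- add_sector_label(img, anatomy, 0.05)
  expect_identical(sum(out == 4L), sum(img > 0.05 & unclass(anatomy) == 0L))
  expect_identical(out[unclass(anatomy) != 0L], anatomy[unclass(anatomy) != 0L])
  expect_error(add_sector_label(ones, as_label_map(matrix(0L, 4, 4)), 0.5),
               "grid")
})

test_that("dataset construction multiplies counts and aggregates without loss", {
  sched <- cosine_schedule(2)
  lm16 <- tiny_label_map(16)
  maps <- function(n) replicate(n, lm16, simplify = FALSE)
  sources <- list("2C/ED" = list(train = maps(2), val = maps(1)),
                  "4C/ED" = list(train = maps(3), val = maps(1)))
  specs <- list(dataset_spec("2C", "ED", 2, 1, 3), dataset_spec("4C", "ED", 3, 1, 3))
  preds <- list("2C" = stub_predictor(), "4C" = stub_predictor())
  built <- build_synthetic_datasets(sources, specs, preds, sched,
                                    augmentation_params(seed = 2))
  expect_length(built$datasets[["2C/ED"]]$train, 6L)   # 2 maps x 3 transforms
  expect_length(built$datasets[["4C/ED"]]$train, 9L)
  expect_length(built$datasets$aggregate$train, 15L)   # concatenation, no dedup
  expect_length(built$datasets$aggregate$val, 6L)
  m <- built$manifest
  expect_identical(nrow(m[m$dataset == "2C/ED" & m$split == "train", ]), 6L)
  # images are paired and share the label grid
  e <- built$datasets[["2C/ED"]]$train[[1]]
  expect_identical(dim(e$image), dim(e$label_map))
  expect_error(
    build_synthetic_datasets(sources, specs, list("2C" = stub_predictor()),
                             sched, augmentation_params()),
    "predictor for view 4C")
})

test_that("dataset construction is deterministic given seeds and sources", {
  sched <- cosine_schedule(2)
  lm <- tiny_label_map(16)
  sources <- list("2C/ED" = list(train = list(lm, lm), val = list(lm)))
  specs <- list(dataset_spec("2C", "ED", 2, 1, 2))
  preds <- list("2C" = stub_predictor())
  b1 <- build_synthetic_datasets(sources, specs, preds, sched,
                                 augmentation_params(seed = 4))
  b2 <- build_synthetic_datasets(sources, specs, preds, sched,
                                 augmentation_params(seed = 4))
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(b1$datasets, b2$datasets)
})
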