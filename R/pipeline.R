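#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters behind one object with a resolved seed
#' per stochastic stage. Two resolution profiles are provided: `"toy"` — a
#' minutes-scale configuration exercising every stage on small phantoms —
#' and `"paper"` — the full-scale recipe (1000-step schedule, KL weight
#' 0.001, the printed augmentation ranges, depth-8 U-Net at 256 px, Adam
#' 1e-3/0.9/0.999, 300 epochs), which is expressible and exportable but far
#' beyond desk-scale runtime.
#'
#' @param profile `"toy"` or `"paper"`.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param out_root Artifact directory.
#' @param overrides Named list overriding any config block field, e.g.
#'   `list(sdm = list(steps = 100))`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(profile = c("toy", "paper"), seed = 1,
                            out_root = tempfile("echosynth_run_"),
                            overrides = list()) {
  profile <- match.arg(profile)
  cfg <- if (profile == "toy") {
    list(
      phantom = list(n_cases = 8, image_size = 24,
                     n_train = 5, n_val = 1, n_test = 2,
                     speckle_scale = 0.15, blur_radius = 0),
      schedule = list(T_steps = 12, offset = 0.008),
      denoiser = list(base_channels = 8, channel_multipliers = c(1, 2),
                      timestep_embedding_dim = 16),
      sdm = list(steps = 300, batch_size = 4, lr = 2e-3, kl_weight = 0.001),
      augment = list(transforms_per_map = 2,
                     rotation_range = c(-5, 5), translate_range = c(0, 0.05),
                     scale_range = c(0.8, 1.05), shear_max = 5,
                     elastic_control_points = c(10, 10, 4),
                     elastic_max_displacement = c(0, 30, 30)),
      seg = list(n_layers = 3, channels = c(16, 32, 64), epochs = 16,
                 batch_size = 4, learning_rate = 1e-3,
                 adam_beta1 = 0.9, adam_beta2 = 0.999, loss = "ce_dice"),
      seg_dataset = "aggregate"
    )
  } else {
    list(
      phantom = list(n_cases = 500, image_size = 256,
                     n_train = 400, n_val = 50, n_test = 50,
                     speckle_scale = 0.25, blur_radius = 1),
      schedule = list(T_steps = 1000, offset = 0.008),
      denoiser = list(base_channels = 64, channel_multipliers = c(1, 2, 4, 8),
                      timestep_embedding_dim = 128),
      sdm = list(steps = 50000, batch_size = 12, lr = 1e-4, kl_weight = 0.001),
      augment = list(transforms_per_map = 5,
                     rotation_range = c(-5, 5), translate_range = c(0, 0.05),
                     scale_range = c(0.8, 1.05), shear_max = 5,
                     elastic_control_points = c(10, 10, 4),
                     elastic_max_displacement = c(0, 30, 30)),
      seg = list(n_layers = 8, channels = NULL, epochs = 300,
                 batch_size = 12, learning_rate = 1e-3,
                 adam_beta1 = 0.9, adam_beta2 = 0.999, loss = "ce_dice"),
      seg_dataset = "aggregate"
    )
  }
  for (blk in names(overrides)) {
    if (is.list(overrides[[blk]])) {
      for (k in names(overrides[[blk]])) cfg[[blk]][[k]] <- overrides[[blk]][[k]]
    } else {
      cfg[[blk]] <- overrides[[blk]]
    }
  }
  cfg$profile <- profile
  cfg$seed <- seed
  cfg$stage_seeds <- list(phantom = derive_seed(seed, 1),
                          sdm = derive_seed(seed, 2),
                          augment = derive_seed(seed, 3),
                          seg = derive_seed(seed, 4))
  cfg$out_root <- out_root
  structure(cfg, class = "pipeline_config")
}

#' Pipeline stage names, in execution order
#' @return Character vector of stage identifiers.
#' @export
pipeline_stages <- function() {
  c("phantom-gen", "sdm-train", "augment-build", "seg-train", "seg-eval")
}

config_hash <- function(config) {
  content_hash(unclass(config)[setdiff(names(config), "out_root")])
}

stage_done <- function(dir, hash) {
  f <- file.path(dir, "DONE")
  file.exists(f) && identical(readLines(f, n = 1), hash)
}

mark_done <- function(dir, hash) writeLines(hash, file.path(dir, "DONE"))

#' Run the synthesis-and-segmentation pipeline
#'
#' Executes the enabled stages in order: phantom generation, per-view
#' diffusion training, augmented dataset construction with diffusion-sampled
#' images, segmentation training on the synthetic dataset, and evaluation on
#' held-out phantom cases (standing in for the real test data; a user with
#' CAMUS-format data can mount it through the MetaImage adapter and the
#' `test_samples` override). Every stage directory carries the config hash;
#' re-running with an identical config skips completed stages.
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to run (subset of `pipeline_stages()`).
#' @param force Recompute even if a stage is already done.
#' @return Invisible list of stage artifacts (paths and key objects).
#' @export
run_pipeline <- function(config, stages = pipeline_stages(), force = FALSE) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  root <- config$out_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log <- function(...) message(sprintf("[echosynth %s] %s",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)))
  paths <- list(
    phantom = file.path(root, "phantom"),
    sdm = file.path(root, "sdm"),
    augment = file.path(root, "augment"),
    seg = file.path(root, "seg"),
    evald = file.path(root, "eval")
  )
  need <- function(path, stage_hint) {
    if (!file.exists(path)) {
      abort(sprintf("missing upstream artifact %s: run %s first.", path, stage_hint))
    }
    readRDS(path)
  }
  out <- list(root = root, hash = hash)

  if ("phantom-gen" %in% stages) {
    d <- paths$phantom
    dir.create(d, showWarnings = FALSE)
    if (force || !stage_done(d, hash)) {
      t0 <- Sys.time()
      pc <- config$phantom
      prof <- echogenicity_profile(speckle_scale = pc$speckle_scale,
                                   blur_radius = pc$blur_radius)
      ph <- make_phantom_dataset(pc$n_cases, image_size = pc$image_size,
                                 profile = prof, seed = config$stage_seeds$phantom)
      saveRDS(ph, file.path(d, "dataset.rds"))
      write_manifest(ph$manifest, file.path(d, "manifest.csv"))
      mark_done(d, hash)
      log("phantom-gen: %d samples in %.1fs", length(ph$samples),
          as.numeric(Sys.time() - t0, units = "secs"))
    } else log("phantom-gen: up to date, skipping")
  }

  if ("sdm-train" %in% stages) {
    d <- paths$sdm
    dir.create(d, showWarnings = FALSE)
    if (force || !stage_done(d, hash)) {
      t0 <- Sys.time()
      ph <- need(file.path(paths$phantom, "dataset.rds"), "phantom-gen")
      sched <- cosine_schedule(config$schedule$T_steps, config$schedule$offset)
      write_schedule_csv(sched, file.path(d, "schedule.csv"))
      pc <- config$phantom
      train_cases <- seq_len(pc$n_train)
      for (view in c("2C", "4C")) {
        # one model per view, trained on the ED frames of the training cases
        sub <- filter_samples(ph, view = view, phase = "ED", cases = train_cases)
        dcfg <- denoiser_config(
          image_size = pc$image_size,
          base_channels = config$denoiser$base_channels,
          channel_multipliers = config$denoiser$channel_multipliers,
          timestep_embedding_dim = config$denoiser$timestep_embedding_dim,
          seed = derive_seed(config$stage_seeds$sdm, match(view, c("2C", "4C"))))
        fit <- train_sdm(sub, sched,
                         loss_config = hybrid_loss_config(config$sdm$kl_weight),
                         steps = config$sdm$steps,
                         batch_size = config$sdm$batch_size,
                         lr = config$sdm$lr, config = dcfg,
                         seed = derive_seed(config$stage_seeds$sdm, 10,
                                            match(view, c("2C", "4C"))))
        save_checkpoint(fit$model, file.path(d, paste0("ckpt_", view, ".rds")))
        write_training_log(fit, file.path(d, paste0("log_", view, ".csv")))
      }
      mark_done(d, hash)
      log("sdm-train: 2 view models, %d steps each in %.1fs", config$sdm$steps,
          as.numeric(Sys.time() - t0, units = "secs"))
    } else log("sdm-train: up to date, skipping")
  }

  if ("augment-build" %in% stages) {
    d <- paths$augment
    dir.create(d, showWarnings = FALSE)
    if (force || !stage_done(d, hash)) {
      t0 <- Sys.time()
      ph <- need(file.path(paths$phantom, "dataset.rds"), "phantom-gen")
      sched <- cosine_schedule(config$schedule$T_steps, config$schedule$offset)
      pc <- config$phantom
      predictors <- list(
        "2C" = load_checkpoint(need_path(paths$sdm, "ckpt_2C.rds", "sdm-train")),
        "4C" = load_checkpoint(need_path(paths$sdm, "ckpt_4C.rds", "sdm-train")))
      train_cases <- seq_len(pc$n_train)
      val_cases <- pc$n_train + seq_len(pc$n_val)
      sources <- list(); specs <- list()
      for (view in c("2C", "4C")) for (phase in c("ED", "ES")) {
        key <- paste(view, phase, sep = "/")
        get_maps <- function(cases) {
          lapply(filter_samples(ph, view, phase, cases)$samples, `[[`, "label_map")
        }
        sources[[key]] <- list(train = get_maps(train_cases),
                               val = get_maps(val_cases))
        specs[[key]] <- dataset_spec(view, phase,
                                     n_source_train = pc$n_train,
                                     n_source_val = pc$n_val,
                                     transforms_per_map = config$augment$transforms_per_map)
      }
      ap <- augmentation_params(
        rotation_range = config$augment$rotation_range,
        translate_range = config$augment$translate_range,
        scale_range = config$augment$scale_range,
        shear_max = config$augment$shear_max,
        elastic_control_points = config$augment$elastic_control_points,
        elastic_max_displacement = config$augment$elastic_max_displacement,
        seed = config$stage_seeds$augment)
      built <- build_synthetic_datasets(sources, specs, predictors, sched, ap)
      saveRDS(built, file.path(d, "datasets.rds"))
      write_manifest(built$manifest, file.path(d, "manifest.csv"))
      mark_done(d, hash)
      log("augment-build: %d manifest rows in %.1fs", nrow(built$manifest),
          as.numeric(Sys.time() - t0, units = "secs"))
    } else log("augment-build: up to date, skipping")
  }

  if ("seg-train" %in% stages) {
    d <- paths$seg
    dir.create(d, showWarnings = FALSE)
    if (force || !stage_done(d, hash)) {
      t0 <- Sys.time()
      built <- need(file.path(paths$augment, "datasets.rds"), "augment-build")
      ds <- built$datasets[[config$seg_dataset]]
      sc <- config$seg
      scfg <- seg_config(n_layers = sc$n_layers,
                         input_size = config$phantom$image_size,
                         n_classes = length(echo_classes()),
                         channels = sc$channels, epochs = sc$epochs,
                         batch_size = sc$batch_size,
                         learning_rate = sc$learning_rate,
                         adam_beta1 = sc$adam_beta1, adam_beta2 = sc$adam_beta2,
                         loss = sc$loss,
                         seed = derive_seed(config$stage_seeds$seg, 1))
      tm <- dplyr::filter(built$manifest,
                          .data$dataset == config$seg_dataset,
                          .data$split == "train")
      fit <- train_segmenter(ds$train, ds$val, scfg,
                             seed = derive_seed(config$stage_seeds$seg, 2),
                             train_manifest = tm)
      save_seg_checkpoint(fit, file.path(d, "ckpt.rds"))
      readr::write_csv(fit$history, file.path(d, "log.csv"))
      mark_done(d, hash)
      log("seg-train: %d epochs on %d pairs in %.1fs", scfg$epochs,
          length(ds$train), as.numeric(Sys.time() - t0, units = "secs"))
    } else log("seg-train: up to date, skipping")
  }

  if ("seg-eval" %in% stages) {
    d <- paths$evald
    dir.create(d, showWarnings = FALSE)
    if (force || !stage_done(d, hash)) {
      t0 <- Sys.time()
      ph <- need(file.path(paths$phantom, "dataset.rds"), "phantom-gen")
      fit <- load_seg_checkpoint(need_path(paths$seg, "ckpt.rds", "seg-train"))
      pc <- config$phantom
      test_cases <- pc$n_train + pc$n_val + seq_len(pc$n_test)
      test <- filter_samples(ph, cases = test_cases)$samples
      train_ids <- tibble::tibble(case_id = seq_len(pc$n_train + pc$n_val))
      test_ids <- tibble::tibble(case_id = test_cases)
      report <- evaluate_segmenter(fit, test,
                                   train_manifest = train_ids,
                                   test_manifest = test_ids)
      write_dice_report(report, file.path(d, "dice.csv"))
      saveRDS(report, file.path(d, "report.rds"))
      mark_done(d, hash)
      log("seg-eval: %d cases, mean Dice %.3f in %.1fs", length(test),
          mean(report$summary$mean_dice),
          as.numeric(Sys.time() - t0, units = "secs"))
    } else log("seg-eval: up to date, skipping")
  }
  invisible(out)
}

need_path <- function(dir, file, stage_hint) {
  p <- file.path(dir, file)
  if (!file.exists(p)) {
    abort(sprintf("missing upstream artifact %s: run %s first.", p, stage_hint))
  }
  p
}
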