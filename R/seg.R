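#' U-Net segmenter configuration
#'
#' Encoder depth `n_layers` with `2^L` channels at layer `L` (capped at
#' `max_channels` so desk-scale runs stay tractable), mirrored decoder with
#' skip connections, trained with Adam. The defaults describe the full-scale
#' recipe (depth 8, 256-px input, 300 epochs, lr 1e-3, betas 0.9/0.999);
#' tests and the toy profile pass smaller values.
#'
#' @param n_layers Encoder depth (>= 2).
#' @param input_size Input side in pixels; must be divisible by
#'   `2^(n_layers - 1)`.
#' @param n_classes Number of semantic classes.
#' @param channels Optional explicit per-layer channel widths (overrides the
#'   `2^L` rule).
#' @param max_channels Cap applied to the `2^L` rule.
#' @param learning_rate,adam_beta1,adam_beta2 Adam hyperparameters
#'   (defaults 1e-3, 0.9, 0.999).
#' @param epochs Training epochs (default 300).
#' @param batch_size Minibatch size.
#' @param loss `"ce_dice"` (cross-entropy + soft Dice, default) or `"ce"`.
#' @param seed Weight-initialisation seed.
#' @return A `seg_config` object.
#' @export
seg_config <- function(n_layers = 8, input_size = 256, n_classes = 5,
                       channels = NULL, max_channels = 256,
                       learning_rate = 1e-3, adam_beta1 = 0.9,
                       adam_beta2 = 0.999, epochs = 300, batch_size = 8,
                       loss = c("ce_dice", "ce"), seed = 0) {
  loss <- match.arg(loss)
  if (n_layers < 2) abort("seg_config: n_layers must be >= 2.")
  if (input_size %% (2^(n_layers - 1)) != 0) {
    abort(sprintf("seg_config: input_size %d not divisible by 2^%d.",
                  input_size, n_layers - 1))
  }
  channels <- channels %||% pmin(2^seq_len(n_layers), max_channels)
  if (length(channels) != n_layers) {
    abort("seg_config: channels must have one width per layer.")
  }
  structure(list(n_layers = as.integer(n_layers),
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 channels = as.integer(channels),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss, seed = seed),
            class = "seg_config")
}

unet_param_template <- function(cfg) {
  ch <- cfg$channels
  L <- cfg$n_layers
  p <- list()
  sc <- 0L
  s <- function() { sc <<- sc + 1L; derive_seed(cfg$seed, 1000 + sc) }
  put <- function(prefix, cin, cout) {
    p[[paste0(prefix, "_w")]] <<- init_conv(3, cin, cout, s())
    p[[paste0(prefix, "_b")]] <<- rep(0, cout)
  }
  cin <- 1L
  for (l in seq_len(L)) {
    put(paste0("enc", l, "_c1"), cin, ch[l])
    put(paste0("enc", l, "_c2"), ch[l], ch[l])
    cin <- ch[l]
  }
  for (l in rev(seq_len(L - 1))) {
    put(paste0("dec", l, "_c1"), ch[l + 1] + ch[l], ch[l])
    put(paste0("dec", l, "_c2"), ch[l], ch[l])
  }
  put("head", ch[1], cfg$n_classes)
  p
}

unet_forward <- function(tape, store, cfg, x) {
  L <- cfg$n_layers
  P <- function(name) ag_param(tape, store, name)
  cv <- function(h, prefix) ag_conv2d(tape, h, P(paste0(prefix, "_w")), P(paste0(prefix, "_b")))
  h <- ag_input(tape, x)
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    if (l > 1) h <- ag_pool2(tape, h)
    h <- ag_relu(tape, cv(h, paste0("enc", l, "_c1")))
    h <- ag_relu(tape, cv(h, paste0("enc", l, "_c2")))
    skips[[l]] <- h
  }
  for (l in rev(seq_len(L - 1))) {
    h <- ag_up2(tape, h)
    h <- ag_concat_c(tape, h, skips[[l]])
    h <- ag_relu(tape, cv(h, paste0("dec", l, "_c1")))
    h <- ag_relu(tape, cv(h, paste0("dec", l, "_c2")))
  }
  cv(h, "head")
}

# numerically stable softmax over the channel dim of (H, W, C, N)
softmax4 <- function(z) {
  d <- dim(z)
  zp <- aperm(z, c(3, 1, 2, 4))                 # C first
  zm <- matrix(zp, d[3])
  zm <- sweep(zm, 2, apply(zm, 2, max))
  e <- exp(zm)
  p <- sweep(e, 2, colSums(e), `/`)
  aperm(array(p, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

#' Train a U-Net segmenter
#'
#' Minimises cross-entropy (optionally plus soft Dice) over the training
#' pairs with Adam at the configured hyperparameters, evaluates the
#' validation split each epoch, and retains the best-validation weights.
#'
#' @param train,val Lists of entries with `image` (unit-scale `echo_image`)
#'   and `label_map`, e.g. one split of [build_synthetic_datasets()] output
#'   or `phantom_dataset$samples`.
#' @param config A [seg_config()].
#' @param seed Seed for batch shuffling.
#' @param train_manifest Optional manifest tibble; its content hash is
#'   embedded in the fitted object so evaluation can verify provenance.
#' @return A `seg_fit` with `model`, `history` (per-epoch losses),
#'   `best_epoch` and `train_manifest_hash`.
#' @export
train_segmenter <- function(train, val, config, seed = 1,
                            train_manifest = NULL) {
  if (!length(train) || !length(val)) abort("train_segmenter: empty dataset.")
  if (config$epochs < 1) abort("train_segmenter: epochs must be >= 1 (degenerate request).")
  S <- config$input_size
  n_cls <- config$n_classes
  check_entry <- function(e) {
    if (nrow(e$label_map) != S) abort("train_segmenter: data grid != config input_size.")
    if (max(e$label_map) >= n_cls) {
      abort("train_segmenter: label map contains classes beyond config n_classes.")
    }
  }
  check_entry(train[[1]]); check_entry(val[[1]])

  store <- param_store(unet_param_template(config))
  st <- adam_state(store$values)
  x_all <- lapply(train, function(e) to_diffusion_scale(e$image))
  y_all <- lapply(train, function(e) label_onehot(e$label_map, n_cls))
  n_tr <- length(train)
  bs <- min(config$batch_size, n_tr)
  eps_s <- 1e-6

  model <- structure(list(config = config, store = store), class = "seg_net")
  best <- list(loss = Inf, params = NULL, epoch = 0L)
  hist <- vector("list", config$epochs)

  with_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      tr_losses <- c()
      for (start in seq(1, n_tr, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n_tr)]
        nb <- length(idx)
        x <- array(unlist(x_all[idx]), c(S, S, 1L, nb))
        oh <- array(unlist(y_all[idx]), c(S, S, n_cls, nb))
        tape <- tape_new()
        logits <- unet_forward(tape, store, config, x)
        p <- softmax4(logits$value)
        npix <- S * S * nb
        ce <- -sum(oh * log(pmax(p, 1e-12))) / npix
        g <- (p - oh) / npix
        loss <- ce
        if (config$loss == "ce_dice") {
          pm <- matrix(aperm(p, c(1, 2, 4, 3)), ncol = n_cls)
          ym <- matrix(aperm(oh, c(1, 2, 4, 3)), ncol = n_cls)
          num <- 2 * colSums(pm * ym) + eps_s
          den <- colSums(pm) + colSums(ym) + eps_s
          dice_loss <- 1 - mean(num / den)
          loss <- loss + dice_loss
          dLdp <- -t((2 * t(ym) * den - num) / den^2) / n_cls
          # chain through softmax: dz = p * (dLdp - sum_c p_c dLdp_c)
          inner <- rowSums(pm * dLdp)
          dz <- pm * (dLdp - inner)
          g <- g + aperm(array(dz, c(S, S, nb, n_cls)), c(1, 2, 4, 3))
        }
        if (!is.finite(loss)) abort(sprintf("train_segmenter: non-finite loss (epoch %d).", epoch))
        grads <- backward(tape, list(list(node = logits, grad = g)))
        st <- adam_update(store, grads, st, config$learning_rate,
                          config$adam_beta1, config$adam_beta2)
        tr_losses <- c(tr_losses, loss)
      }
      val_loss <- mean(vapply(val, function(e) {
        lg <- seg_logits(model, e$image)
        p <- softmax4(array(lg, c(S, S, n_cls, 1)))
        oh <- array(label_onehot(e$label_map, n_cls), c(S, S, n_cls, 1))
        -sum(oh * log(pmax(p, 1e-12))) / (S * S)
      }, numeric(1)))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = store$values, epoch = epoch)
      }
      hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                      train_loss = mean(tr_losses),
                                      val_loss = val_loss)
    }
  })
  store$values <- best$params
  structure(list(model = model,
                 history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch,
                 train_manifest_hash = if (!is.null(train_manifest)) {
                   content_hash(train_manifest)
                 } else NA_character_,
                 seed = seed),
            class = "seg_fit")
}

seg_logits <- function(model, image) {
  S <- model$config$input_size
  x <- array(to_diffusion_scale(image), c(S, S, 1L, 1L))
  tape <- tape_new()
  unet_forward(tape, model$store, model$config, x)$value[, , , 1]
}

#' Predict a label map with a trained segmenter
#' @param model A `seg_net` (from `seg_fit$model`).
#' @param image Unit-scale `echo_image`.
#' @return Predicted `label_map` (per-pixel argmax).
#' @export
seg_predict <- function(model, image) {
  lg <- seg_logits(model, image)
  as_label_map(apply(lg, c(1, 2), which.max) - 1L)
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf("<seg_fit> %d epochs, best val loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' Save / load a segmenter checkpoint
#' @param fit A `seg_fit`.
#' @param path File path (`.rds`).
#' @export
save_seg_checkpoint <- function(fit, path) {
  saveRDS(list(kind = "seg_net", config = fit$model$config,
               params = fit$model$store$values,
               best_epoch = fit$best_epoch,
               train_manifest_hash = fit$train_manifest_hash), path)
  invisible(path)
}

#' @rdname save_seg_checkpoint
#' @export
load_seg_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$kind, "seg_net")) abort("not a seg_net checkpoint.")
  model <- structure(list(config = ck$config, store = param_store(ck$params)),
                     class = "seg_net")
  structure(list(model = model, history = NULL, best_epoch = ck$best_epoch,
                 train_manifest_hash = ck$train_manifest_hash),
            class = "seg_fit")
}
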