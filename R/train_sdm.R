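as_sample_list <- function(pairs) {
  if (inherits(pairs, "phantom_dataset")) pairs$samples else pairs
}

#' Train the label-conditioned denoiser with the hybrid objective
#'
#' Standard diffusion training: at each step a batch of (clean image, label
#' map) pairs is drawn, per-sample timesteps are sampled uniformly in `1..T`,
#' noise is added via the closed-form forward process, and the network
#' minimises the noise-prediction mean squared error plus `kl_weight` times
#' the KL divergence between the estimated reverse-step Gaussian and the
#' diffusion posterior. The KL term receives gradient only through the
#' variance head (the mean path is detached), so it trains the learned-range
#' variances without destabilising noise prediction. The learning rate
#' anneals linearly from `lr` to 0 over `steps`.
#'
#' @param pairs A `phantom_dataset` or list of paired samples
#'   (`label_map`, `image`, `meta`); images on the unit scale.
#' @param schedule A [cosine_schedule()].
#' @param loss_config A [hybrid_loss_config()] (KL weight default 0.001).
#' @param steps Optimisation steps (>= 1).
#' @param batch_size Batch size.
#' @param lr Initial Adam learning rate.
#' @param config A [denoiser_config()]; its `image_size`/`n_label_classes`
#'   must match the data. Ignored when `model` is supplied.
#' @param model Optional existing `sdm_denoiser` to continue training.
#' @param view Optional view filter (`"2C"` or `"4C"`): one model per view.
#' @param cfg_dropout Probability of replacing a batch's condition with the
#'   null condition (classifier-free-guidance training; default 0, matching
#'   guidance-free inference).
#' @param seed Seed controlling batching and noise draws.
#' @return An `sdm_fit`: list with `model` (trained `sdm_denoiser`) and
#'   `history` tibble `(step, lr, simple_term, kl_term)`.
#' @export
train_sdm <- function(pairs, schedule, loss_config = hybrid_loss_config(),
                      steps = 1000, batch_size = 8, lr = 2e-3,
                      config = NULL, model = NULL, view = NULL,
                      cfg_dropout = 0, seed = 1) {
  samples <- as_sample_list(pairs)
  if (!is.null(view)) {
    samples <- Filter(function(s) s$meta$view %in% view, samples)
  }
  if (!length(samples)) abort("train_sdm: empty training set.")
  if (steps < 1) abort("train_sdm: steps must be >= 1.")
  S <- nrow(samples[[1]]$label_map)
  if (is.null(model)) {
    config <- config %||% denoiser_config(image_size = S)
    model <- build_denoiser(config)
  }
  cfg <- model$config
  if (cfg$image_size != S) abort("train_sdm: data grid does not match model config.")
  T_steps <- schedule_T(schedule)
  pvc <- clipped_posterior_variance(schedule)
  lambda <- loss_config$kl_weight

  x0_all <- lapply(samples, function(s) to_diffusion_scale(s$image))
  oh_all <- lapply(samples, function(s) label_onehot(s$label_map, cfg$n_label_classes))

  st <- adam_state(model$store$values)
  hist_step <- integer(steps); hist_lr <- hist_simple <- hist_kl <- numeric(steps)

  with_seed(seed, {
    for (step in seq_len(steps)) {
      idx <- sample.int(length(samples), batch_size, replace = TRUE)
      t_vec <- sample.int(T_steps, batch_size, replace = TRUE)
      x0 <- array(unlist(x0_all[idx]), c(S, S, 1L, batch_size))
      noise <- array(rnorm(S * S * batch_size), c(S, S, 1L, batch_size))
      ab <- schedule$alpha_bar[t_vec]
      scale_sig <- rep(sqrt(ab), each = S * S)
      scale_noi <- rep(sqrt(1 - ab), each = S * S)
      yt <- array(scale_sig * as.vector(x0) + scale_noi * as.vector(noise),
                  c(S, S, 1L, batch_size))
      use_null <- cfg_dropout > 0 && runif(1) < cfg_dropout
      onehot <- if (use_null) NULL else {
        array(unlist(oh_all[idx]), c(S, S, cfg$n_label_classes, batch_size))
      }

      tape <- tape_new()
      out <- sdm_forward(tape, model$store, cfg, yt, t_vec, onehot)
      eps_pred <- out$eps$value
      n_el <- length(eps_pred)
      simple <- mean((eps_pred - noise)^2)

      # learned-range variance KL (mean path detached)
      beta_t <- rep(schedule$beta[t_vec], each = S * S)
      pv_t <- rep(pvc[t_vec], each = S * S)
      vlogit <- out$vlogit$value
      v <- 1 / (1 + exp(-vlogit))
      log_var <- v * log(beta_t) + (1 - v) * log(pv_t)
      var_pred <- exp(log_var)
      # estimated mean from detached eps equals the posterior mean applied to
      # the implied x0; the mean difference term of the KL
      x0_hat <- (as.vector(yt) - sqrt(1 - rep(ab, each = S * S)) * as.vector(eps_pred)) /
        sqrt(rep(ab, each = S * S))
      ab_prev <- ifelse(t_vec == 1L, 1, schedule$alpha_bar[pmax(t_vec - 1L, 1L)])
      coef0 <- rep(sqrt(ab_prev) * schedule$beta[t_vec] / (1 - ab), each = S * S)
      coeft <- rep(sqrt(schedule$alpha[t_vec]) * (1 - ab_prev) / (1 - ab), each = S * S)
      mu_est <- coef0 * x0_hat + coeft * as.vector(yt)
      mu_post <- coef0 * as.vector(x0) + coeft * as.vector(yt)
      delta2 <- (mu_est - mu_post)^2
      kl <- mean(0.5 * (log(pv_t / var_pred) + (var_pred + delta2) / pv_t - 1))
      loss <- simple + lambda * kl
      if (!is.finite(loss)) {
        abort(sprintf("train_sdm: non-finite loss at step %d.", step))
      }

      g_eps <- 2 * (eps_pred - noise) / n_el
      dkl_dvar <- (-1 / (2 * var_pred) + 1 / (2 * pv_t)) / n_el
      g_vlogit <- lambda * dkl_dvar * var_pred * (log(beta_t) - log(pv_t)) *
        v * (1 - v)
      grads <- backward(tape, list(
        list(node = out$eps, grad = array(g_eps, dim(eps_pred))),
        list(node = out$vlogit, grad = array(g_vlogit, dim(vlogit)))
      ))
      lr_t <- lr * (1 - (step - 1) / steps)
      st <- adam_update(model$store, grads, st, lr_t)
      hist_step[step] <- step; hist_lr[step] <- lr_t
      hist_simple[step] <- simple; hist_kl[step] <- kl
    }
  })
  model$step <- as.integer(model$step + steps)
  structure(list(
    model = model,
    history = tibble::tibble(step = hist_step, lr = hist_lr,
                             simple_term = hist_simple, kl_term = hist_kl),
    loss_config = loss_config, seed = seed
  ), class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<sdm_fit> %d steps; simple loss %.4f -> %.4f (last-50 mean)\n",
              nrow(h), mean(head(h$simple_term, 50)),
              mean(tail(h$simple_term, 50))))
  invisible(x)
}

#' Save / load a denoiser checkpoint
#'
#' Checkpoints embed the full configuration and weights; a reloaded model
#' reproduces predictions bit-for-bit.
#'
#' @param model An `sdm_denoiser`.
#' @param path File path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(kind = "sdm_denoiser", config = model$config,
               params = model$store$values, step = model$step), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$kind, "sdm_denoiser")) abort("not an sdm_denoiser checkpoint.")
  structure(list(config = ck$config, store = param_store(ck$params),
                 step = ck$step), class = "sdm_denoiser")
}

#' Write a training log as CSV
#' @param fit An `sdm_fit` (or `seg_fit`).
#' @param path CSV path.
#' @export
write_training_log <- function(fit, path) {
  readr::write_csv(fit$history, path)
  invisible(path)
}
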