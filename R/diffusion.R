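#' Cosine noise schedule
#'
#' Builds the per-timestep schedule of a denoising diffusion process with the
#' squared-cosine cumulative signal profile: with
#' \eqn{f(t) = \cos^2\!\big(\tfrac{t/T + s}{1 + s}\cdot\tfrac{\pi}{2}\big)},
#' \eqn{\bar\alpha_t = f(t)/f(0)}, \eqn{\beta_t = 1 - \bar\alpha_t/\bar\alpha_{t-1}}
#' clipped at 0.999. Compared with a linear schedule this adds noise more
#' slowly early on, shifting more of the corruption to late timesteps.
#'
#' @param T_steps Number of diffusion steps (>= 1).
#' @param offset Small offset `s` in (0, 1) preventing a singular first step
#'   (default 0.008).
#' @return A tibble of class `noise_schedule` with columns `t`, `beta`,
#'   `alpha`, `alpha_bar`, `posterior_variance` and attribute `T_steps`.
#'   `posterior_variance[t]` is the variance of the diffusion posterior
#'   \eqn{q(y_{t-1} \mid y_t, y_0)}; it is 0 at `t = 1`
#'   (\eqn{\bar\alpha_0 = 1}).
#' @export
cosine_schedule <- function(T_steps = 1000, offset = 0.008) {
  if (!is.numeric(T_steps) || length(T_steps) != 1L || T_steps < 1) {
    abort("`T_steps` must be an integer >= 1.")
  }
  if (!is.numeric(offset) || offset <= 0 || offset >= 1) {
    abort("`offset` must lie strictly in (0, 1).")
  }
  T_steps <- as.integer(T_steps)
  f <- function(t) cos(((t / T_steps + offset) / (1 + offset)) * pi / 2)^2
  alpha_bar_full <- f(0:T_steps) / f(0)       # index 1 is t = 0 (== 1 exactly)
  beta <- 1 - alpha_bar_full[-1] / alpha_bar_full[-(T_steps + 1)]
  beta <- pmin(beta, 0.999)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)                 # recompute after clipping
  alpha_bar_prev <- c(1, alpha_bar[-T_steps])
  post_var <- beta * (1 - alpha_bar_prev) / (1 - alpha_bar)
  out <- tibble::tibble(t = seq_len(T_steps), beta = beta, alpha = alpha,
                        alpha_bar = alpha_bar, posterior_variance = post_var)
  structure(out, class = c("noise_schedule", class(out)),
            T_steps = T_steps, offset = offset)
}

#' Closed-form cumulative signal fraction of the cosine schedule
#'
#' \eqn{\bar\alpha_t = f(t)/f(0)} before any clipping of the per-step betas;
#' exposed for inspection and schedule regression tests. `t` may be a vector
#' and may include 0 (where the value is exactly 1) and `T` (exactly 0).
#'
#' @param t Timestep(s) in `0..T_steps`.
#' @param T_steps Total steps.
#' @param offset Cosine offset.
#' @return Numeric vector of \eqn{\bar\alpha_t}.
#' @export
cosine_alpha_bar <- function(t, T_steps, offset = 0.008) {
  f <- function(u) cos(((u / T_steps + offset) / (1 + offset)) * pi / 2)^2
  f(t) / f(0)
}

schedule_T <- function(schedule) attr(schedule, "T_steps")

check_t <- function(t, schedule) {
  T_steps <- schedule_T(schedule)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t > T_steps) {
    abort(sprintf("timestep t = %s out of range 1..%d.", format(t), T_steps))
  }
  as.integer(t)
}

#' Closed-form forward diffusion
#'
#' \eqn{y_t = \sqrt{\bar\alpha_t}\, y_0 + \sqrt{1-\bar\alpha_t}\,\epsilon},
#' elementwise on the image grid.
#'
#' @param x0 Clean image raster (matrix, diffusion scale `[-1, 1]`).
#' @param t Timestep in `1..T`.
#' @param noise Noise raster on the same grid.
#' @param schedule A [cosine_schedule()].
#' @return A `noisy_image` matrix carrying attribute `t`.
#' @export
forward_diffuse <- function(x0, t, noise, schedule) {
  t <- check_t(t, schedule)
  assert_same_grid(x0, noise, "x0 and noise")
  ab <- schedule$alpha_bar[t]
  y <- sqrt(ab) * unclass(x0) + sqrt(1 - ab) * noise
  structure(y, class = c("noisy_image", "matrix", "array"), t = t)
}

#' Diffusion posterior parameters
#'
#' Mean and variance of \eqn{q(y_{t-1} \mid y_t, y_0)}:
#' \deqn{\tilde\mu_t = \frac{\sqrt{\bar\alpha_{t-1}}\beta_t}{1-\bar\alpha_t} y_0
#'   + \frac{\sqrt{\alpha_t}(1-\bar\alpha_{t-1})}{1-\bar\alpha_t} y_t,\quad
#'   \tilde\beta_t = \beta_t\frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}.}
#' At `t = 1` the posterior collapses onto the clean image
#' (\eqn{\tilde\mu_1 = y_0}, variance 0).
#'
#' @param x0 Clean image raster.
#' @param y_t Noisy raster; `t` is read from its attribute unless given.
#' @param schedule A [cosine_schedule()].
#' @param t Timestep (>= 1).
#' @return List with `mean` (raster) and `variance` (scalar).
#' @export
posterior_params <- function(x0, y_t, schedule, t = attr(y_t, "t")) {
  if (is.null(t) || t < 1) abort("posterior_params: t must be >= 1.")
  t <- check_t(t, schedule)
  assert_same_grid(x0, y_t, "x0 and y_t")
  ab_t <- schedule$alpha_bar[t]
  ab_prev <- if (t == 1L) 1 else schedule$alpha_bar[t - 1L]
  beta_t <- schedule$beta[t]
  alpha_t <- schedule$alpha[t]
  coef0 <- sqrt(ab_prev) * beta_t / (1 - ab_t)
  coeft <- sqrt(alpha_t) * (1 - ab_prev) / (1 - ab_t)
  strip <- function(v) matrix(as.numeric(v), nrow(v), ncol(v))
  list(mean = coef0 * strip(x0) + coeft * strip(y_t),
       variance = schedule$posterior_variance[t])
}

#' Classifier-free guidance configuration
#'
#' Holds the guidance scale `s` of the extrapolation
#' \eqn{\hat\epsilon = \epsilon_c + s(\epsilon_c - \epsilon_\varnothing)}.
#' When disabled (the default at inference, which roughly halves sampling
#' cost since only the conditional branch is evaluated), the sampler never
#' evaluates the null-condition branch.
#'
#' @param scale Guidance scale `s` (>= 0).
#' @param enabled Logical flag.
#' @return A `guidance_setting` object.
#' @export
guidance_setting <- function(scale = 0, enabled = FALSE) {
  stopifnot_scalar_num(scale, "scale", lower = 0)
  structure(list(scale = scale, enabled = isTRUE(enabled)),
            class = "guidance_setting")
}

#' Combine conditional and unconditional noise predictions
#'
#' Returns \eqn{\epsilon_c + s(\epsilon_c - \epsilon_\varnothing)} when
#' guidance is enabled; with guidance disabled the conditional prediction is
#' returned untouched and `eps_null` is never required.
#'
#' @param eps_cond Conditional noise prediction raster.
#' @param eps_null Unconditional (null-condition) prediction; may be `NULL`
#'   when guidance is disabled.
#' @param g A [guidance_setting()].
#' @return Raster of guided noise.
#' @export
guided_noise <- function(eps_cond, eps_null = NULL, g = guidance_setting()) {
  if (!g$enabled) return(eps_cond)
  if (is.null(eps_null)) abort("guided_noise: eps_null required when guidance is enabled.")
  assert_same_grid(eps_cond, eps_null, "eps_cond and eps_null")
  eps_cond + g$scale * (eps_cond - eps_null)
}

#' Hybrid diffusion loss configuration
#' @param kl_weight Weight of the KL term (default 0.001, chosen to keep the
#'   variance-learning term from destabilising the noise-prediction term).
#' @return A `hybrid_loss_config` object.
#' @export
hybrid_loss_config <- function(kl_weight = 0.001) {
  stopifnot_scalar_num(kl_weight, "kl_weight", lower = 0)
  structure(list(kl_weight = kl_weight), class = "hybrid_loss_config")
}

# KL( N(mu1, var1) || N(mu2, var2) ), elementwise
gaussian_kl <- function(mu1, var1, mu2, var2) {
  0.5 * (log(var2 / var1) + (var1 + (mu1 - mu2)^2) / var2 - 1)
}

#' Hybrid diffusion training loss
#'
#' `mean((eps_pred - eps_true)^2) + kl_weight * mean(KL(estimated || posterior))`,
#' where the estimated reverse-step distribution has per-pixel variance
#' `var_pred` and mean `mean_pred` (taken as the posterior mean when omitted:
#' the mean path of the KL term is detached during training, so only the
#' variance head receives gradient from it).
#'
#' @param eps_pred,eps_true Predicted and true noise rasters.
#' @param var_pred Per-pixel variance estimate (raster or scalar, > 0).
#' @param config A [hybrid_loss_config()].
#' @param posterior List `(mean, variance)` from [posterior_params()].
#' @param mean_pred Optional estimated mean raster (detached).
#' @return List with `loss`, `simple_term`, `kl_term` scalars.
#' @export
hybrid_loss <- function(eps_pred, eps_true, var_pred, config, posterior,
                        mean_pred = NULL) {
  if (!all(is.finite(eps_pred)) || !all(is.finite(eps_true)) ||
      !all(is.finite(var_pred))) {
    abort("hybrid_loss: non-finite inputs.")
  }
  assert_same_grid(eps_pred, eps_true, "eps_pred and eps_true")
  simple <- mean((eps_pred - eps_true)^2)
  mu_est <- if (is.null(mean_pred)) posterior$mean else mean_pred
  pv <- posterior$variance
  kl <- if (pv <= 0) {
    # degenerate first-step posterior: fall back to a matched-variance check
    mean(0.5 * (mu_est - posterior$mean)^2 / pmax(var_pred, 1e-12))
  } else {
    mean(gaussian_kl(mu_est, var_pred, posterior$mean, pv))
  }
  list(loss = simple + config$kl_weight * kl, simple_term = simple, kl_term = kl)
}

#' Write / read a noise schedule as CSV
#' @param schedule A `noise_schedule`.
#' @param path CSV path.
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- tibble::as_tibble(schedule)
  df$T_steps <- schedule_T(schedule)
  df$offset <- attr(schedule, "offset")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble::tibble(t = df$t, beta = df$beta, alpha = df$alpha,
                        alpha_bar = df$alpha_bar,
                        posterior_variance = df$posterior_variance)
  structure(out, class = c("noise_schedule", class(out)),
            T_steps = as.integer(max(df$t)), offset = df$offset[1])
}
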