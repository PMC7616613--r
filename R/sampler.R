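# dispatch for "conditional noise predictor": either an sdm_denoiser or a
# plain function(y, t, label_map) returning list(eps, v)
predict_noise <- function(denoiser, y, t, label_map) {
  out <- if (inherits(denoiser, "sdm_denoiser")) {
    sdm_predict(denoiser, y, t, label_map)
  } else {
    denoiser(y, t, label_map)
  }
  if (is.null(out$eps)) abort("denoiser must return list(eps, v).")
  if (!identical(dim(out$eps), dim(y))) {
    abort(sprintf("denoiser output grid %s does not match input %s.",
                  paste(dim(out$eps), collapse = "x"), paste(dim(y), collapse = "x")))
  }
  out
}

# posterior variance with the degenerate first entry replaced (log-space use)
clipped_posterior_variance <- function(schedule) {
  pv <- schedule$posterior_variance
  pv[1] <- if (length(pv) > 1) pv[2] else schedule$beta[1]
  pmax(pv, 1e-20)
}

#' Ancestral sampling from a trained conditional denoiser
#'
#' Starts from unit Gaussian noise and iterates \eqn{t = T..1}: the denoiser
#' predicts the noise (combined across the conditional and null branches by
#' classifier-free extrapolation only when guidance is enabled; when disabled
#' the null branch is never evaluated), the implied clean image is clipped to
#' `[-1, 1]`, the reverse step draws from a Gaussian centred on the diffusion
#' posterior mean with learned-range variance
#' \eqn{\exp(v \log\beta_t + (1-v)\log\tilde\beta_t)}, and no noise is added
#' at `t = 1`. Reproducible from `rng_seed`.
#'
#' @param denoiser An `sdm_denoiser` or a function `(y, t, label_map)` that
#'   returns `list(eps, v)`.
#' @param label_map Conditioning `label_map` raster.
#' @param schedule A [cosine_schedule()].
#' @param g A [guidance_setting()]; disabled by default.
#' @param rng_seed Seed for the noise draws.
#' @param clip_x0 Clip the implied clean image to `[-1, 1]` (default TRUE).
#' @return An `echo_image` matrix on the diffusion scale `[-1, 1]`.
#' @export
ddpm_sample <- function(denoiser, label_map, schedule, g = guidance_setting(),
                        rng_seed = 0, clip_x0 = TRUE) {
  T_steps <- schedule_T(schedule)
  s <- dim(label_map)
  pvc <- clipped_posterior_variance(schedule)
  with_seed(rng_seed, {
    y <- matrix(rnorm(prod(s)), s[1], s[2])
    for (t in seq(T_steps, 1)) {
      pr <- predict_noise(denoiser, y, t, label_map)
      eps <- pr$eps
      if (g$enabled) {
        pr0 <- predict_noise(denoiser, y, t, NULL)
        eps <- guided_noise(eps, pr0$eps, g)
      }
      ab <- schedule$alpha_bar[t]
      x0_hat <- (y - sqrt(1 - ab) * eps) / sqrt(ab)
      if (clip_x0) x0_hat <- pmin(pmax(x0_hat, -1), 1)
      post <- posterior_params(x0_hat, y, schedule, t = t)
      if (t > 1) {
        log_var <- pr$v * log(schedule$beta[t]) + (1 - pr$v) * log(pvc[t])
        z <- matrix(rnorm(prod(s)), s[1], s[2])
        y <- post$mean + exp(0.5 * log_var) * z
      } else {
        y <- post$mean
      }
    }
    structure(y, class = c("echo_image", "matrix", "array"))
  })
}

#' Convert between unit `[0, 1]` and diffusion `[-1, 1]` intensity scales
#' @param img Image raster.
#' @return Rescaled raster.
#' @export
to_diffusion_scale <- function(img) 2 * unclass(img) - 1

#' @rdname to_diffusion_scale
#' @export
to_unit_scale <- function(img) (unclass(img) + 1) / 2
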