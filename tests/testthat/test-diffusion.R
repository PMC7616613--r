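test_that("cosine schedule satisfies its invariants", {
  for (T_steps in c(1, 50, 100, 1000)) {
    s <- cosine_schedule(T_steps)
    expect_true(all(s$beta > 0 & s$beta <= 0.999))
    expect_true(all(s$alpha_bar > 0 & s$alpha_bar < 1))
    if (T_steps > 1) expect_true(all(diff(s$alpha_bar) < 0))
    expect_equal(s$posterior_variance[1], 0)
    if (T_steps >= 2) {
      t <- 2:T_steps
      expect_equal(s$posterior_variance[t],
                   s$beta[t] * (1 - s$alpha_bar[t - 1]) / (1 - s$alpha_bar[t]))
    }
  }
  expect_error(cosine_schedule(0), "T_steps")
  expect_error(cosine_schedule(10, offset = 0), "offset")
})

test_that("cosine closed form is exact at the endpoints and at t = 500", {
  expect_identical(cosine_alpha_bar(0, 1000), 1)       # f(0)/f(0)
  expect_lt(cosine_alpha_bar(1000, 1000), 1e-30)       # cos^2(pi/2), pre-clipping
  # frozen arbitrary-precision evaluations of f(t)/f(0), T = 1000, offset 0.008
  expect_equal(cosine_alpha_bar(500, 1000), 0.493843590440637713, tolerance = 1e-12)
  expect_equal(cosine_schedule(1000)$alpha_bar[500], 0.493843590440637713,
               tolerance = 1e-10)
})

test_that("cosine schedule adds noise more slowly than linear early on", {
  T_steps <- 1000
  s <- cosine_schedule(T_steps)
  beta_lin <- seq(s$beta[1], s$beta[T_steps], length.out = T_steps)
  ab_lin <- cumprod(1 - beta_lin)
  expect_gt(s$alpha_bar[T_steps / 4], ab_lin[T_steps / 4])
})

test_that("forward diffusion matches its closed form in all limits", {
  s <- cosine_schedule(1000)
  x0 <- matrix(runif(16, -1, 1), 4, 4)
  noise <- matrix(rnorm(16), 4, 4)
  y <- forward_diffuse(x0, 1, noise, s)   # alpha_bar near 1
  expect_equal(unclass(y), sqrt(s$alpha_bar[1]) * x0 + sqrt(1 - s$alpha_bar[1]) * noise,
               ignore_attr = TRUE)
  y_end <- forward_diffuse(x0, 1000, noise, s)  # alpha_bar near 0
  expect_lt(max(abs(y_end - noise)), 0.05)
  # alpha_bar = 0.25, x0 = 1, noise = 0 -> 0.5 exactly
  t_q <- which.min(abs(s$alpha_bar - 0.25))
  ones <- matrix(1, 2, 2)
  y_q <- forward_diffuse(ones, t_q, ones * 0, s)
  expect_equal(unclass(y_q), sqrt(s$alpha_bar[t_q]) * ones, ignore_attr = TRUE)
  expect_error(forward_diffuse(x0, 0, noise, s), "out of range")
  expect_error(forward_diffuse(x0, 1001, noise, s), "out of range")
})

test_that("posterior parameters match a conjugate-Gaussian Bayes oracle", {
  s <- cosine_schedule(40)
  x0 <- matrix(c(0.3, -0.6), 1, 2)
  # independent route: product of the two Gaussian factors in y_{t-1}
  # (likelihood q(y_t | y_{t-1}) and prior q(y_{t-1} | y_0)), precision form
  for (t in c(2, 17, 40)) {
    y_t <- forward_diffuse(x0, t, matrix(rnorm(2), 1, 2), s)
    ab_prev <- s$alpha_bar[t - 1]
    tau <- s$alpha[t] / s$beta[t] + 1 / (1 - ab_prev)
    mean_oracle <- (sqrt(s$alpha[t]) * unclass(y_t) / s$beta[t] +
                      sqrt(ab_prev) * x0 / (1 - ab_prev)) / tau
    p <- posterior_params(x0, y_t, s)
    expect_lt(max(abs(p$mean - mean_oracle)), 1e-10)
    expect_lt(abs(p$variance - 1 / tau), 1e-10)
  }
  # t = 1: the posterior collapses onto the clean image
  y_1 <- forward_diffuse(x0, 1, matrix(rnorm(2), 1, 2), s)
  p1 <- posterior_params(x0, y_1, s)
  expect_equal(p1$mean, x0, tolerance = 1e-12)
  expect_equal(p1$variance, 0)
  # beta -> 0: the no-noise step is the identity on y_t
  s_big <- cosine_schedule(100000)
  y_b <- forward_diffuse(x0, 2, matrix(rnorm(2), 1, 2), s_big)
  pb <- posterior_params(x0, y_b, s_big)
  expect_lt(max(abs(pb$mean - y_b)), 5e-3)
  expect_error(posterior_params(x0, unclass(y_1), s, t = 0), "t must be")
})

test_that("guidance is linear in s, exact at s = 0, lazy when disabled", {
  ec <- matrix(2, 3, 3); en <- matrix(1, 3, 3)
  expect_identical(guided_noise(ec, en, guidance_setting(0, TRUE)), ec)
  expect_identical(guided_noise(ec, en, guidance_setting(1, TRUE)), matrix(3, 3, 3))
  expect_identical(guided_noise(ec, ec, guidance_setting(5, TRUE)), ec)
  # linearity in s
  s_vals <- c(0.5, 1.5, 4)
  outs <- vapply(s_vals, function(s) {
    guided_noise(ec, en, guidance_setting(s, TRUE))[1, 1]
  }, numeric(1))
  expect_equal(outs, 2 + s_vals * (2 - 1))
  # disabled: eps_null never required nor touched
  expect_identical(guided_noise(ec, NULL, guidance_setting(enabled = FALSE)), ec)
  expect_error(guided_noise(ec, matrix(1, 2, 2), guidance_setting(1, TRUE)),
               "grid")
})

test_that("hybrid loss vanishes at the optimum and reduces to MSE at weight 0", {
  s <- cosine_schedule(30)
  x0 <- matrix(runif(4, -1, 1), 2, 2)
  noise <- matrix(rnorm(4), 2, 2)
  y_t <- forward_diffuse(x0, 12, noise, s)
  post <- posterior_params(x0, y_t, s)
  out <- hybrid_loss(noise, noise, post$variance, hybrid_loss_config(), post)
  expect_equal(out$loss, 0, tolerance = 1e-12)
  eps_pred <- noise + 0.1
  out0 <- hybrid_loss(eps_pred, noise, post$variance * 2, hybrid_loss_config(0), post)
  expect_equal(out0$loss, mean((eps_pred - noise)^2))
  expect_error(hybrid_loss(noise * NA, noise, 1, hybrid_loss_config(), post),
               "non-finite")
})

test_that("hybrid-loss KL matches a closed-form univariate Gaussian oracle", {
  s <- cosine_schedule(30)
  x0 <- matrix(c(0.4, -0.2), 1, 2)
  y_t <- forward_diffuse(x0, 9, matrix(rnorm(2), 1, 2), s)
  post <- posterior_params(x0, y_t, s)
  mean_pred <- post$mean + c(0.05, -0.03)
  var_pred <- matrix(c(post$variance * 1.7, post$variance * 0.6), 1, 2)
  out <- hybrid_loss(matrix(0, 1, 2), matrix(0, 1, 2), var_pred,
                     hybrid_loss_config(1), post, mean_pred = mean_pred)
  kl_hand <- function(mu1, v1, mu2, v2) {
    log(sqrt(v2) / sqrt(v1)) + (v1 + (mu1 - mu2)^2) / (2 * v2) - 0.5
  }
  expected <- mean(c(kl_hand(mean_pred[1], var_pred[1], post$mean[1], post$variance),
                     kl_hand(mean_pred[2], var_pred[2], post$mean[2], post$variance)))
  expect_equal(out$kl_term, expected, tolerance = 1e-12)
})

test_that("forward single-step iteration matches the closed-form marginal", {
  # iterate y_t = sqrt(alpha_t) y_{t-1} + sqrt(beta_t) z_t and compare the
  # Monte-Carlo mean/variance with the marginal closed form
  s <- cosine_schedule(20)
  t_star <- 12
  x0 <- matrix(c(0.8, -0.5, 0.1, 0.9), 2, 2)
  n_mc <- 2000
  set.seed(42)
  vals <- replicate(n_mc, {
    y <- x0
    for (t in 1:t_star) {
      y <- sqrt(s$alpha[t]) * y + sqrt(s$beta[t]) * matrix(rnorm(4), 2, 2)
    }
    y
  })
  ab <- s$alpha_bar[t_star]
  mc_mean <- apply(vals, c(1, 2), mean)
  mc_var <- apply(vals, c(1, 2), stats::var)
  se_mean <- sqrt((1 - ab) / n_mc)
  expect_true(all(abs(mc_mean - sqrt(ab) * x0) < 3 * se_mean))
  se_var <- (1 - ab) * sqrt(2 / (n_mc - 1))
  expect_true(all(abs(mc_var - (1 - ab)) < 3 * se_var))
})

test_that("schedules round-trip through CSV", {
  s <- cosine_schedule(64)
  p <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(s, p)
  s2 <- read_schedule_csv(p)
  expect_equal(s2$alpha_bar, s$alpha_bar)
  expect_equal(s2$posterior_variance, s$posterior_variance)
  expect_identical(attr(s2, "T_steps"), attr(s, "T_steps"))
})
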