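# finite-difference gradient checks of the autodiff engine on tiny tensors
es <- asNamespace("echosynth")

fd_check <- function(f, x, g_analytic, h = 1e-6, tol = 1e-5) {
  set.seed(99)
  dx <- array(rnorm(length(x)), if (is.null(dim(x))) length(x) else dim(x))
  num <- (f(x + h * dx) - f(x - h * dx)) / (2 * h)
  expect_equal(num, sum(g_analytic * dx), tolerance = tol)
}

test_that("convolution forward/backward agree with finite differences", {
  set.seed(1)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  gy <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  bw <- es$conv2d_bw(x, w, gy, TRUE)
  fd_check(function(xx) sum(es$conv2d_fw(xx, w, b) * gy), x, bw$gx)
  fd_check(function(ww) sum(es$conv2d_fw(x, ww, b) * gy), w, bw$gw)
  fd_check(function(bb) sum(es$conv2d_fw(x, w, bb) * gy), b, bw$gb)
})

test_that("pool, upsample, instance norm and concat backprop correctly", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  probe <- function(opname) {
    tape <- es$tape_new()
    xin <- es$ag_input(tape, x, requires_grad = TRUE)
    node <- switch(opname,
                   pool = es$ag_pool2(tape, xin),
                   up = es$ag_up2(tape, xin),
                   inorm = es$ag_inorm(tape, xin),
                   silu = es$ag_silu(tape, xin),
                   concat = es$ag_concat_c(tape, xin, es$ag_input(tape, x * 2)))
    gy <- array(rnorm(length(node$value)), dim(node$value))
    es$backward(tape, list(list(node = node, grad = gy)))
    forward_scalar <- function(xx) {
      tp <- es$tape_new()
      xi <- es$ag_input(tp, xx)
      nd <- switch(opname,
                   pool = es$ag_pool2(tp, xi),
                   up = es$ag_up2(tp, xi),
                   inorm = es$ag_inorm(tp, xi),
                   silu = es$ag_silu(tp, xi),
                   concat = es$ag_concat_c(tp, xi, es$ag_input(tp, x * 2)))
      sum(nd$value * gy)
    }
    fd_check(forward_scalar, x, xin$grad, tol = 1e-4)
  }
  for (op in c("pool", "up", "inorm", "silu", "concat")) probe(op)
})

test_that("whole-denoiser parameter gradients agree with finite differences", {
  cfg <- denoiser_config(image_size = 8, base_channels = 4,
                         channel_multipliers = c(1, 2),
                         n_label_classes = 5, timestep_embedding_dim = 8,
                         seed = 3)
  den <- build_denoiser(cfg)
  # perturb zero-initialised layers so their gradients are informative
  set.seed(4)
  for (nm in names(den$store$values)) {
    if (all(den$store$values[[nm]] == 0)) {
      den$store$values[[nm]] <- den$store$values[[nm]] +
        rnorm(length(den$store$values[[nm]]), sd = 0.1)
    }
  }
  y <- array(rnorm(8 * 8), c(8, 8, 1, 1))
  oh <- array(0, c(8, 8, 5, 1)); oh[, , 1, ] <- 1; oh[3:6, 3:6, 1, ] <- 0
  oh[3:6, 3:6, 2, ] <- 1
  t_vec <- 3
  loss_of <- function(store) {
    tape <- es$tape_new()
    out <- es$sdm_forward(tape, store, cfg, y, t_vec, oh)
    sum(out$eps$value^2) + sum(out$vlogit$value^2)
  }
  tape <- es$tape_new()
  out <- es$sdm_forward(tape, den$store, cfg, y, t_vec, oh)
  grads <- es$backward(tape, list(
    list(node = out$eps, grad = 2 * out$eps$value),
    list(node = out$vlogit, grad = 2 * out$vlogit$value)))
  h <- 1e-5
  for (nm in c("conv_in_w", "enc1_c1_w", "mid_c2_b", "dec1_g_w", "dec2_c1_w",
               "temb_w", "enc2_tp_w", "head_w")) {
    st2 <- es$param_store(den$store$values)
    i <- which.max(abs(grads[[nm]]))
    st2$values[[nm]][i] <- st2$values[[nm]][i] + h
    up <- loss_of(st2)
    st2$values[[nm]][i] <- st2$values[[nm]][i] - 2 * h
    dn <- loss_of(st2)
    st2$values[[nm]][i] <- st2$values[[nm]][i] + h
    expect_equal((up - dn) / (2 * h), grads[[nm]][i], tolerance = 1e-3,
                 label = paste("grad of", nm))
  }
})

test_that("Adam with linear annealing drives a quadratic toward its optimum", {
  store <- es$param_store(list(theta = c(5, -3)))
  st <- es$adam_state(store$values)
  for (i in 1:300) {
    g <- 2 * (store$values$theta - c(1, 2))
    st <- es$adam_update(store, list(theta = g), st, lr = 0.1)
  }
  expect_equal(store$values$theta, c(1, 2), tolerance = 1e-3)
})
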