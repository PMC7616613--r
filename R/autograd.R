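# A compact reverse-mode autodiff engine ("tape") for the denoiser and the
# U-Net. Activations are column-major arrays (H, W, C, N); dense features are
# (d, N) matrices. Each op appends a node holding its value and a backward
# closure; backward() walks the tape in reverse, accumulating gradients into
# nodes that require them. Convolutions are the only compiled ops; everything
# else is vectorised base R. This is deliberately minimal: stride-1 "same"
# 3x3 convs, factor-2 pooling/upsampling, instance norm, dense layers and
# pointwise nonlinearities are all the nets here need.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$param_nodes <- list()
  tp
}

nd_new <- function(tape, value, parents = list(), backfn = NULL,
                   requires_grad = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$requires_grad <- requires_grad %||%
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  tape$nodes[[length(tape$nodes) + 1L]] <- node
  node
}

add_grad <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ag_input <- function(tape, value, requires_grad = FALSE) {
  nd_new(tape, value, requires_grad = requires_grad)
}

# Parameters live as plain arrays in `store$values`; ag_param materialises a
# tape node for one and records it so grads can be collected by name.
param_store <- function(values) {
  st <- new.env(parent = emptyenv())
  st$values <- values
  st
}

ag_param <- function(tape, store, name) {
  node <- nd_new(tape, store$values[[name]], requires_grad = TRUE)
  tape$param_nodes[[name]] <- c(tape$param_nodes[[name]], list(node))
  node
}

backward <- function(tape, seeds) {
  for (s in seeds) s$node$grad <- s$grad
  for (i in rev(seq_along(tape$nodes))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backfn)) node$backfn(node)
  }
  grads <- lapply(tape$param_nodes, function(nodes) {
    g <- NULL
    for (n in nodes) if (!is.null(n$grad)) g <- if (is.null(g)) n$grad else g + n$grad
    g
  })
  grads
}

## ---- ops ----

ag_conv2d <- function(tape, x, w, b) {
  val <- conv2d_fw(x$value, w$value, b$value)
  nd_new(tape, val, list(x, w, b), function(node) {
    r <- conv2d_bw(x$value, w$value, node$grad, x$requires_grad)
    if (x$requires_grad) add_grad(x, r$gx)
    add_grad(w, r$gw)
    add_grad(b, r$gb)
  })
}

ag_dense <- function(tape, x, w, b) {
  val <- w$value %*% x$value + b$value
  nd_new(tape, val, list(x, w, b), function(node) {
    g <- node$grad
    if (x$requires_grad) add_grad(x, crossprod(w$value, g))
    add_grad(w, tcrossprod(g, x$value))
    add_grad(b, rowSums(g))
  })
}

ag_relu <- function(tape, x) {
  mask <- x$value > 0
  nd_new(tape, x$value * mask, list(x), function(node) {
    add_grad(x, node$grad * mask)
  })
}

ag_silu <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  nd_new(tape, x$value * s, list(x), function(node) {
    add_grad(x, node$grad * (s * (1 + x$value * (1 - s))))
  })
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  nd_new(tape, s, list(x), function(node) {
    add_grad(x, node$grad * s * (1 - s))
  })
}

ag_add <- function(tape, a, b) {
  nd_new(tape, a$value + b$value, list(a, b), function(node) {
    add_grad(a, node$grad)
    add_grad(b, node$grad)
  })
}

# add a per-channel bias (C, N) to activations (H, W, C, N)
ag_add_chan <- function(tape, a, bias) {
  d <- dim(a$value)
  hw <- d[1] * d[2]
  expand <- function(bv) array(rep(as.vector(bv), each = hw), dim = d)
  nd_new(tape, a$value + expand(bias$value), list(a, bias), function(node) {
    add_grad(a, node$grad)
    gb <- colSums(matrix(node$grad, hw, d[3] * d[4]))
    add_grad(bias, matrix(gb, d[3], d[4]))
  })
}

ag_mul <- function(tape, a, b) {
  nd_new(tape, a$value * b$value, list(a, b), function(node) {
    add_grad(a, node$grad * b$value)
    add_grad(b, node$grad * a$value)
  })
}

ag_concat_c <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  val <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  val[, , seq_len(da[3]), ] <- a$value
  val[, , da[3] + seq_len(db[3]), ] <- b$value
  nd_new(tape, val, list(a, b), function(node) {
    add_grad(a, node$grad[, , seq_len(da[3]), , drop = FALSE])
    add_grad(b, node$grad[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

ag_slice_c <- function(tape, x, idx) {
  d <- dim(x$value)
  nd_new(tape, x$value[, , idx, , drop = FALSE], list(x), function(node) {
    g <- array(0, d)
    g[, , idx, ] <- node$grad
    add_grad(x, g)
  })
}

ag_pool2 <- function(tape, x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  o <- x$value[seq(1, H, 2), , , , drop = FALSE] +
    x$value[seq(2, H, 2), , , , drop = FALSE]
  o <- (o[, seq(1, W, 2), , , drop = FALSE] +
          o[, seq(2, W, 2), , , drop = FALSE]) / 4
  nd_new(tape, o, list(x), function(node) {
    g <- node$grad / 4
    gx <- g[rep(seq_len(H / 2), each = 2), rep(seq_len(W / 2), each = 2), , ,
            drop = FALSE]
    add_grad(x, gx)
  })
}

ag_up2 <- function(tape, x) {
  d <- dim(x$value)
  val <- x$value[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
                 drop = FALSE]
  nd_new(tape, val, list(x), function(node) {
    g <- node$grad
    H2 <- d[1] * 2; W2 <- d[2] * 2
    o <- g[seq(1, H2, 2), , , , drop = FALSE] + g[seq(2, H2, 2), , , , drop = FALSE]
    o <- o[, seq(1, W2, 2), , , drop = FALSE] + o[, seq(2, W2, 2), , , drop = FALSE]
    add_grad(x, o)
  })
}

# instance normalisation over (H, W) per channel per sample, no affine
ag_inorm <- function(tape, x, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  xm <- matrix(x$value, hw, d[3] * d[4])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  nd_new(tape, array(xhat, d), list(x), function(node) {
    g <- matrix(node$grad, hw, d[3] * d[4])
    gm <- colMeans(g)
    gxm <- colMeans(g * xhat)
    dx <- sweep(sweep(g, 2, gm) - sweep(xhat, 2, gxm, `*`), 2, istd, `*`)
    add_grad(x, array(dx, d))
  })
}

## ---- parameter initialisation and Adam ----

init_conv <- function(k, cin, cout, seed) {
  with_seed(seed, {
    fan_in <- k * k * cin
    array(rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)), c(k, k, cin, cout))
  })
}

init_dense <- function(din, dout, seed) {
  with_seed(seed, matrix(rnorm(dout * din, sd = sqrt(2 / din)), dout, din))
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       step = 0L)
}

adam_update <- function(store, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  for (name in names(grads)) {
    g <- grads[[name]]
    if (is.null(g)) next
    state$m[[name]] <- beta1 * state$m[[name]] + (1 - beta1) * g
    state$v[[name]] <- beta2 * state$v[[name]] + (1 - beta2) * g^2
    mhat <- state$m[[name]] / (1 - beta1^t)
    vhat <- state$v[[name]] / (1 - beta2^t)
    store$values[[name]] <- store$values[[name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# sinusoidal timestep embedding, dim must be even; returns (dim, length(t))
timestep_embedding <- function(t, dim, max_period = 10000) {
  half <- dim / 2
  freqs <- exp(-log(max_period) * (0:(half - 1)) / half)
  ang <- outer(freqs, t)
  rbind(cos(ang), sin(ang))
}
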