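#' Configuration of the label-conditioned denoiser
#'
#' A U-Net-shaped conditional noise predictor in the semantic-diffusion style:
#' the noisy image enters through the encoder, the semantic label map is
#' injected only into the decoder through spatially-adaptive normalisation
#' (per-pixel scale and shift computed from the one-hot label map by small
#' convolutions), and the timestep enters every residual block via a
#' sinusoidal embedding projected to a per-channel bias. The head emits two
#' channels: the noise estimate and a variance-interpolation coefficient in
#' (0, 1) (learned-range variance between \eqn{\beta_t} and the posterior
#' variance \eqn{\tilde\beta_t}).
#'
#' @param image_size Input side in pixels; must be divisible by
#'   `2^(levels - 1)` where `levels = length(channel_multipliers)`.
#' @param base_channels Channels at the first level.
#' @param channel_multipliers Per-level channel multipliers (also sets depth).
#' @param n_label_classes Number of semantic classes (>= 2).
#' @param timestep_embedding_dim Even embedding dimension.
#' @param attention_resolutions Reserved; the built-in engine implements no
#'   attention layers, so this must stay empty.
#' @param seed Seed for weight initialisation.
#' @return A `denoiser_config` object.
#' @export
denoiser_config <- function(image_size = 32,
                            base_channels = 16,
                            channel_multipliers = c(1, 2),
                            n_label_classes = 5,
                            timestep_embedding_dim = 32,
                            attention_resolutions = integer(0),
                            seed = 0) {
  levels <- length(channel_multipliers)
  if (image_size %% (2^(levels - 1)) != 0) {
    abort(sprintf("image_size %d not divisible by 2^%d.", image_size, levels - 1))
  }
  if (n_label_classes < 2) abort("n_label_classes must be >= 2.")
  if (timestep_embedding_dim %% 2 != 0) abort("timestep_embedding_dim must be even.")
  if (length(attention_resolutions)) {
    abort("attention_resolutions: attention layers are not implemented by the built-in engine.")
  }
  structure(list(image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels),
                 channel_multipliers = as.integer(channel_multipliers),
                 n_label_classes = as.integer(n_label_classes),
                 timestep_embedding_dim = as.integer(timestep_embedding_dim),
                 seed = seed),
            class = "denoiser_config")
}

#' One-hot expansion of a label map
#' @param label_map Integer raster with codes `0..n_classes-1`.
#' @param n_classes Number of classes.
#' @return Array `(H, W, n_classes)`.
#' @export
label_onehot <- function(label_map, n_classes = length(echo_classes())) {
  h <- nrow(label_map); w <- ncol(label_map)
  oh <- array(0, c(h, w, n_classes))
  for (k in seq_len(n_classes)) oh[, , k] <- (label_map == (k - 1L)) * 1
  oh
}

sdm_param_template <- function(cfg) {
  ch <- cfg$base_channels * cfg$channel_multipliers
  L <- length(ch)
  dt <- cfg$timestep_embedding_dim
  labC <- cfg$n_label_classes
  p <- list()
  sc <- 0L
  s <- function() { sc <<- sc + 1L; derive_seed(cfg$seed, sc) }
  conv <- function(cin, cout) list(w = init_conv(3, cin, cout, s()), b = rep(0, cout))
  # residual-branch outputs, SPADE modulations and the head start at zero so
  # the untrained network is near-identity — standard diffusion practice
  zconv <- function(cin, cout) list(w = array(0, c(3, 3, cin, cout)), b = rep(0, cout))
  put <- function(prefix, pair) {
    p[[paste0(prefix, "_w")]] <<- pair$w
    p[[paste0(prefix, "_b")]] <<- pair$b
  }
  p[["temb_w"]] <- init_dense(dt, dt, s()); p[["temb_b"]] <- rep(0, dt)
  put("conv_in", conv(1, ch[1]))
  res_params <- function(prefix, c_in) {
    put(paste0(prefix, "_c1"), conv(c_in, c_in))
    p[[paste0(prefix, "_tp_w")]] <<- init_dense(dt, c_in, s())
    p[[paste0(prefix, "_tp_b")]] <<- rep(0, c_in)
    put(paste0(prefix, "_c2"), zconv(c_in, c_in))
  }
  spade_params <- function(prefix, c_in, c_out) {
    put(paste0(prefix, "_g"), zconv(labC, c_in))
    put(paste0(prefix, "_s"), zconv(labC, c_in))
    put(paste0(prefix, "_c1"), conv(c_in, c_out))
    p[[paste0(prefix, "_tp_w")]] <<- init_dense(dt, c_out, s())
    p[[paste0(prefix, "_tp_b")]] <<- rep(0, c_out)
    put(paste0(prefix, "_c2"), zconv(c_out, c_out))
    put(paste0(prefix, "_sk"), conv(c_in, c_out))
  }
  for (l in seq_len(L)) {
    res_params(paste0("enc", l), ch[l])
    if (l < L) put(paste0("proj", l), conv(ch[l], ch[l + 1]))
  }
  res_params("mid", ch[L])
  spade_params(paste0("dec", L), ch[L], ch[L])
  for (l in rev(seq_len(L - 1))) {
    spade_params(paste0("dec", l), ch[l + 1] + ch[l], ch[l])
  }
  put("head", zconv(ch[1], 2))
  p
}

# forward pass; y (H,W,1,N), t_vec length N, onehot (H,W,C,N) or NULL for the
# null condition (all-zero one-hot). Returns nodes eps and vlogit.
sdm_forward <- function(tape, store, cfg, y, t_vec, onehot) {
  ch <- cfg$base_channels * cfg$channel_multipliers
  L <- length(ch)
  N <- dim(y)[4]
  P <- function(name) ag_param(tape, store, name)
  cv <- function(x, prefix) ag_conv2d(tape, x, P(paste0(prefix, "_w")), P(paste0(prefix, "_b")))

  temb_raw <- ag_input(tape, timestep_embedding(t_vec, cfg$timestep_embedding_dim))
  temb <- ag_silu(tape, ag_dense(tape, temb_raw, P("temb_w"), P("temb_b")))
  tbias <- function(prefix) {
    ag_dense(tape, temb, P(paste0(prefix, "_tp_w")), P(paste0(prefix, "_tp_b")))
  }

  # label pyramid (constant inputs); all-zero tensor encodes the null condition
  if (is.null(onehot)) {
    onehot <- array(0, c(cfg$image_size, cfg$image_size, cfg$n_label_classes, N))
  }
  lab <- list(ag_input(tape, onehot))
  for (l in seq_len(L - 1)) {
    lab[[l + 1]] <- ag_pool2(tape, lab[[l]])
  }

  resblock <- function(h, prefix) {
    h1 <- cv(h, paste0(prefix, "_c1"))
    h1 <- ag_add_chan(tape, h1, tbias(prefix))
    h1 <- ag_relu(tape, h1)
    h1 <- cv(h1, paste0(prefix, "_c2"))
    ag_add(tape, h, h1)
  }
  spade_block <- function(h, prefix, lab_node) {
    hn <- ag_inorm(tape, h)
    gamma <- cv(lab_node, paste0(prefix, "_g"))
    shift <- cv(lab_node, paste0(prefix, "_s"))
    one <- ag_input(tape, array(1, dim(gamma$value)))
    hmod <- ag_add(tape, ag_mul(tape, hn, ag_add(tape, one, gamma)), shift)
    h1 <- cv(hmod, paste0(prefix, "_c1"))
    h1 <- ag_add_chan(tape, h1, tbias(prefix))
    h1 <- ag_relu(tape, h1)
    h1 <- cv(h1, paste0(prefix, "_c2"))
    ag_add(tape, cv(h, paste0(prefix, "_sk")), h1)
  }

  h <- cv(ag_input(tape, y), "conv_in")
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    h <- resblock(h, paste0("enc", l))
    skips[[l]] <- h
    if (l < L) h <- cv(ag_pool2(tape, h), paste0("proj", l))
  }
  h <- resblock(h, "mid")
  h <- spade_block(h, paste0("dec", L), lab[[L]])
  for (l in rev(seq_len(L - 1))) {
    h <- ag_up2(tape, h)
    h <- ag_concat_c(tape, h, skips[[l]])
    h <- spade_block(h, paste0("dec", l), lab[[l]])
  }
  out <- cv(h, "head")
  list(eps = ag_slice_c(tape, out, 1L), vlogit = ag_slice_c(tape, out, 2L))
}

#' Build a label-conditioned denoiser
#'
#' Instantiates the network of [denoiser_config()] with freshly initialised
#' weights. The returned object is callable through [sdm_predict()].
#'
#' @param config A [denoiser_config()].
#' @return An `sdm_denoiser` object.
#' @export
build_denoiser <- function(config) {
  structure(list(config = config,
                 store = param_store(sdm_param_template(config)),
                 step = 0L),
            class = "sdm_denoiser")
}

#' @export
print.sdm_denoiser <- function(x, ...) {
  n_par <- sum(vapply(x$store$values, length, numeric(1)))
  cat(sprintf("<sdm_denoiser> %dpx, channels (%s), %d classes, %s parameters, step %d\n",
              x$config$image_size,
              paste(x$config$base_channels * x$config$channel_multipliers, collapse = ", "),
              x$config$n_label_classes, format(n_par, big.mark = ","), x$step))
  invisible(x)
}

#' Evaluate the denoiser on a batch
#'
#' @param model An `sdm_denoiser`.
#' @param y Noisy image: a matrix (single image) or array `(H, W, N)`.
#' @param t Timestep(s), length 1 or N.
#' @param label_map A `label_map` raster, a list of them (length N), or
#'   `NULL` for the null condition.
#' @return List with `eps` and `v` (variance-interpolation coefficient in
#'   (0,1)), each shaped like `y`.
#' @export
sdm_predict <- function(model, y, t, label_map = NULL) {
  cfg <- model$config
  single <- is.matrix(y)
  if (single) y <- array(y, c(dim(y), 1L))
  d <- dim(y)
  if (d[1] != cfg$image_size || d[2] != cfg$image_size) {
    abort(sprintf("sdm_predict: input grid %dx%d does not match model size %d.",
                  d[1], d[2], cfg$image_size))
  }
  N <- d[3]
  t_vec <- rep_len(t, N)
  onehot <- NULL
  if (!is.null(label_map)) {
    maps <- if (is.matrix(label_map)) list(label_map) else label_map
    maps <- rep_len(maps, N)
    onehot <- array(0, c(d[1], d[2], cfg$n_label_classes, N))
    for (n in seq_len(N)) onehot[, , , n] <- label_onehot(maps[[n]], cfg$n_label_classes)
  }
  tape <- tape_new()
  out <- sdm_forward(tape, model$store, cfg, array(y, c(d[1], d[2], 1L, N)),
                     t_vec, onehot)
  eps <- array(out$eps$value, c(d[1], d[2], N))
  v <- array(1 / (1 + exp(-out$vlogit$value)), c(d[1], d[2], N))
  if (single) {
    eps <- eps[, , 1]; v <- v[, , 1]
  }
  list(eps = eps, v = v)
}
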