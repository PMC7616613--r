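#' Affine + elastic augmentation parameters
#'
#' Ranges for the random label-map transformations used when constructing
#' synthetic datasets: rotation, translation (fraction of the image side),
#' isotropic scale and shear for the affine part; a coarse control-point grid
#' with bounded per-point displacement, smoothly interpolated, for the
#' elastic part. The control-point and displacement triples follow the
#' 3D-volume convention of (out-of-plane, row, col) applied to a
#' single-slice 2D image: the first component is inert, the in-plane grid is
#' `control_points[1:2]` cubic B-spline coefficients (free-form-deformation
#' style) and the in-plane displacement bound is `max_displacement[2:3]`
#' pixels — the peak-to-peak range of a coefficient, interpreted at a 256-px
#' reference resolution and scaled with the actual image size.
#'
#' @param rotation_range Degrees, default `c(-5, 5)`.
#' @param translate_range Fraction of image size, default `c(0, 0.05)`
#'   (magnitude; a random sign is drawn per axis).
#' @param scale_range Unitless, default `c(0.8, 1.05)`.
#' @param shear_max Degrees, default 5.
#' @param elastic_control_points Integer triple, default `c(10, 10, 4)`.
#' @param elastic_max_displacement Pixel triple, default `c(0, 30, 30)`.
#' @param seed Base seed of the augmentation rng streams.
#' @return An `augmentation_params` object.
#' @export
augmentation_params <- function(rotation_range = c(-5, 5),
                                translate_range = c(0, 0.05),
                                scale_range = c(0.8, 1.05),
                                shear_max = 5,
                                elastic_control_points = c(10, 10, 4),
                                elastic_max_displacement = c(0, 30, 30),
                                seed = 1) {
  if (any(scale_range <= 0)) abort("scale_range bounds must be positive.")
  if (!all(is.finite(c(rotation_range, shear_max)))) {
    abort("rotation and shear ranges must be finite.")
  }
  if (any(elastic_max_displacement < 0)) {
    abort("elastic displacement components must be >= 0.")
  }
  if (translate_range[1] < 0 || translate_range[2] < translate_range[1]) {
    abort("translate_range must be an increasing non-negative pair.")
  }
  structure(list(rotation_range = rotation_range,
                 translate_range = translate_range,
                 scale_range = scale_range,
                 shear_max = shear_max,
                 elastic_control_points = elastic_control_points,
                 elastic_max_displacement = elastic_max_displacement,
                 seed = seed),
            class = "augmentation_params")
}

# uniform cubic B-spline basis matrix mapping g control coefficients to s
# pixel positions (free-form-deformation convention: the control values are
# spline coefficients, so the smoothed field never exceeds their bound)
bspline_basis <- function(s, g) {
  # mesh-size convention of B-spline FFD libraries: g coefficients span a
  # lattice of (g - 3) cells across the image
  h <- s / (g - 3)
  u <- (0:(s - 1)) / h
  i <- floor(u)
  t_ <- u - i
  w <- cbind((1 - t_)^3 / 6,
             (3 * t_^3 - 6 * t_^2 + 4) / 6,
             (-3 * t_^3 + 3 * t_^2 + 3 * t_ + 1) / 6,
             t_^3 / 6)
  A <- matrix(0, s, g)
  for (k in 0:3) {
    idx <- pmin(pmax(i + k - 1, 0), g - 1) + 1
    A[cbind(seq_len(s), idx)] <- A[cbind(seq_len(s), idx)] + w[, k + 1]
  }
  A
}

# tensor-product cubic B-spline smoothing of a coarse (gr x gc) coefficient
# grid onto all pixel coordinates of an s x s image
interp_control_grid <- function(vals, s) {
  A1 <- bspline_basis(s, nrow(vals))
  A2 <- bspline_basis(s, ncol(vals))
  A1 %*% vals %*% t(A2)
}

#' Apply one random affine + elastic transform to a label map
#'
#' Draws one affine (rotation, translation, scale, shear inside the
#' configured ranges, about the image centre) and one elastic displacement
#' field (per-control-point displacements bounded by the in-plane maximum,
#' cubic-spline interpolated to the pixel grid), composes them, and resamples
#' the label map with nearest-neighbour interpolation, so no new class values
#' can appear. Out-of-bounds pixels become background. The rng stream is
#' keyed by `(params$seed, source_key, draw_index)`, making datasets
#' order-independent.
#'
#' @param labels A `label_map`.
#' @param params An [augmentation_params()].
#' @param draw_index Index of the draw (1-based).
#' @param source_key Integer identifying the source map.
#' @return Transformed `label_map`.
#' @export
random_affine_elastic <- function(labels, params, draw_index = 1, source_key = 0) {
  s <- nrow(labels)
  draw_seed <- derive_seed(params$seed, source_key, draw_index)
  with_seed(draw_seed, {
    rot <- runif(1, params$rotation_range[1], params$rotation_range[2]) * pi / 180
    tr_mag <- runif(2, params$translate_range[1], params$translate_range[2]) * s
    tr <- tr_mag * sample(c(-1, 1), 2, replace = TRUE)
    sc <- runif(1, params$scale_range[1], params$scale_range[2])
    sh <- runif(1, -params$shear_max, params$shear_max) * pi / 180
    gr <- params$elastic_control_points[1]
    gc <- params$elastic_control_points[2]
    # max_displacement bounds a coefficient's peak-to-peak range (half-
    # amplitude sampling), in pixels at the 256-px reference resolution
    dmax <- params$elastic_max_displacement[2:3] * s / 256 / 2
    dis_r <- matrix(runif(gr * gc, -dmax[1], dmax[1]), gr, gc)
    dis_c <- matrix(runif(gr * gc, -dmax[2], dmax[2]), gr, gc)

    # affine matrix mapping output pixel -> source pixel, about the centre
    ctr <- (s - 1) / 2
    rotm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    shm <- matrix(c(1, 0, tan(sh), 1), 2, 2)
    A <- (rotm %*% shm) * sc
    g <- pixel_grid(s)
    pr <- as.vector(g$r) - ctr
    pc <- as.vector(g$c) - ctr
    src_r <- A[1, 1] * pr + A[1, 2] * pc + ctr + tr[1]
    src_c <- A[2, 1] * pr + A[2, 2] * pc + ctr + tr[2]
    if (any(params$elastic_max_displacement[2:3] > 0)) {
      src_r <- src_r + as.vector(interp_control_grid(dis_r, s))
      src_c <- src_c + as.vector(interp_control_grid(dis_c, s))
    }
    ir <- round(src_r); ic <- round(src_c)
    ok <- ir >= 0 & ir < s & ic >= 0 & ic < s
    out <- integer(s * s)                       # background fill
    out[ok] <- labels[cbind(ir[ok] + 1L, ic[ok] + 1L)]
    as_label_map(matrix(out, s, s))
  })
}

#' Add the ultrasound-sector class to a label map by intensity thresholding
#'
#' Pixels whose image intensity exceeds `threshold` and that carry no anatomy
#' label receive the sector class; anatomy labels are never overwritten.
#'
#' @param image An `echo_image` on the unit scale.
#' @param labels A `label_map` on the same grid.
#' @param threshold Intensity threshold.
#' @return Updated `label_map`.
#' @export
add_sector_label <- function(image, labels, threshold = 0.02) {
  assert_same_grid(image, labels, "image and labels")
  cls <- echo_classes()
  out <- unclass(labels)
  out[unclass(image) > threshold & out == cls[["background"]]] <- cls[["sector"]]
  as_label_map(out)
}

#' Per-dataset construction specification
#'
#' @param view `"2C"` or `"4C"`; `phase` `"ED"` or `"ES"`.
#' @param n_source_train,n_source_val Source label-map counts (defaults 400
#'   and 50, the generative-model split).
#' @param transforms_per_map Random transforms applied to every source map
#'   (default 5), so each split grows by this factor.
#' @return A `dataset_spec` object.
#' @export
dataset_spec <- function(view, phase, n_source_train = 400, n_source_val = 50,
                         transforms_per_map = 5) {
  if (any(c(n_source_train, n_source_val, transforms_per_map) < 1)) {
    abort("dataset_spec: all counts must be >= 1.")
  }
  structure(list(view = match.arg(view, c("2C", "4C")),
                 phase = match.arg(phase, c("ED", "ES")),
                 n_source_train = as.integer(n_source_train),
                 n_source_val = as.integer(n_source_val),
                 transforms_per_map = as.integer(transforms_per_map)),
            class = "dataset_spec")
}

#' Build synthetic segmentation datasets from augmented label maps
#'
#' For each (view, phase) specification, every source label map is augmented
#' `transforms_per_map` times and each augmented map is paired with an image
#' sampled from that view's trained denoiser (one model per view; the same
#' model serves ED and ES). A fifth dataset aggregates the other four by
#' concatenation. The manifest records full provenance.
#'
#' @param sources Named list `"view/phase"` (e.g. `"2C/ED"`) of lists with
#'   elements `train` and `val`, each a list of `label_map`s.
#' @param specs List of [dataset_spec()]s, one per (view, phase).
#' @param predictors Named list (`"2C"`, `"4C"`) of denoisers (or predictor
#'   functions) used to sample images.
#' @param schedule A [cosine_schedule()] used for sampling.
#' @param params An [augmentation_params()].
#' @param guidance A [guidance_setting()] for sampling.
#' @return List with `datasets` (named list; each a list of entries
#'   `(label_map, image, meta)` split into `train`/`val`) and `manifest`
#'   tibble (`dataset, split, entry, source_id, draw, view, phase, seed`).
#' @export
build_synthetic_datasets <- function(sources, specs, predictors, schedule,
                                     params = augmentation_params(),
                                     guidance = guidance_setting()) {
  datasets <- list()
  rows <- list()
  for (spec in specs) {
    key <- paste(spec$view, spec$phase, sep = "/")
    src <- sources[[key]]
    if (is.null(src)) abort(sprintf("missing source maps for %s.", key))
    den <- predictors[[spec$view]]
    if (is.null(den)) {
      abort(sprintf("missing trained predictor for view %s.", spec$view))
    }
    ds <- list(train = list(), val = list())
    for (split in c("train", "val")) {
      n_src <- if (split == "train") spec$n_source_train else spec$n_source_val
      maps <- src[[split]]
      if (length(maps) < n_src) {
        abort(sprintf("%s/%s: %d source maps but %d requested.", key, split,
                      length(maps), n_src))
      }
      entry <- 0L
      for (i in seq_len(n_src)) {
        src_key <- derive_seed(params$seed, match(spec$view, c("2C", "4C")),
                               match(spec$phase, c("ED", "ES")),
                               match(split, c("train", "val")), i)
        for (d in seq_len(spec$transforms_per_map)) {
          aug <- random_affine_elastic(maps[[i]], params, draw_index = d,
                                       source_key = src_key)
          samp_seed <- derive_seed(src_key, d, 11L)
          img <- ddpm_sample(den, aug, schedule, g = guidance,
                             rng_seed = samp_seed)
          entry <- entry + 1L
          ds[[split]][[entry]] <- list(label_map = aug, image = img,
                                       meta = list(source_id = i, draw = d,
                                                   view = spec$view,
                                                   phase = spec$phase,
                                                   seed = samp_seed))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            dataset = key, split = split, entry = entry, source_id = i,
            draw = d, view = spec$view, phase = spec$phase, seed = samp_seed)
        }
      }
    }
    datasets[[key]] <- ds
  }
  agg <- list(
    train = do.call(c, lapply(datasets, `[[`, "train")),
    val = do.call(c, lapply(datasets, `[[`, "val"))
  )
  names(agg$train) <- NULL; names(agg$val) <- NULL
  datasets[["aggregate"]] <- agg
  manifest <- dplyr::bind_rows(rows)
  agg_rows <- dplyr::mutate(manifest, dataset = "aggregate")
  manifest <- dplyr::bind_rows(manifest, agg_rows)
  list(datasets = datasets, manifest = manifest)
}
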