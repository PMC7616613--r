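#' Semantic class codes used throughout the package
#'
#' Label maps are single-channel integer rasters with mutually exclusive
#' per-pixel codes: background 0, left-ventricular endocardium (cavity) 1,
#' left-ventricular myocardium/epicardium 2, left atrium 3, and ultrasound
#' sector 4. The sector code is assigned only where no anatomy class is
#' present; anatomically the chambers lie inside the sector, but codes are
#' exclusive so that one-hot expansion happens only at the model boundary.
#'
#' @return Named integer vector mapping class names to codes.
#' @export
echo_classes <- function() {
  c(background = 0L, lv_endo = 1L, lv_myo = 2L, la = 3L, sector = 4L)
}

class_name_of <- function(code) {
  cls <- echo_classes()
  names(cls)[match(code, cls)]
}

#' Cardiac phantom geometry
#'
#' Parametric description of one phantom frame: a cone-shaped ultrasound
#' sector with apex near the top of the image, an elliptical left-ventricular
#' cavity wrapped by a myocardial ring, and an elliptical left atrium below
#' the ventricle. All lengths are in pixels; pixel indices are 0-based,
#' row-major with the origin at the top-left corner.
#'
#' @param image_size Side of the square raster in pixels.
#' @param view `"2C"` or `"4C"` (apical two- / four-chamber).
#' @param phase `"ED"` or `"ES"`; ES scales the LV cavity axes by
#'   `systolic_factor` so that systolic frames have a strictly smaller cavity.
#' @param systolic_factor LV-axis scale applied at ES (default 0.7).
#' @param sector_apex,sector_half_angle,sector_depth Sector cone: apex
#'   `(row, col)`, half opening angle in degrees, depth in pixels.
#' @param lv_center,lv_axes LV cavity ellipse centre `(row, col)` and
#'   semi-axes `(row, col)` in pixels.
#' @param myo_thickness Myocardial ring thickness in pixels.
#' @param la_center,la_axes Left-atrium ellipse centre and semi-axes.
#' @return A `phantom_geometry` object (validated list).
#' @export
phantom_geometry <- function(image_size = 256,
                             view = c("4C", "2C"),
                             phase = c("ED", "ES"),
                             systolic_factor = 0.7,
                             sector_apex = NULL,
                             sector_half_angle = 45,
                             sector_depth = NULL,
                             lv_center = NULL,
                             lv_axes = NULL,
                             myo_thickness = NULL,
                             la_center = NULL,
                             la_axes = NULL) {
  view <- match.arg(view)
  phase <- match.arg(phase)
  s <- image_size
  stopifnot_scalar_num(s, "image_size", lower = 8)
  stopifnot_scalar_num(systolic_factor, "systolic_factor", lower = 0.1, upper = 1)

  # view-dependent template: 2C has a slimmer, slightly left-shifted ventricle
  side <- if (view == "4C") 1 else -1
  sector_apex <- sector_apex %||% c(0.04 * s, 0.50 * s)
  sector_depth <- sector_depth %||% (0.92 * s)
  lv_center <- lv_center %||% c(0.45 * s, (0.5 + side * 0.015) * s)
  lv_axes <- lv_axes %||% (if (view == "4C") c(0.21 * s, 0.125 * s) else c(0.22 * s, 0.105 * s))
  myo_thickness <- myo_thickness %||% max(1, 0.06 * s)
  la_center <- la_center %||% c(0.76 * s, (0.5 + side * 0.03) * s)
  la_axes <- la_axes %||% c(0.105 * s, 0.09 * s)

  if (phase == "ES") {
    lv_axes <- lv_axes * systolic_factor
  }

  geom <- structure(
    list(
      image_size = as.integer(round(s)),
      sector_apex = as.numeric(sector_apex),
      sector_half_angle = as.numeric(sector_half_angle),
      sector_depth = as.numeric(sector_depth),
      lv_center = as.numeric(lv_center),
      lv_axes = as.numeric(lv_axes),
      myo_thickness = as.numeric(myo_thickness),
      la_center = as.numeric(la_center),
      la_axes = as.numeric(la_axes),
      view_tag = view,
      phase_tag = phase,
      systolic_factor = systolic_factor
    ),
    class = "phantom_geometry"
  )
  validate_phantom_geometry(geom)
  geom
}

validate_phantom_geometry <- function(geom) {
  with(geom, {
    if (any(c(lv_axes, la_axes, myo_thickness, sector_depth) <= 0)) {
      abort("phantom_geometry: all axis lengths, thickness and depth must be strictly positive.")
    }
    if (sector_half_angle <= 0 || sector_half_angle >= 90) {
      abort("phantom_geometry: sector_half_angle must lie in (0, 90) degrees.")
    }
  })
  invisible(geom)
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("<phantom_geometry %s/%s %dpx> LV axes (%.1f, %.1f), myo %.1f px, LA axes (%.1f, %.1f)\n",
              x$view_tag, x$phase_tag, x$image_size,
              x$lv_axes[1], x$lv_axes[2], x$myo_thickness,
              x$la_axes[1], x$la_axes[2]))
  invisible(x)
}

# pixel-centre coordinate grids (0-based)
pixel_grid <- function(s) {
  list(r = matrix(rep(0:(s - 1), s), s, s),
       c = matrix(rep(0:(s - 1), each = s), s, s))
}

ellipse_mask <- function(s, center, axes) {
  g <- pixel_grid(s)
  ((g$r - center[1]) / axes[1])^2 + ((g$c - center[2]) / axes[2])^2 <= 1
}

sector_mask <- function(geom) {
  s <- geom$image_size
  g <- pixel_grid(s)
  dr <- g$r - geom$sector_apex[1]
  dc <- g$c - geom$sector_apex[2]
  dist <- sqrt(dr^2 + dc^2)
  ang <- atan2(abs(dc), dr) * 180 / pi  # angle from the downward axis
  dr >= 0 & dist <= geom$sector_depth & ang <= geom$sector_half_angle
}

#' Rasterise a phantom geometry into a semantic label map
#'
#' Deterministic for a fixed geometry. Classes follow [echo_classes()]:
#' the LV cavity is the geometry's ellipse, the myocardium is the ring
#' between the cavity and an ellipse grown by `myo_thickness`, the left
#' atrium its own ellipse, and the remaining insonified cone is sector fill.
#'
#' @param geometry A [phantom_geometry()].
#' @return An integer matrix of class `label_map` with a `classes` attribute.
#' @export
make_label_map <- function(geometry) {
  validate_phantom_geometry(geometry)
  s <- geometry$image_size
  sec <- sector_mask(geometry)
  bounds_ok <- function(center, axes) {
    all(center - axes >= 0) && all(center + axes <= s - 1)
  }
  if (!bounds_ok(geometry$lv_center, geometry$lv_axes + geometry$myo_thickness)) {
    abort("make_label_map: LV epicardium extends outside the ultrasound sector/image.")
  }
  if (!bounds_ok(geometry$la_center, geometry$la_axes)) {
    abort("make_label_map: left atrium extends outside the ultrasound sector/image.")
  }
  endo <- ellipse_mask(s, geometry$lv_center, geometry$lv_axes)
  epi <- ellipse_mask(s, geometry$lv_center, geometry$lv_axes + geometry$myo_thickness)
  la <- ellipse_mask(s, geometry$la_center, geometry$la_axes)

  for (part in list(list(epi, "LV epicardium"), list(la, "left atrium"))) {
    if (any(part[[1]] & !sec)) {
      abort(sprintf("make_label_map: %s extends outside the ultrasound sector/image.", part[[2]]))
    }
  }
  if (!any(endo) || !any(la) || !any(epi & !endo)) {
    abort("make_label_map: a structure rasterises to zero pixels; enlarge the geometry or the image.")
  }

  cls <- echo_classes()
  lab <- matrix(cls[["background"]], s, s)
  lab[sec] <- cls[["sector"]]
  lab[epi & !endo] <- cls[["lv_myo"]]
  lab[endo] <- cls[["lv_endo"]]
  lab[la & !epi] <- cls[["la"]]
  as_label_map(lab)
}

#' @export
as_label_map <- function(x) {
  stopifnot(is.matrix(x))
  storage.mode(x) <- "integer"
  structure(x, class = c("label_map", "matrix", "array"), classes = echo_classes())
}

#' Per-tissue echogenicity profile for pseudo-ultrasound rendering
#'
#' @param means Named per-class mean intensity in `[0, 1]`; the background
#'   mean must be 0. Defaults mimic the relative brightness of blood pools
#'   (dark), myocardium (bright) and unlabelled tissue in the sector.
#' @param speckle_scale Standard deviation of the unit-mean multiplicative
#'   speckle noise (>= 0); 0 disables speckle.
#' @param blur_radius Gaussian blur sigma in pixels; 0 disables blurring.
#' @return An `echo_profile` object.
#' @export
echogenicity_profile <- function(means = c(background = 0, lv_endo = 0.08,
                                           lv_myo = 0.65, la = 0.14, sector = 0.38),
                                 speckle_scale = 0.25,
                                 blur_radius = 1) {
  stopifnot_scalar_num(speckle_scale, "speckle_scale", lower = 0)
  stopifnot_scalar_num(blur_radius, "blur_radius", lower = 0)
  if (is.null(names(means)) || !all(names(echo_classes()) %in% names(means))) {
    abort("`means` must be named with one entry per class in echo_classes().")
  }
  if (means[["background"]] != 0) abort("background mean intensity must be 0.")
  if (any(means < 0 | means > 1)) abort("class mean intensities must lie in [0, 1].")
  structure(list(means = means, speckle_scale = speckle_scale,
                 blur_radius = blur_radius),
            class = "echo_profile")
}

# separable gaussian blur with edge replication; sigma in pixels
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  hw <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2))
  k <- k / sum(k)
  s <- nrow(img)
  pad_idx <- c(rep(1L, hw), seq_len(s), rep(s, hw))
  blur1 <- function(m) {  # blur down columns
    p <- m[pad_idx, , drop = FALSE]
    out <- matrix(0, s, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * p[j:(j + s - 1L), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

#' Render a pseudo-ultrasound image from a label map
#'
#' Per-pixel intensity is the class mean from `profile`, multiplied by
#' unit-mean gamma-distributed speckle with spread `speckle_scale`
#' (ultrasound speckle is multiplicative), Gaussian-blurred by
#' `blur_radius`, clipped to `[0, 1]`. Pixels outside the sector are
#' exactly 0. Reproducible for a fixed `rng_seed`.
#'
#' @param label_map A `label_map` raster.
#' @param profile An [echogenicity_profile()].
#' @param rng_seed Integer seed for the speckle draw.
#' @return A numeric matrix of class `echo_image` with intensities in `[0, 1]`.
#' @export
render_pseudo_ultrasound <- function(label_map, profile, rng_seed = 0) {
  cls <- echo_classes()
  present <- sort(unique(as.vector(label_map)))
  unknown <- setdiff(present, cls)
  if (length(unknown)) {
    abort(sprintf("render_pseudo_ultrasound: unknown class value(s) in label map: %s",
                  paste(unknown, collapse = ", ")))
  }
  lut <- profile$means[names(cls)]
  img <- matrix(lut[as.vector(label_map) + 1L], nrow(label_map), ncol(label_map))
  if (profile$speckle_scale > 0) {
    shape <- 1 / profile$speckle_scale^2
    noise <- with_seed(rng_seed, matrix(
      rgamma(length(img), shape = shape, scale = 1 / shape),
      nrow(img), ncol(img)))
    img <- img * noise
  }
  img <- gaussian_blur(img, profile$blur_radius)
  img[label_map == cls[["background"]]] <- 0
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(img, class = c("echo_image", "matrix", "array"))
}

jitter_geometry <- function(base, jitter, seed) {
  with_seed(seed, {
    s <- base$image_size
    j <- function(lo, hi) runif(1, lo, hi)
    phantom_geometry(
      image_size = s,
      view = base$view_tag,
      phase = base$phase_tag,
      systolic_factor = base$systolic_factor,
      sector_half_angle = base$sector_half_angle + j(-jitter$angle_deg, jitter$angle_deg),
      lv_center = base$lv_center + c(j(-1, 1), j(-1, 1)) * jitter$center_frac * s,
      lv_axes = (if (base$phase_tag == "ES") base$lv_axes / base$systolic_factor else base$lv_axes) *
        c(j(1 - jitter$axis_frac, 1 + jitter$axis_frac),
          j(1 - jitter$axis_frac, 1 + jitter$axis_frac)) *
        (if (base$phase_tag == "ES") base$systolic_factor else 1),
      myo_thickness = base$myo_thickness * j(1 - jitter$axis_frac, 1 + jitter$axis_frac),
      la_center = base$la_center + c(j(-1, 1), j(-1, 1)) * jitter$center_frac * s,
      la_axes = base$la_axes * c(j(1 - jitter$axis_frac, 1 + jitter$axis_frac),
                                 j(1 - jitter$axis_frac, 1 + jitter$axis_frac))
    )
  })
}

#' Generate a phantom dataset of paired label maps and pseudo-ultrasound images
#'
#' Each case contributes four paired samples (2C/4C views at ED/ES), with the
#' case geometry jittered around the view templates. ES frames reuse the ED
#' jitter so the systolic cavity is strictly smaller than its diastolic pair.
#' Fully reproducible from `seed`.
#'
#' @param n_cases Number of cases (>= 1).
#' @param image_size Raster side in pixels.
#' @param profile Rendering profile; see [echogenicity_profile()].
#' @param jitter List with `center_frac`, `axis_frac`, `angle_deg` jitter
#'   ranges applied per case.
#' @param seed Master seed.
#' @return A `phantom_dataset`: list of paired samples plus a tibble manifest
#'   (`case_id`, `view`, `phase`, `seed`).
#' @export
make_phantom_dataset <- function(n_cases,
                                 image_size = 64,
                                 profile = echogenicity_profile(),
                                 jitter = list(center_frac = 0.015, axis_frac = 0.08,
                                               angle_deg = 2),
                                 seed = 1) {
  if (!is.numeric(n_cases) || n_cases < 1) abort("`n_cases` must be >= 1.")
  n_cases <- as.integer(n_cases)
  samples <- vector("list", n_cases * 4L)
  rows <- vector("list", n_cases * 4L)
  i <- 0L
  for (case in seq_len(n_cases)) {
    for (view in c("2C", "4C")) {
      geom_seed <- derive_seed(seed, case, match(view, c("2C", "4C")))
      for (phase in c("ED", "ES")) {
        base <- phantom_geometry(image_size = image_size, view = view, phase = phase)
        geom <- jitter_geometry(base, jitter, geom_seed)  # shared seed pairs ED/ES
        lab <- make_label_map(geom)
        img_seed <- derive_seed(geom_seed, match(phase, c("ED", "ES")), 7L)
        img <- render_pseudo_ultrasound(lab, profile, rng_seed = img_seed)
        i <- i + 1L
        samples[[i]] <- list(label_map = lab, image = img,
                             meta = list(case_id = case, view = view,
                                         phase = phase, seed = img_seed))
        rows[[i]] <- tibble::tibble(case_id = case, view = view, phase = phase,
                                    seed = img_seed)
      }
    }
  }
  structure(list(samples = samples, manifest = dplyr::bind_rows(rows),
                 image_size = as.integer(image_size), seed = seed),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d samples (%d cases x 2 views x 2 phases), %dpx\n",
              length(x$samples), length(x$samples) / 4L, x$image_size))
  invisible(x)
}

#' Filter a phantom dataset by view/phase/case
#' @param data A `phantom_dataset`.
#' @param view,phase,cases Optional filters.
#' @return A `phantom_dataset` restricted to matching samples.
#' @export
filter_samples <- function(data, view = NULL, phase = NULL, cases = NULL) {
  keep <- vapply(data$samples, function(s) {
    (is.null(view) || s$meta$view %in% view) &&
      (is.null(phase) || s$meta$phase %in% phase) &&
      (is.null(cases) || s$meta$case_id %in% cases)
  }, logical(1))
  out <- data
  out$samples <- data$samples[keep]
  out$manifest <- data$manifest[keep, ]
  out
}
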