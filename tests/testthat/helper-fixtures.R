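# Shared fixtures, all generated in code.

tiny_label_map <- function(size = 16, phase = "ED") {
  make_label_map(phantom_geometry(size, phase = phase, myo_thickness = 2))
}

flat_profile <- function() echogenicity_profile(speckle_scale = 0, blur_radius = 0)

# denoiser that knows the true x0, inverting the forward process exactly
oracle_denoiser <- function(x0, schedule) {
  function(y, t, label_map) {
    ab <- schedule$alpha_bar[t]
    list(eps = (y - sqrt(ab) * x0) / sqrt(1 - ab),
         v = matrix(0.5, nrow(y), ncol(y)))
  }
}

# trivial predictor for dataset-construction tests: no network, returns a
# constant denoised estimate so sampling is instant
stub_predictor <- function() {
  function(y, t, label_map) {
    list(eps = y * 0, v = matrix(0.5, nrow(y), ncol(y)))
  }
}

identity_augmentation <- function(seed = 1) {
  augmentation_params(rotation_range = c(0, 0), translate_range = c(0, 0),
                      scale_range = c(1, 1), shear_max = 0,
                      elastic_max_displacement = c(0, 0, 0), seed = seed)
}

quiet_pipeline <- function(...) suppressMessages(run_pipeline(...))
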