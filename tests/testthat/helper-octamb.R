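# Shared fixtures. Everything is generated in code; the expensive trained
# model is built once per test run and cached for the acceptance tests.

# Small phantom frame used by most unit tests (fast to render and train on).
small_config <- function(...) {
  phantom_config(width_ascans = 64L, depth_pixels = 64L,
                 foveal_pit = list(center_frac = 0.5, depth_px = 6,
                                   halfwidth_ascans = 6), ...)
}

# Deterministic flat phantom: no waviness, no noise, no pit.
flat_config <- function(width = 64L, depth = 64L) {
  phantom_config(width_ascans = width, depth_pixels = depth,
                 boundary_waviness_amplitude = 0,
                 foveal_pit = list(center_frac = 0.5, depth_px = 0,
                                   halfwidth_ascans = 1),
                 speckle_noise_sd = 0)
}

# Tiny 2-level network for fast segnet unit tests.
tiny_model_config <- function(depth = 32L, width = 16L) {
  model_config(input_depth = depth, input_width = width, base_channels = 2L,
               n_levels = 2L, mdc_dilations = c(1L, 2L), seed = 11L)
}

# Random probability volume (width x depth x layers), rows on the simplex.
random_pv <- function(width = 8L, depth = 16L, layers = 6L, seed = 1L,
                      sharpness = 1) {
  p <- octamb:::with_seed(seed,
    array(stats::rexp(width * depth * layers)^sharpness,
          c(width, depth, layers)))
  for (x in seq_len(width)) for (l in seq_len(layers))
    p[x, , l] <- p[x, , l] / sum(p[x, , l])
  probability_volume(p)
}

# The shared "production" model for acceptance-level tests: trained once on
# clean default-frame phantoms, reused by criteria 4, 5 and 6.
.octamb_cache <- new.env(parent = emptyenv())

acceptance_model <- function() {
  if (!is.null(.octamb_cache$model)) return(.octamb_cache$model)
  pc <- phantom_config()
  train_s <- lapply(seq_len(100), function(i) generate_bscan(pc, list(), seed = i))
  model <- build_model(model_config())
  model <- train_model(model, train_s,
                       train_config(epochs = 6L, seed = 2024L))
  .octamb_cache$model <- model
  model
}

acceptance_phantom_config <- function() phantom_config()

# Cohort lesion menu used by the acceptance discrimination study:
# outer-retinal EZ loss plus inner-retinal edema.
acceptance_menu <- function(pc = phantom_config()) {
  W <- pc$width_ascans; H <- pc$depth_pixels
  list(
    lesion_spec("EZ_LOSS", lateral_center = W / 2, lateral_halfwidth = W / 8,
                amplitude = 0.7, blur_sd = 0.03 * H),
    lesion_spec("EDEMA", lateral_center = W / 2, lateral_halfwidth = W / 8,
                amplitude = 0.06 * H, blur_sd = 0.01 * H)
  )
}
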