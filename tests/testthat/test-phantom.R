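# Phantom generator: geometry, determinism, lesion locality and labels.

test_that("noise-free flat config reproduces the mean depths exactly", {
  cfg <- flat_config()
  s <- generate_bscan(cfg, list(), seed = 1)
  expect_equal(s$truth_boundaries,
               matrix(cfg$layer_mean_depths, 6, cfg$width_ascans),
               tolerance = 0)
  expect_false(s$global_label)
  expect_equal(dim(s$image), c(64L, 64L))
  expect_true(all(s$image >= 0 & s$image <= 1))
})

test_that("generation is deterministic and boundaries never cross", {
  cfg <- small_config()
  le <- lesion_spec("EDEMA", lateral_center = 32, lateral_halfwidth = 10,
                    amplitude = 4, blur_sd = 1)
  a <- generate_bscan(cfg, list(le), seed = 7)
  b <- generate_bscan(cfg, list(le), seed = 7)
  expect_identical(a, b)
  # ordering property over many random configurations and seeds
  for (i in 1:250) {
    cfg_i <- octamb:::with_seed(1000 + i, phantom_config(
      width_ascans = 32L, depth_pixels = 48L,
      boundary_waviness_amplitude = stats::runif(1, 0, 3),
      foveal_pit = list(center_frac = stats::runif(1, 0.3, 0.7),
                        depth_px = stats::runif(1, 0, 8),
                        halfwidth_ascans = stats::runif(1, 2, 8)),
      speckle_noise_sd = stats::runif(1, 0, 0.2)))
    s <- generate_bscan(cfg_i, list(), seed = i)
    expect_true(all(apply(s$truth_boundaries, 2, diff) > 0))
  }
})

test_that("EZ blur lesion lowers image gradient across the EZ without moving it", {
  cfg <- small_config(speckle_noise_sd = 0)
  le <- lesion_spec("EZ_LOSS", lateral_center = 32, lateral_halfwidth = 20,
                    amplitude = 0, blur_sd = 3)
  clean <- generate_bscan(cfg, list(), seed = 5)
  les <- generate_bscan(cfg, list(le), seed = 5)
  expect_equal(les$truth_boundaries, clean$truth_boundaries)
  # independent gradient oracle: central-difference magnitude across the EZ
  grad_at_ez <- function(s, cols) {
    g <- abs(s$image[-1, ] - s$image[-nrow(s$image), ])
    mean(vapply(cols, function(x) {
      z <- round(s$truth_boundaries[5, x])
      max(g[(z - 3):(z + 2), x])
    }, numeric(1)))
  }
  inside <- 25:39
  outside <- c(1:10, 54:64)
  expect_lt(grad_at_ez(les, inside), grad_at_ez(les, outside))
  # labels: blur-only lesion still marks the EZ abnormal
  expect_identical(les$layer_labels, c(rep(FALSE, 4), TRUE, FALSE))
})

test_that("lesions act only inside their window", {
  cfg <- small_config()
  le <- lesion_spec("OPL_DISTORTION", lateral_center = 30,
                    lateral_halfwidth = 8, amplitude = 3)
  clean <- generate_bscan(cfg, list(), seed = 3)
  les <- generate_bscan(cfg, list(le), seed = 3)
  out <- which(abs(seq_len(64) - 30) >= 8)
  expect_identical(les$image[, out], clean$image[, out])
  expect_identical(les$truth_boundaries[, out], clean$truth_boundaries[, out])
  expect_false(identical(les$truth_boundaries, clean$truth_boundaries))
})

test_that("invalid lesions are rejected with diagnostics", {
  cfg <- small_config()
  expect_error(lesion_spec("EZ_LOSS", 10, 5, amplitude = 0.5,
                           target_boundaries = 2L), "may only target")
  expect_error(lesion_spec("BOGUS", 10, 5), "unknown lesion kind")
  far <- lesion_spec("ERM", lateral_center = 500, lateral_halfwidth = 5,
                     amplitude = 2)
  expect_error(generate_bscan(cfg, list(far), seed = 1), "outside image width")
  huge <- lesion_spec("EDEMA", lateral_center = 32, lateral_halfwidth = 10,
                      amplitude = 200)
  expect_error(generate_bscan(cfg, list(huge), seed = 1), "cross")
})

test_that("volumes derive per-slice seeds and keep labels per slice", {
  cfg <- small_config()
  v1 <- generate_volume(cfg, n_slices = 6, seed = 11)
  v2 <- generate_volume(cfg, n_slices = 6, seed = 11)
  expect_identical(v1, v2)
  expect_error(generate_volume(cfg, n_slices = 0), "must lie in")
  # single slice equals generate_bscan under the derived seed
  v <- generate_volume(cfg, n_slices = 1, seed = 4)
  ds <- octamb:::derive_seeds(4, 1)
  expect_identical(v$slices[[1]], generate_bscan(cfg, list(), seed = ds[1]))
  # a blob spanning slices 3..5 labels exactly those slices
  tpl <- lesion_spec("EZ_LOSS", lateral_center = 32, lateral_halfwidth = 10,
                     amplitude = 0.6, blur_sd = 2)
  field <- lesion_blob(tpl, n_slices = 6, slice_center = 4,
                       slice_halfwidth = 1.5)
  vb <- generate_volume(cfg, n_slices = 6, lesion_field = field, seed = 11)
  lab <- vapply(vb$slices, function(s) s$layer_labels[5], logical(1))
  expect_identical(lab, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("cohort sizes, labels and per-layer counts are consistent", {
  cfg <- small_config()
  menu <- list(lesion_spec("EZ_LOSS", 32, 8, amplitude = 0.6, blur_sd = 2),
               lesion_spec("ERM", 32, 8, amplitude = 2, blur_sd = 0.5))
  normals <- generate_cohort(5, 0, menu, cfg, seed = 2)
  expect_length(normals, 5)
  expect_false(any(vapply(normals, `[[`, logical(1), "global_label")))

  ez_only <- generate_cohort(0, 5, menu[1], cfg, seed = 2)
  expect_true(all(vapply(ez_only, function(s) s$layer_labels[5], logical(1))))

  coh <- generate_cohort(20, 20, menu, cfg, seed = 7)
  labs <- vapply(coh, `[[`, logical(1), "global_label")
  expect_identical(labs, rep(c(FALSE, TRUE), each = 20))
  # recount oracle: labels match an independent pass over the drawn lesions
  for (s in coh) {
    expect_identical(s$global_label, any(s$layer_labels))
    recount <- rep(FALSE, 6)
    for (le in s$lesions)
      if (le$amplitude > 0 || le$blur_sd > 0)
        recount[le$target_boundaries] <- TRUE
    expect_identical(s$layer_labels, recount)
  }
  # reproducibility
  expect_identical(coh, generate_cohort(20, 20, menu, cfg, seed = 7))
  expect_error(generate_cohort(0, 3, list(), cfg, seed = 1),
               "non-empty lesion_menu")
})
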