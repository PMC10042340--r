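# Network contracts: shapes, softmax normalization, determinism, boundary
# extraction, tiling and augmentation, and a small end-to-end training run.

test_that("model output is a normalized probability volume of the right shape", {
  cfg <- tiny_model_config(depth = 32, width = 16)
  m <- build_model(cfg)
  img <- octamb:::with_seed(2, matrix(stats::runif(32 * 16), 32, 16))
  pv <- predict_probabilities(m, img)
  expect_s3_class(pv, "probability_volume")
  expect_equal(dim(pv$p), c(16L, 32L, 6L))
  sums <- apply(pv$p, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(pv$p >= 0))
  # determinism in inference mode (including all-zero input)
  z <- matrix(0, 32, 16)
  expect_identical(predict_probabilities(m, z), predict_probabilities(m, z))
  # same seed -> same weights
  expect_identical(build_model(cfg)$params, m$params)
  # dimension mismatch rejected
  expect_error(predict_probabilities(m, matrix(0, 32, 20)), "expects")
  # indivisible input sizes rejected with padding hint
  expect_error(model_config(input_depth = 30, input_width = 16,
                            n_levels = 3), "pad")
})

test_that("extract_boundaries is an argmax with smallest-depth tie-break", {
  p <- array(0, c(3, 50, 2))
  p[, 40, ] <- 1
  pv <- probability_volume(p)
  expect_true(all(extract_boundaries(pv) == 40L))
  # tie at depths 10 and 20 resolves to 10
  p2 <- array(0, c(1, 30, 1))
  p2[1, c(10, 20), 1] <- 0.5
  expect_equal(as.vector(extract_boundaries(probability_volume(p2))), 10L)
  # linear-scan oracle on random volumes
  pvr <- random_pv(width = 7, depth = 19, layers = 6, seed = 8)
  tr <- extract_boundaries(pvr)
  for (l in 1:6) for (x in 1:7) {
    best <- 1L
    for (z in 2:19) if (pvr$p[x, z, l] > pvr$p[x, best, l]) best <- z
    expect_identical(unname(tr[l, x]), best)
  }
})

test_that("quarter_split tiles partition the image and slice the truth", {
  s <- generate_bscan(small_config(), list(), seed = 4)
  tiles <- quarter_split(s)
  expect_length(tiles, 4)
  expect_true(all(vapply(tiles, function(t) ncol(t$image), integer(1)) == 16L))
  expect_identical(do.call(cbind, lapply(tiles, `[[`, "image")), s$image)
  for (k in 1:4) for (x in c(1L, 9L, 16L))
    expect_identical(tiles[[k]]$truth_boundaries[, x],
                     s$truth_boundaries[, x + (k - 1L) * 16L])
  odd <- s; odd$image <- s$image[, 1:63]; odd$truth_boundaries <- s$truth_boundaries[, 1:63]
  expect_error(quarter_split(odd), "divisible by 4")
})

test_that("augmentation: involution, identity, and flip oracle", {
  s <- generate_bscan(small_config(), list(), seed = 6)
  expect_identical(augment_sample(augment_sample(s, flip = TRUE), flip = TRUE), s)
  expect_identical(augment_sample(s, flip = FALSE, scale = 1, rotation_deg = 0), s)
  fl <- augment_sample(s, flip = TRUE)
  expect_identical(fl$truth_boundaries, s$truth_boundaries[, 64:1])
  expect_identical(fl$image, s$image[, 64:1])
  expect_identical(fl$layer_labels, s$layer_labels)
  # scaling/rotating keeps boundaries finite and ordered
  tr <- augment_sample(s, scale = 1.1, rotation_deg = 10)
  expect_true(all(apply(tr$truth_boundaries, 2, diff) > 0))
  expect_true(all(tr$image >= 0 & tr$image <= 1))
  # absurd transform rejected
  expect_error(augment_sample(s, scale = 20), "out of frame")
})

test_that("training reduces loss, is seeded, and recovers flat boundaries", {
  cfg <- flat_config(width = 32, depth = 32)
  train_s <- lapply(1:20, function(i) generate_bscan(cfg, list(), seed = i))
  mcfg <- model_config(input_depth = 32, input_width = 32, base_channels = 4,
                       n_levels = 2, mdc_dilations = c(1, 2, 4), seed = 3)
  tc <- train_config(epochs = 10, seed = 5,
                     augmentation = list(lr_flip = TRUE,
                                         scale_range = NULL,
                                         rotation_deg = 0,
                                         quarter_split = TRUE))
  m <- train_model(build_model(mcfg), train_s, tc)
  expect_length(m$loss_history, 10)
  expect_lt(utils::tail(m$loss_history, 1), m$loss_history[1])
  expect_true(m$trained)
  # bit-identical retraining under the same seeds
  m2 <- train_model(build_model(mcfg), train_s, tc)
  expect_identical(m$loss_history, m2$loss_history)
  expect_identical(m$params, m2$params)
  # boundary recovery on held-out clean flat phantoms
  held <- lapply(31:35, function(i) generate_bscan(cfg, list(), seed = i))
  mae <- vapply(held, function(s) {
    tr <- extract_boundaries(predict_probabilities(m, s))
    mean(abs(tr - s$truth_boundaries))
  }, numeric(1))
  expect_lt(mean(mae), 2)
  expect_error(train_model(build_model(mcfg), list(), tc), "no training samples")
})
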