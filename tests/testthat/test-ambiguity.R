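# Entropy and ambiguity-index computations, checked against closed forms
# and a term-by-term summation oracle.

make_pv <- function(rows) {
  # rows: list of probability vectors, one per (x, l) cell on a 1-layer strip
  depth <- length(rows[[1]])
  p <- array(0, c(length(rows), depth, 1))
  for (i in seq_along(rows)) p[i, , 1] <- rows[[i]]
  probability_volume(p)
}

test_that("entropy matches analytic values and conventions", {
  Z <- 512L
  pv <- make_pv(list(rep(1 / Z, Z),                      # uniform
                     c(1, rep(0, Z - 1)),                # one-hot
                     c(0.5, 0.5, rep(0, Z - 2))))        # half-half
  e <- ascan_entropy(pv)$e
  dimnames(e) <- NULL
  expect_equal(e[1, 1], log(Z), tolerance = 1e-10)
  expect_equal(e[2, 1], 0, tolerance = 1e-10)
  expect_equal(e[3, 1], log(2), tolerance = 1e-10)
  # log base 2 rescales
  e2 <- unname(ascan_entropy(pv, log_base = 2)$e)
  expect_equal(e2[1, 1], log2(Z), tolerance = 1e-10)
})

test_that("entropy equals direct term-by-term summation", {
  pv <- make_pv(list(c(0.7, 0.2, 0.1)))
  oracle <- -(0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1))
  expect_equal(unname(ascan_entropy(pv)$e[1, 1]), oracle, tolerance = 1e-12)
  # random distributions vs an independent double-loop summation
  pvr <- random_pv(width = 6, depth = 12, layers = 3, seed = 42)
  e <- ascan_entropy(pvr)$e
  dimnames(e) <- NULL
  for (x in 1:6) for (l in 1:3) {
    ref <- 0
    for (z in 1:12) {
      p <- pvr$p[x, z, l]
      if (p > 0) ref <- ref - p * log(p)
    }
    expect_equal(e[x, l], ref, tolerance = 1e-12)
  }
})

test_that("invalid probability volumes are rejected", {
  p <- array(1 / 4, c(2, 4, 1))
  p[1, 1, 1] <- -0.1
  expect_error(probability_volume(p), "negative")
  p2 <- array(1 / 3, c(2, 4, 1))
  expect_error(ascan_entropy(p2), "not normalized")
})

test_that("ambiguity indices are means, pooled identity holds", {
  pv <- random_pv(width = 10, depth = 16, layers = 6, seed = 3)
  ep <- ascan_entropy(pv)
  # closed-form mean
  ec <- ep; ec$e[, 2] <- c(0, log(2), log(4), rep(0.5, 7))
  expect_equal(layer_ambiguity_index(ec, 2, mask = 1:3),
               (0 + log(2) + log(4)) / 3, tolerance = 1e-12)
  # naive-mean oracle on every layer
  for (l in 1:6)
    expect_equal(layer_ambiguity_index(ep, l), sum(ep$e[, l]) / 10,
                 tolerance = 1e-12)
  ai <- overall_ambiguity_index(ep)
  expect_equal(ai$overall, mean(ai$per_layer), tolerance = 1e-12)
  expect_equal(ai$overall, mean(ep$e), tolerance = 1e-12)  # pooled identity
  expect_true(min(ai$per_layer) <= ai$overall &&
              ai$overall <= max(ai$per_layer))
  expect_named(ai$per_layer, boundary_names())
  # masks
  expect_error(layer_ambiguity_index(ep, 1, mask = integer(0)), "empty")
  expect_error(layer_ambiguity_index(ep, 1, mask = 99), "outside")
  m <- fovea_mask(10, 2, center_frac = 0.5)   # centre 5.5, excludes 4..7
  expect_identical(m, c(1L, 2L, 3L, 8L, 9L, 10L))
  expect_equal(overall_ambiguity_index(ep, m)$n_ascans, length(m))
})

test_that("entropy bounds, mixing monotonicity and sharpening hold", {
  Z <- 24L
  octamb:::with_seed(99, {
    for (i in 1:120) {
      p <- stats::rexp(Z); p <- p / sum(p)
      H0 <- -sum(p * log(p))
      expect_true(H0 >= 0 && H0 <= log(Z) + 1e-12)
      # entropy nondecreasing along the segment toward uniform
      ts <- seq(0, 1, length.out = 11)
      hs <- vapply(ts, function(t) {
        q <- (1 - t) * p + t / Z
        -sum(q * log(q))
      }, numeric(1))
      expect_true(all(diff(hs) >= -1e-10))
      # sharpening (power beta > 1, renormalized) never increases entropy
      for (beta in c(1.5, 2, 4)) {
        q <- p^beta; q <- q / sum(q)
        expect_lte(-sum(q * log(q)), H0 + 1e-12)
      }
    }
  })
})
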