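# Boundary-detection network: a U-Net-style encoder/decoder with skip
# connections and a multiple-dilated-convolution (MDC) bottleneck. All
# convolutions are 7x1 (vertical) to pick up horizontal edges; lateral
# context enters through the 2x2 pooling pyramid and the MDC block widens
# the vertical receptive field. The head is a per-boundary softmax along the
# depth axis, so each A-scan yields a probability distribution over the
# depth of each of the six boundaries.

#' Configuration of the boundary-detection network
#'
#' @param input_depth,input_width Expected image size in pixels. Both must be
#'   divisible by `2^(n_levels - 1)`.
#' @param n_boundaries Number of boundary layers (6 for the retinal set).
#' @param base_channels Channels at the first encoder level; doubled at each
#'   deeper level. The default 8 keeps a full training run within a few
#'   minutes on one CPU core; raise it for more capacity.
#' @param n_levels Encoder depth including the MDC bottleneck (2 or more).
#' @param mdc_dilations Distinct positive dilation rates of the parallel
#'   7x1 convolutions in the MDC block; their outputs are summed.
#' @param seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_depth = 128L, input_width = 256L,
                         n_boundaries = 6L, base_channels = 8L,
                         n_levels = 3L, mdc_dilations = c(1L, 2L, 4L, 8L),
                         seed = 42L) {
  check_scalar(input_depth, "input_depth", 8, Inf, integer = TRUE)
  check_scalar(input_width, "input_width", 4, Inf, integer = TRUE)
  check_scalar(base_channels, "base_channels", 1, Inf, integer = TRUE)
  check_scalar(n_levels, "n_levels", 2, 6, integer = TRUE)
  if (length(mdc_dilations) < 1L || any(mdc_dilations < 1) ||
      anyDuplicated(mdc_dilations))
    stop_octamb("'mdc_dilations' must be distinct positive integers")
  div <- 2L^(as.integer(n_levels) - 1L)
  if (input_depth %% div != 0L || input_width %% div != 0L)
    stop_octamb(paste0("input size %dx%d not divisible by 2^(n_levels-1)=%d; ",
                       "pad the image to a multiple of %d"),
                input_depth, input_width, div, div)
  structure(list(input_depth = as.integer(input_depth),
                 input_width = as.integer(input_width),
                 n_boundaries = as.integer(n_boundaries),
                 base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels),
                 vertical_kernel = c(7L, 1L),
                 mdc_dilations = as.integer(mdc_dilations),
                 seed = as.integer(seed)),
            class = "model_config")
}

# He-initialized 7x1 conv parameter block.
init_conv <- function(cin, cout, dil = 1L) {
  sd <- sqrt(2 / (KTAPS * cin))
  list(W = matrix(stats::rnorm(cin * KTAPS * cout, sd = sd), cin, KTAPS * cout),
       b = numeric(cout), dil = as.integer(dil))
}

#' Build a randomly initialized boundary-detection model
#'
#' @param config A [model_config()].
#' @return An object of class `octamb_model` holding the parameter list, the
#'   configuration, and a `trained` flag.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  C <- config$base_channels
  L <- config$n_levels
  params <- with_seed(config$seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(L - 1L)) {
      cc <- C * 2L^(i - 1L)
      p[[sprintf("enc%d.c1", i)]] <- init_conv(cin, cc)
      p[[sprintf("enc%d.c2", i)]] <- init_conv(cc, cc)
      cin <- cc
    }
    cb <- C * 2L^(L - 1L)
    p[["bott.c1"]] <- init_conv(cin, cb)
    for (dl in config$mdc_dilations)
      p[[sprintf("mdc.d%d", dl)]] <- init_conv(cb, cb, dil = dl)
    for (i in rev(seq_len(L - 1L))) {
      cc <- C * 2L^(i - 1L)
      cup <- C * 2L^i            # channels arriving from the level below
      p[[sprintf("dec%d.c1", i)]] <- init_conv(cup + cc, cc)
      p[[sprintf("dec%d.c2", i)]] <- init_conv(cc, cc)
    }
    p[["out"]] <- list(W = matrix(stats::rnorm(C * config$n_boundaries,
                                               sd = sqrt(2 / C)),
                                  C, config$n_boundaries),
                       b = numeric(config$n_boundaries))
    p
  })
  structure(list(config = config, params = params, trained = FALSE,
                 loss_history = numeric(0)),
            class = "octamb_model")
}

# Forward pass. x: (H, W, 1) array. Returns list(logits, probs, cache).
model_forward <- function(params, config, x, keep_cache = FALSE) {
  L <- config$n_levels
  cache <- if (keep_cache) list() else NULL
  a <- x
  skips <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {
    n1 <- sprintf("enc%d.c1", i); n2 <- sprintf("enc%d.c2", i)
    if (keep_cache) cache[[paste0(n1, ".x")]] <- a
    r1 <- relu_fwd(conv_fwd(a, params[[n1]]))
    if (keep_cache) { cache[[paste0(n1, ".y")]] <- r1
                      cache[[paste0(n2, ".x")]] <- r1 }
    r2 <- relu_fwd(conv_fwd(r1, params[[n2]]))
    if (keep_cache) cache[[paste0(n2, ".y")]] <- r2
    skips[[i]] <- r2
    a <- pool2_fwd(r2)
  }
  if (keep_cache) cache[["bott.c1.x"]] <- a
  rb <- relu_fwd(conv_fwd(a, params[["bott.c1"]]))
  if (keep_cache) cache[["bott.c1.y"]] <- rb
  m <- 0
  for (dl in config$mdc_dilations)
    m <- m + conv_fwd(rb, params[[sprintf("mdc.d%d", dl)]])
  rm_ <- relu_fwd(m)
  if (keep_cache) cache[["mdc.y"]] <- rm_
  a <- rm_
  for (i in rev(seq_len(L - 1L))) {
    n1 <- sprintf("dec%d.c1", i); n2 <- sprintf("dec%d.c2", i)
    u <- ups2_fwd(a)
    cc <- concat_ch(u, skips[[i]])
    if (keep_cache) cache[[paste0(n1, ".x")]] <- cc
    r1 <- relu_fwd(conv_fwd(cc, params[[n1]]))
    if (keep_cache) { cache[[paste0(n1, ".y")]] <- r1
                      cache[[paste0(n2, ".x")]] <- r1 }
    r2 <- relu_fwd(conv_fwd(r1, params[[n2]]))
    if (keep_cache) cache[[paste0(n2, ".y")]] <- r2
    a <- r2
  }
  d <- dim(a)
  am <- matrix(a, d[1L] * d[2L], d[3L])
  lo <- am %*% params[["out"]]$W
  lo <- lo + rep(params[["out"]]$b, each = nrow(lo))
  logits <- array(lo, c(d[1L], d[2L], config$n_boundaries))
  if (keep_cache) cache[["out.x"]] <- a
  list(logits = logits, probs = softmax_vert(logits), cache = cache)
}

# Backward pass from d(loss)/d(logits). Returns gradient list keyed like
# `params`, each entry list(W, b).
model_backward <- function(params, config, cache, dlogits) {
  L <- config$n_levels
  grads <- list()
  d <- dim(dlogits)
  dlm <- matrix(dlogits, d[1L] * d[2L], d[3L])
  aout <- cache[["out.x"]]
  am <- matrix(aout, length(aout) / dim(aout)[3L], dim(aout)[3L])
  grads[["out"]] <- list(W = crossprod(am, dlm), b = colSums(dlm))
  da <- array(tcrossprod(dlm, params[["out"]]$W), dim(aout))
  for (i in seq_len(L - 1L)) {
    n1 <- sprintf("dec%d.c1", i); n2 <- sprintf("dec%d.c2", i)
    da <- relu_bwd(da, cache[[paste0(n2, ".y")]])
    g2 <- conv_bwd(da, cache[[paste0(n2, ".x")]], params[[n2]])
    grads[[n2]] <- list(W = g2$dW, b = g2$db)
    da <- relu_bwd(g2$dx, cache[[paste0(n1, ".y")]])
    g1 <- conv_bwd(da, cache[[paste0(n1, ".x")]], params[[n1]])
    grads[[n1]] <- list(W = g1$dW, b = g1$db)
    cc <- dim(cache[[paste0(n1, ".x")]])[3L]
    cskip <- config$base_channels * 2L^(i - 1L)
    cup <- cc - cskip
    dcc <- g1$dx
    dskip <- dcc[, , cup + seq_len(cskip), drop = FALSE]
    da <- ups2_bwd(dcc[, , seq_len(cup), drop = FALSE])
    # stash the skip gradient; consumed when the encoder pass reaches level i
    grads[[sprintf(".skipgrad%d", i)]] <- dskip
  }
  # `da` now carries the gradient entering the MDC output
  da <- relu_bwd(da, cache[["mdc.y"]])
  drb <- 0
  for (dl in config$mdc_dilations) {
    nm <- sprintf("mdc.d%d", dl)
    g <- conv_bwd(da, cache[["bott.c1.y"]], params[[nm]])
    grads[[nm]] <- list(W = g$dW, b = g$db)
    drb <- drb + g$dx
  }
  drb <- relu_bwd(drb, cache[["bott.c1.y"]])
  gb <- conv_bwd(drb, cache[["bott.c1.x"]], params[["bott.c1"]])
  grads[["bott.c1"]] <- list(W = gb$dW, b = gb$db)
  da <- gb$dx
  for (i in rev(seq_len(L - 1L))) {
    n1 <- sprintf("enc%d.c1", i); n2 <- sprintf("enc%d.c2", i)
    hw <- dim(cache[[paste0(n2, ".y")]])
    dr2 <- pool2_bwd(da, hw) + grads[[sprintf(".skipgrad%d", i)]]
    grads[[sprintf(".skipgrad%d", i)]] <- NULL
    dr2 <- relu_bwd(dr2, cache[[paste0(n2, ".y")]])
    g2 <- conv_bwd(dr2, cache[[paste0(n2, ".x")]], params[[n2]])
    grads[[n2]] <- list(W = g2$dW, b = g2$db)
    dr1 <- relu_bwd(g2$dx, cache[[paste0(n1, ".y")]])
    g1 <- conv_bwd(dr1, cache[[paste0(n1, ".x")]], params[[n1]])
    grads[[n1]] <- list(W = g1$dW, b = g1$db)
    da <- g1$dx
  }
  grads[!startsWith(names(grads), ".skipgrad")]
}

#' Run the network on one image and return its probability volume
#'
#' Applies the forward pass and re-orders the softmax output into the
#' `p[x, z, l]` convention: the probability that boundary `l` lies at depth
#' `z` in A-scan `x`, normalized over `z` for every `(x, l)`.
#'
#' @param model An `octamb_model`.
#' @param image A depth x width matrix in `[0, 1]`, or a `bscan_sample`.
#' @return An object of class `probability_volume` with field `p`
#'   (width x depth x n_boundaries array) and metadata.
#' @export
predict_probabilities <- function(model, image) {
  stopifnot(inherits(model, "octamb_model"))
  if (inherits(image, "bscan_sample")) image <- image$image
  if (!is.matrix(image))
    stop_octamb("'image' must be a depth x width matrix or a bscan_sample")
  cfg <- model$config
  if (nrow(image) != cfg$input_depth || ncol(image) != cfg$input_width)
    stop_octamb("image is %dx%d but the model expects %dx%d (depth x width)",
                nrow(image), ncol(image), cfg$input_depth, cfg$input_width)
  fw <- model_forward(model$params, cfg, array(image, c(dim(image), 1L)))
  probability_volume(aperm(fw$probs, c(2L, 1L, 3L)))
}

#' Construct a probability volume container
#'
#' @param p A width x depth x n_boundaries array; `p[x, z, l]` is the
#'   probability that boundary `l` sits at depth `z` in A-scan `x`. Each
#'   `(x, l)` slice must be a probability distribution over depth.
#' @param tol Normalization tolerance.
#' @return An object of class `probability_volume`.
#' @export
probability_volume <- function(p, tol = 1e-5) {
  if (!is.array(p) || length(dim(p)) != 3L)
    stop_octamb("'p' must be a 3-d array (width x depth x layers)")
  if (any(p < -1e-9))
    stop_octamb("probability volume contains negative entries")
  s <- apply(p, c(1L, 3L), sum)
  if (any(abs(s - 1) > tol))
    stop_octamb("probability volume not normalized over depth (max |sum-1| = %g)",
                max(abs(s - 1)))
  structure(list(p = p,
                 width = dim(p)[1L], depth = dim(p)[2L],
                 n_boundaries = dim(p)[3L],
                 boundary_names = if (dim(p)[3L] == 6L) boundary_names()
                                  else paste0("L", seq_len(dim(p)[3L]))),
            class = "probability_volume")
}

#' Extract boundary positions as the per-A-scan argmax depth
#'
#' The depth with the highest probability in each A-scan is taken as the
#' boundary position; ties resolve to the smallest depth index.
#'
#' @param pv A [probability_volume()].
#' @return Integer matrix `depth[l, x]` (n_boundaries x width), 1-based.
#' @export
extract_boundaries <- function(pv) {
  stopifnot(inherits(pv, "probability_volume"))
  out <- matrix(0L, pv$n_boundaries, pv$width)
  for (l in seq_len(pv$n_boundaries)) {
    m <- pv$p[, , l]
    dim(m) <- c(pv$width, pv$depth)
    out[l, ] <- max.col(m, ties.method = "first")
  }
  rownames(out) <- pv$boundary_names
  out
}
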