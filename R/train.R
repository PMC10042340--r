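# Training recipe: quarter the annotated B-scans laterally, augment each
# tile (left-right flip, 0.9-1.1x scaling, +/-15 degree rotation), encode
# boundary truth as one-hot depth targets per (A-scan, layer), and minimize
# vertical cross-entropy with the AMSGrad optimizer. Tiles in a minibatch
# are concatenated along the A-scan axis: with vertical-only kernels and
# tile widths divisible by 2^(n_levels-1), pooling windows never straddle a
# tile border, so one forward pass serves the whole batch.

#' Training configuration
#'
#' @param learning_rate Step size of the AMSGrad optimizer.
#' @param batch_size Tiles per minibatch (default 5).
#' @param epochs Passes over the tile set.
#' @param augmentation List with `lr_flip` (logical), `scale_range`
#'   (length-2 in (0, Inf)), `rotation_deg` (max absolute rotation) and
#'   `quarter_split` (split each B-scan into 4 lateral tiles).
#' @param seed Seed controlling shuffling and augmentation draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 5L, epochs = 10L,
                         augmentation = list(lr_flip = TRUE,
                                             scale_range = c(0.9, 1.1),
                                             rotation_deg = 15,
                                             quarter_split = TRUE),
                         seed = 1L) {
  check_scalar(learning_rate, "learning_rate", 1e-8, 1)
  check_scalar(batch_size, "batch_size", 1, Inf, integer = TRUE)
  check_scalar(epochs, "epochs", 1, Inf, integer = TRUE)
  sr <- augmentation$scale_range
  if (!is.null(sr) && (length(sr) != 2L || any(sr <= 0)))
    stop_octamb("'scale_range' must be two positive numbers")
  structure(list(optimizer = "amsgrad", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 augmentation = augmentation, seed = as.integer(seed)),
            class = "train_config")
}

#' Split a B-scan laterally into four equal tiles
#'
#' Cuts along vertical lines into 4 tiles of `width/4` A-scans each, slicing
#' the image and the truth boundaries consistently; labels are carried over.
#'
#' @param sample A `bscan_sample`.
#' @return List of 4 `bscan_sample` tiles.
#' @export
quarter_split <- function(sample) {
  stopifnot(inherits(sample, "bscan_sample"))
  W <- ncol(sample$image)
  if (W %% 4L != 0L)
    stop_octamb("width %d not divisible by 4", W)
  tw <- W %/% 4L
  lapply(0:3, function(k) {
    cols <- k * tw + seq_len(tw)
    out <- sample
    out$image <- sample$image[, cols, drop = FALSE]
    out$truth_boundaries <- sample$truth_boundaries[, cols, drop = FALSE]
    out$tile_index <- k + 1L
    out
  })
}

#' Apply the training augmentations to a sample
#'
#' Left-right flip, isotropic scaling and rotation about the image centre.
#' The image is resampled bilinearly (edge-replicated outside the frame) and
#' the truth boundary curves are pushed through the same affine map, then
#' re-interpolated per output column; labels are preserved. Scale 1 with
#' rotation 0 and no flip is an exact identity, and flipping twice restores
#' the original sample.
#'
#' @param sample A `bscan_sample`.
#' @param flip Flip left-right?
#' @param scale Isotropic scale factor (> 0).
#' @param rotation_deg Rotation in degrees (counter-clockwise in image axes).
#' @return The transformed `bscan_sample`.
#' @export
augment_sample <- function(sample, flip = FALSE, scale = 1, rotation_deg = 0) {
  stopifnot(inherits(sample, "bscan_sample"))
  check_scalar(scale, "scale", 1e-6, Inf)
  img <- sample$image
  tb <- sample$truth_boundaries
  H <- nrow(img); W <- ncol(img)
  if (flip) {
    img <- img[, W:1, drop = FALSE]
    tb <- tb[, W:1, drop = FALSE]
  }
  if (scale != 1 || rotation_deg != 0) {
    th <- rotation_deg * pi / 180
    cz <- (H + 1) / 2; cx <- (W + 1) / 2
    # inverse map: output (z, x) -> input coordinates
    zz <- matrix(seq_len(H), H, W) - cz
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    iz <- ( cos(th) * zz - sin(th) * xx) / scale + cz
    ix <- ( sin(th) * zz + cos(th) * xx) / scale + cx
    img <- bilinear_sample(img, iz, ix)
    # forward-map the truth curve vertices, then re-grid per output column
    xs <- seq_len(W)
    tb2 <- matrix(NA_real_, nrow(tb), W)
    for (l in seq_len(nrow(tb))) {
      zf <- cz + scale * ( cos(th) * (tb[l, ] - cz) + sin(th) * (xs - cx))
      xf <- cx + scale * (-sin(th) * (tb[l, ] - cz) + cos(th) * (xs - cx))
      o <- order(xf)
      tb2[l, ] <- stats::approx(xf[o], zf[o], xout = xs, rule = 2)$y
    }
    tb <- tb2
    if (any(tb < 1) || any(tb > H))
      stop_octamb("augmentation pushed boundaries out of frame")
  }
  out <- sample
  out$image <- img
  out$truth_boundaries <- tb
  out
}

# Bilinear sampling with edge replication. iz/ix: matrices of input coords.
bilinear_sample <- function(img, iz, ix) {
  H <- nrow(img); W <- ncol(img)
  iz <- clamp(iz, 1, H); ix <- clamp(ix, 1, W)
  z0 <- pmin(floor(iz), H - 1L); x0 <- pmin(floor(ix), W - 1L)
  fz <- iz - z0; fx <- ix - x0
  i00 <- cbind(as.vector(z0), as.vector(x0))
  v <- (1 - fz) * (1 - fx) * img[i00] +
       fz * (1 - fx) * img[i00 + c(1L, 0L)] +
       (1 - fz) * fx * img[i00 + c(0L, 1L)] +
       fz * fx * img[i00 + c(1L, 1L)]
  matrix(v, H, W)
}

# --- AMSGrad -----------------------------------------------------------------

amsgrad_init <- function(params) {
  st <- list(t = 0L, m = list(), v = list(), vhat = list())
  for (nm in names(params)) {
    st$m[[nm]] <- list(W = 0 * params[[nm]]$W, b = 0 * params[[nm]]$b)
    st$v[[nm]] <- st$m[[nm]]
    st$vhat[[nm]] <- st$m[[nm]]
  }
  st
}

amsgrad_step <- function(params, grads, st, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (f in c("W", "b")) {
      g <- grads[[nm]][[f]]
      st$m[[nm]][[f]] <- beta1 * st$m[[nm]][[f]] + (1 - beta1) * g
      st$v[[nm]][[f]] <- beta2 * st$v[[nm]][[f]] + (1 - beta2) * g * g
      st$vhat[[nm]][[f]] <- pmax(st$vhat[[nm]][[f]], st$v[[nm]][[f]])
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (st$m[[nm]][[f]] / bc1) / (sqrt(st$vhat[[nm]][[f]] / bc2) + eps)
    }
  }
  list(params = params, state = st)
}

# --- training loop -----------------------------------------------------------

# One-hot depth targets for a tile: integer (W, L) matrix of rounded truth.
tile_targets <- function(tile, H) {
  t(pmin(pmax(round(tile$truth_boundaries), 1L), H))
}

#' Train the boundary-detection model
#'
#' Runs the full recipe: optional lateral quartering, per-tile augmentation,
#' minibatch vertical cross-entropy against one-hot boundary depths, AMSGrad
#' updates, and a per-epoch mean-loss history. Fully deterministic given the
#' seeds in the model and training configurations.
#'
#' @param model An `octamb_model` from [build_model()].
#' @param samples Non-empty list of `bscan_sample` training images.
#' @param cfg A [train_config()].
#' @return The trained model, with `trained = TRUE` and `loss_history`
#'   (mean minibatch loss per epoch).
#' @export
train_model <- function(model, samples, cfg = train_config()) {
  stopifnot(inherits(model, "octamb_model"), inherits(cfg, "train_config"))
  if (length(samples) == 0L) stop_octamb("no training samples given")
  for (s in samples) stopifnot(inherits(s, "bscan_sample"))
  mcfg <- model$config
  aug <- cfg$augmentation
  tiles <- if (isTRUE(aug$quarter_split)) {
    unlist(lapply(samples, quarter_split), recursive = FALSE)
  } else samples
  H <- nrow(tiles[[1L]]$image)
  tw <- ncol(tiles[[1L]]$image)
  if (H != mcfg$input_depth)
    stop_octamb("tile depth %d does not match model input_depth %d",
                H, mcfg$input_depth)
  div <- 2L^(mcfg$n_levels - 1L)
  if (tw %% div != 0L)
    stop_octamb("tile width %d not divisible by %d", tw, div)

  params <- model$params
  st <- amsgrad_init(params)
  nL <- mcfg$n_boundaries
  history <- numeric(cfg$epochs)

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(tiles))
      losses <- numeric(0)
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        xs <- vector("list", length(idx))
        ts <- vector("list", length(idx))
        for (j in seq_along(idx)) {
          tl <- tiles[[idx[j]]]
          fl <- isTRUE(aug$lr_flip) && stats::runif(1) < 0.5
          sc <- if (is.null(aug$scale_range)) 1
                else stats::runif(1, aug$scale_range[1L], aug$scale_range[2L])
          ro <- if (is.null(aug$rotation_deg) || aug$rotation_deg == 0) 0
                else stats::runif(1, -aug$rotation_deg, aug$rotation_deg)
          tl <- tryCatch(augment_sample(tl, fl, sc, ro),
                         error = function(e) tiles[[idx[j]]])
          xs[[j]] <- tl$image
          ts[[j]] <- tile_targets(tl, H)
        }
        xb <- array(do.call(cbind, xs), c(H, tw * length(idx), 1L))
        tb <- do.call(rbind, ts)           # (sum widths, L)
        fw <- model_forward(params, mcfg, xb, keep_cache = TRUE)
        lo <- ce_loss_vert(fw$probs, tb)
        if (!is.finite(lo$loss))
          stop_octamb("training diverged: non-finite loss at epoch %d", ep)
        grads <- model_backward(params, mcfg, fw$cache, lo$dlogits)
        up <- amsgrad_step(params, grads, st, cfg$learning_rate)
        params <- up$params
        st <- up$state
        losses <- c(losses, lo$loss)
      }
      history[ep] <- mean(losses)
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$loss_history <- history
  model$train_config <- cfg
  model
}
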