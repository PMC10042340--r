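# Internal neural-network primitives. Feature maps are (H, W, C) arrays
# (depth, A-scan, channel); column-major layout lets an (H, W, C) array be
# reinterpreted as an (H*W, C) matrix for free. All kernels are 7x1
# (vertical), so a convolution factorizes as one channel-mixing GEMM
# Z = X W (W holds the 7 taps side by side) followed by row-shifted
# accumulation of the 7 tap blocks -- the arithmetic lands in BLAS and the
# shifts are plain sub-assignments. Zero padding at the depth borders;
# dilation scales the tap offsets.

KTAPS <- 7L  # vertical kernel extent

# p: list(W = (Cin x 7*Cout) matrix with column blocks per tap,
#         b = length-Cout vector, dil = int)
conv_fwd <- function(x, p) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  Cout <- length(p$b)
  xm <- x; dim(xm) <- c(H * Wd, C)
  Z <- xm %*% p$W                          # (H*Wd, 7*Cout)
  dim(Z) <- c(H, Wd * Cout * KTAPS)
  y <- tap_accum(Z, Wd * Cout, p$dil)
  y <- y + rep(p$b, each = H * Wd)
  dim(y) <- c(H, Wd, Cout)
  y
}

# Returns list(dx, dW, db). `x` is the cached forward input.
conv_bwd <- function(dy, x, p) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  Cout <- length(p$b)
  dym <- dy; dim(dym) <- c(H, Wd * Cout)
  DT <- tap_expand(dym, p$dil)             # (H, Wd*Cout*7)
  dim(DT) <- c(H * Wd, Cout * KTAPS)
  xm <- x; dim(xm) <- c(H * Wd, C)
  dW <- crossprod(xm, DT)
  dim(dym) <- c(H * Wd, Cout)
  db <- colSums(dym)
  dx <- tcrossprod(DT, p$W)                # (H*Wd, C)
  dim(dx) <- c(H, Wd, C)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(dy, y) { dy[y <= 0] <- 0; dy }

# 2x2 average pooling (stride 2). H and W must be even.
pool2_fwd <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  0.25 * (x[ro, co, , drop = FALSE] + x[ro + 1L, co, , drop = FALSE] +
          x[ro, co + 1L, , drop = FALSE] + x[ro + 1L, co + 1L, , drop = FALSE])
}

pool2_bwd <- function(dy, hw) {
  d <- dim(dy)
  dx <- array(0, c(hw[1L], hw[2L], d[3L]))
  ro <- seq(1L, hw[1L], 2L); co <- seq(1L, hw[2L], 2L)
  g <- 0.25 * dy
  dx[ro, co, ] <- g; dx[ro + 1L, co, ] <- g
  dx[ro, co + 1L, ] <- g; dx[ro + 1L, co + 1L, ] <- g
  dx
}

# 2x2 nearest-neighbour upsampling.
ups2_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1L], 2L * d[2L], d[3L]))
  ro <- seq(1L, 2L * d[1L], 2L); co <- seq(1L, 2L * d[2L], 2L)
  y[ro, co, ] <- x; y[ro + 1L, co, ] <- x
  y[ro, co + 1L, ] <- x; y[ro + 1L, co + 1L, ] <- x
  y
}

ups2_bwd <- function(dy) {
  d <- dim(dy)
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  dy[ro, co, , drop = FALSE] + dy[ro + 1L, co, , drop = FALSE] +
    dy[ro, co + 1L, , drop = FALSE] + dy[ro + 1L, co + 1L, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1L], da[2L], da[3L] + db[3L]))
  y[, , seq_len(da[3L])] <- a
  y[, , da[3L] + seq_len(db[3L])] <- b
  y
}

# Softmax along the depth axis, per (A-scan, layer).
softmax_vert <- function(logits) {
  d <- dim(logits)
  m <- logits; dim(m) <- c(d[1L], d[2L] * d[3L])
  mx <- apply(m, 2L, max)
  e <- exp(m - rep(mx, each = d[1L]))
  p <- e / rep(colSums(e), each = d[1L])
  dim(p) <- d
  p
}

# Cross-entropy over the depth axis against one-hot targets.
# probs: (H, W, L); target_z: (W, L) integer depth indices in 1..H.
# Returns list(loss, dlogits) where dlogits is d(mean CE)/d(logits).
ce_loss_vert <- function(probs, target_z) {
  d <- dim(probs)
  n <- d[2L] * d[3L]
  pm <- probs; dim(pm) <- c(d[1L], n)
  idx <- as.integer(target_z) + (seq_len(n) - 1L) * d[1L]
  loss <- -mean(log(pmax(pm[idx], 1e-12)))
  dl <- pm
  dl[idx] <- dl[idx] - 1
  dl <- dl / n
  dim(dl) <- d
  list(loss = loss, dlogits = dl)
}
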