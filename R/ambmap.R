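# En-face ambiguity maps. Entropies from every slice of a volume are
# arranged on the slice x A-scan grid (one map per boundary layer), smoothed
# with an isotropic Gaussian (sigma = 1 by default), min-max normalized to
# [0, 1], and colorized with the classical jet colormap. The pipeline order
# is fixed: raw -> smooth -> normalize -> colorize.

#' Arrange per-slice entropies into a raw en-face map
#'
#' Row `s` of the map is the entropy row of slice `s` for the requested
#' layer, in acquisition order.
#'
#' @param profiles List of `entropy_profile`, one per slice, equal widths.
#' @param layer Boundary index.
#' @return Numeric matrix (slices x A-scans).
#' @export
build_enface <- function(profiles, layer) {
  if (length(profiles) == 0L) stop_octamb("no slices given")
  for (p in profiles) stopifnot(inherits(p, "entropy_profile"))
  ws <- vapply(profiles, function(p) nrow(p$e), integer(1L))
  if (length(unique(ws)) != 1L)
    stop_octamb("slices disagree on width: %s", paste(unique(ws), collapse = ","))
  check_scalar(layer, "layer", 1, ncol(profiles[[1L]]$e), integer = TRUE)
  t(vapply(profiles, function(p) p$e[, layer], numeric(ws[1L])))
}

# Reflect (mirror) an out-of-range index into 1..n.
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  per <- 2L * n
  j <- (i - 1L) %% per
  j <- ifelse(j < 0, j + per, j)
  as.integer(ifelse(j < n, j + 1L, per - j))
}

#' Smooth a map with an isotropic 2-D Gaussian
#'
#' Separable convolution with a normalized Gaussian kernel truncated at
#' `4 * sigma`, using reflect padding at the borders. A constant map is left
#' unchanged, and smoothing twice with sigma approximates a single pass with
#' `sigma * sqrt(2)` on interior pixels (Gaussian semigroup).
#'
#' @param map Numeric matrix with finite entries.
#' @param sigma Gaussian standard deviation in grid units (> 0).
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(map, sigma = 1) {
  if (!is.matrix(map)) stop_octamb("'map' must be a matrix")
  if (any(!is.finite(map))) stop_octamb("map contains non-finite entries")
  check_scalar(sigma, "sigma", 1e-9, Inf)
  r <- as.integer(ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_dim <- function(m) {     # along rows (dim 1)
    n <- nrow(m)
    acc <- 0
    for (t in -r:r) {
      idx <- mirror_index(seq_len(n) + t, n)
      acc <- acc + k[t + r + 1L] * m[idx, , drop = FALSE]
    }
    acc
  }
  t(smooth_dim(t(smooth_dim(map))))
}

#' Min-max normalize a map to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant map maps to all zeros (documented
#' degenerate rule).
#'
#' @param map Numeric matrix with finite entries.
#' @return Matrix in `[0, 1]` with attributes `norm_min` / `norm_max` so raw
#'   values remain recoverable.
#' @export
minmax_normalize <- function(map) {
  if (any(!is.finite(map))) stop_octamb("map contains non-finite entries")
  lo <- min(map); hi <- max(map)
  out <- if (hi == lo) array(0, dim(map)) else (map - lo) / (hi - lo)
  out <- matrix(out, nrow(map), ncol(map))
  attr(out, "norm_min") <- lo
  attr(out, "norm_max") <- hi
  out
}

#' The classical jet colormap specification
#'
#' Piecewise-linear anchors from dark blue through cyan and yellow to dark
#' red: 0 -> (0,0,0.5), 0.125 -> (0,0,1), 0.375 -> (0,1,1),
#' 0.625 -> (1,1,0), 0.875 -> (1,0,0), 1 -> (0.5,0,0).
#'
#' @return An object of class `colormap_spec` with fields `name` and
#'   `anchors` (data.frame with columns v, r, g, b).
#' @export
jet_colormap <- function() {
  structure(list(
    name = "jet",
    anchors = data.frame(v = c(0, 0.125, 0.375, 0.625, 0.875, 1),
                         r = c(0, 0, 0, 1, 1, 0.5),
                         g = c(0, 0, 1, 1, 0, 0),
                         b = c(0.5, 1, 1, 0, 0, 0))
  ), class = "colormap_spec")
}

#' Colorize a normalized map
#'
#' Maps each value in `[0, 1]` to RGB by piecewise-linear interpolation of
#' the colormap anchors.
#'
#' @param map Numeric matrix with values in `[0, 1]`.
#' @param spec A `colormap_spec`; defaults to [jet_colormap()].
#' @return Array (nrow x ncol x 3) of RGB values in `[0, 1]`.
#' @export
apply_colormap <- function(map, spec = jet_colormap()) {
  stopifnot(inherits(spec, "colormap_spec"))
  if (any(!is.finite(map)) || any(map < -1e-12) || any(map > 1 + 1e-12))
    stop_octamb("colormap input must lie in [0, 1]")
  v <- clamp(as.vector(map), 0, 1)
  a <- spec$anchors
  out <- array(0, c(nrow(map), ncol(map), 3L))
  for (ch in 1:3)
    out[, , ch] <- matrix(stats::approx(a$v, a[[c("r", "g", "b")[ch]]],
                                        xout = v)$y,
                          nrow(map), ncol(map))
  out
}

#' Build a per-layer ambiguity map from a volume's entropy profiles
#'
#' Runs the full fixed pipeline raw -> Gaussian smooth -> min-max normalize
#' -> jet colorize and keeps every stage, plus the normalization range so
#' raw entropies are recoverable from the normalized map.
#'
#' @param profiles List of `entropy_profile`, one per slice.
#' @param layer Boundary index.
#' @param sigma Gaussian smoothing sigma (grid units).
#' @param spec Colormap specification.
#' @return An object of class `enface_map` with fields `raw`, `smoothed`,
#'   `normalized`, `rgb`, `layer`, `layer_name`, `sigma`, `norm_range`.
#' @export
ambiguity_map <- function(profiles, layer, sigma = 1, spec = jet_colormap()) {
  raw <- build_enface(profiles, layer)
  sm <- gaussian_smooth(raw, sigma)
  nz <- minmax_normalize(sm)
  rgb <- apply_colormap(nz, spec)
  structure(list(raw = raw, smoothed = sm, normalized = nz, rgb = rgb,
                 layer = as.integer(layer),
                 layer_name = profiles[[1L]]$boundary_names[layer],
                 sigma = sigma,
                 norm_range = c(attr(nz, "norm_min"), attr(nz, "norm_max"))),
            class = "enface_map")
}
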