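# Ambiguity quantification. For each A-scan x and boundary layer l the
# network emits a probability distribution p[x, z, l] over depth; its
# Shannon entropy
#     e[x, l] = -sum_z p[x, z, l] * log p[x, z, l]
# measures how ambiguous the boundary detection is at that A-scan. Averaging
# entropies over A-scans gives the per-layer ambiguity index, and the mean
# of the six per-layer indices is the overall ambiguity index of the image.

#' Per-A-scan boundary-detection entropy
#'
#' Computes the Shannon entropy of the boundary-position distribution for
#' every A-scan and boundary layer, with the `0 * log 0 = 0` convention
#' (probabilities are clamped at `1e-12` inside the logarithm only).
#' Natural log by default; entropies then lie in `[0, ln(depth)]` nats.
#'
#' @param pv A [probability_volume()], or a bare width x depth x layers array
#'   (validated on entry; negative or unnormalized slices are rejected).
#' @param log_base Base of the logarithm (`exp(1)` for nats, 2 for bits).
#' @param tol Normalization tolerance used when validating a bare array.
#' @return An object of class `entropy_profile` with field `e`
#'   (width x layers matrix of entropies) and metadata.
#' @export
ascan_entropy <- function(pv, log_base = exp(1), tol = 1e-5) {
  if (!inherits(pv, "probability_volume")) pv <- probability_volume(pv, tol)
  check_scalar(log_base, "log_base", 1 + 1e-9, Inf)
  p <- pv$p
  lp <- log(pmax(p, 1e-12)) / log(log_base)
  e <- -apply(p * lp, c(1L, 3L), sum)
  e[e < 0] <- 0      # guard tiny negative round-off on one-hot slices
  colnames(e) <- pv$boundary_names
  structure(list(e = e, log_base = log_base,
                 depth_pixels = pv$depth,
                 boundary_names = pv$boundary_names),
            class = "entropy_profile")
}

#' Ambiguity index of one boundary layer
#'
#' Arithmetic mean of the per-A-scan entropies of a layer, optionally over a
#' subset of A-scans (e.g. excluding the foveal window, where the absent
#' inner retina inflates entropy in healthy eyes).
#'
#' @param ep An `entropy_profile` from [ascan_entropy()].
#' @param layer Boundary index in `1..n_layers`.
#' @param mask Optional non-empty integer vector of A-scan indices to include.
#' @return The layer's ambiguity index (a single number).
#' @export
layer_ambiguity_index <- function(ep, layer, mask = NULL) {
  stopifnot(inherits(ep, "entropy_profile"))
  check_scalar(layer, "layer", 1, ncol(ep$e), integer = TRUE)
  if (is.null(mask)) mask <- seq_len(nrow(ep$e))
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop_octamb("empty A-scan mask")
  if (any(mask < 1L) || any(mask > nrow(ep$e)))
    stop_octamb("mask indices outside 1..%d", nrow(ep$e))
  mean(ep$e[mask, layer])
}

#' Overall ambiguity index of an image
#'
#' Per-layer indices are the layer means of the entropy profile; the overall
#' index is the mean of the per-layer values, which on unmasked input equals
#' the pooled mean over all (A-scan, layer) entropies.
#'
#' @inheritParams layer_ambiguity_index
#' @return An object of class `ambiguity_index`: list with `per_layer`
#'   (named numeric of length n_layers), `overall`, `n_ascans`.
#' @export
overall_ambiguity_index <- function(ep, mask = NULL) {
  stopifnot(inherits(ep, "entropy_profile"))
  per <- vapply(seq_len(ncol(ep$e)), function(l)
    layer_ambiguity_index(ep, l, mask), numeric(1L))
  names(per) <- ep$boundary_names
  n <- if (is.null(mask)) nrow(ep$e) else length(mask)
  structure(list(per_layer = per, overall = mean(per), n_ascans = n),
            class = "ambiguity_index")
}

#' A-scan mask excluding a centred foveal window
#'
#' Convenience for the foveal confound: returns the indices of all A-scans
#' except a window of `halfwidth` columns either side of the image centre
#' (or of `center_frac * width`).
#'
#' @param width Number of A-scans.
#' @param halfwidth Half-width of the excluded window in A-scans.
#' @param center_frac Window centre as a fraction of width.
#' @return Integer vector of included A-scan indices.
#' @export
fovea_mask <- function(width, halfwidth, center_frac = 0.5) {
  check_scalar(width, "width", 1, Inf, integer = TRUE)
  check_scalar(halfwidth, "halfwidth", 0, Inf)
  cx <- center_frac * (width - 1) + 1
  x <- seq_len(width)
  out <- x[abs(x - cx) > halfwidth]
  if (length(out) == 0L) stop_octamb("fovea window excludes every A-scan")
  out
}
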