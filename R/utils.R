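# Internal helpers shared across modules.

#' Fixed anatomical order of the six segmented boundaries.
#'
#' ILM, NFL/GCL, IPL/INL, OPL/ONL, EZ and RPE/BM, ordered from the vitreous
#' downward. All per-layer containers in the package index layers in this
#' order.
#'
#' @return Character vector of length 6.
#' @export
boundary_names <- function() {
  c("ILM", "NFL/GCL", "IPL/INL", "OPL/ONL", "EZ", "RPE/BM")
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic entry points funnel through this
# so that a seed argument fully determines their output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from a master seed, each below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_octamb <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_octamb("'%s' must be a single finite number", name)
  if (x < lo || x > hi)
    stop_octamb("'%s' must lie in [%s, %s], got %s", name, lo, hi, x)
  if (integer && x != round(x))
    stop_octamb("'%s' must be an integer, got %s", name, x)
  invisible(TRUE)
}
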