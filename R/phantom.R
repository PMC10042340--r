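# Synthetic OCT phantom: layered retinal cross-sections with known boundary
# geometry, a foveal pit, multiplicative speckle, and injectable lesions.
# Stands in for a clinical B-scan dataset: every sample carries ground-truth
# boundary depths and per-layer abnormality labels.

#' Lesion kinds and the boundaries they are allowed to perturb
#'
#' Maps each supported lesion kind to the boundary indices (in
#' [boundary_names()] order) it may displace, blur or de-contrast.
#'
#' @return Named list of integer vectors.
#' @export
lesion_kinds <- function() {
  list(
    ERM            = 1L,          # epiretinal membrane wrinkles the ILM
    EDEMA          = c(3L, 4L),   # intraretinal fluid spreads IPL/INL vs OPL/ONL
    DRUSEN_PED     = c(5L, 6L),   # sub-RPE deposits elevate RPE/BM (and EZ)
    EZ_LOSS        = 5L,          # attenuation / blur of the ellipsoid zone
    OPL_DISTORTION = 4L,          # wavy distortion of the OPL/ONL boundary
    SRD            = c(5L, 6L)    # serous detachment lifts the EZ off the RPE
  )
}

#' Configuration of the synthetic B-scan phantom
#'
#' Describes the geometry and appearance of a layered retinal cross-section:
#' six boundary surfaces (ILM, NFL/GCL, IPL/INL, OPL/ONL, EZ, RPE/BM) drawn as
#' smooth curves separating seven reflectivity bands, an optional foveal pit
#' that pinches the inner boundaries together near the image centre, and
#' multiplicative speckle noise. The default 128 x 256 (depth x width) frame
#' is a desk-scale stand-in for a 512 x 1024 clinical export; the generator is
#' resolution-agnostic and full-size frames are produced by changing the two
#' size fields.
#'
#' @param width_ascans Number of A-scans (image columns).
#' @param depth_pixels Number of depth samples per A-scan (image rows; depth
#'   increases downward, row 1 is the vitreous side).
#' @param layer_mean_depths Six strictly increasing mean boundary depths in
#'   pixels; default scales fixed anatomical fractions by `depth_pixels`.
#' @param layer_intensities Seven reflectivities in `[0, 1]` for the bands
#'   above/between/below the six boundaries (vitreous, NFL, GCL+IPL, INL+OPL,
#'   ONL, EZ..RPE complex, choroid).
#' @param boundary_waviness_amplitude Peak amplitude in pixels of the smooth
#'   random undulation added to every boundary.
#' @param foveal_pit List with `center_frac` (pit centre as a fraction of
#'   width), `depth_px` (pit depth at the ILM, pixels; 0 disables the pit) and
#'   `halfwidth_ascans` (Gaussian half-width). The pit pulls boundaries 1-3
#'   toward the OPL/ONL surface, emulating the thinning of the inner retina at
#'   the fovea.
#' @param speckle_noise_sd Standard deviation of the multiplicative Gaussian
#'   speckle (`pixel * (1 + sd * N(0,1))`, clipped to `[0, 1]`).
#' @param edge_softness_px Baseline half-width in pixels of the logistic
#'   intensity transition at each boundary.
#' @param seed Default seed used by the generators when no explicit seed is
#'   passed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(width_ascans = 256L,
                           depth_pixels = 128L,
                           layer_mean_depths = NULL,
                           layer_intensities = c(0.05, 0.75, 0.45, 0.35,
                                                 0.15, 0.85, 0.30),
                           boundary_waviness_amplitude = 2,
                           foveal_pit = list(center_frac = 0.5,
                                             depth_px = 0.14 * depth_pixels,
                                             halfwidth_ascans = 0.08 * width_ascans),
                           speckle_noise_sd = 0.1,
                           edge_softness_px = 0.8,
                           seed = 1L) {
  check_scalar(width_ascans, "width_ascans", 8, Inf, integer = TRUE)
  check_scalar(depth_pixels, "depth_pixels", 8, Inf, integer = TRUE)
  if (is.null(layer_mean_depths))
    layer_mean_depths <- depth_pixels * c(0.23, 0.33, 0.43, 0.53, 0.66, 0.74)
  if (length(layer_mean_depths) != 6L)
    stop_octamb("'layer_mean_depths' must have length 6")
  if (any(diff(layer_mean_depths) <= 0))
    stop_octamb("'layer_mean_depths' must be strictly increasing")
  if (any(layer_mean_depths <= 0) || any(layer_mean_depths >= depth_pixels))
    stop_octamb("'layer_mean_depths' must lie strictly inside (0, depth_pixels)")
  if (length(layer_intensities) != 7L ||
      any(layer_intensities < 0) || any(layer_intensities > 1))
    stop_octamb("'layer_intensities' must be 7 values in [0, 1]")
  check_scalar(boundary_waviness_amplitude, "boundary_waviness_amplitude", 0, Inf)
  check_scalar(speckle_noise_sd, "speckle_noise_sd", 0, Inf)
  check_scalar(edge_softness_px, "edge_softness_px", 1e-3, Inf)
  if (is.null(foveal_pit))
    foveal_pit <- list(center_frac = 0.5, depth_px = 0, halfwidth_ascans = 1)
  stopifnot(is.list(foveal_pit))
  check_scalar(foveal_pit$center_frac, "foveal_pit$center_frac", 0, 1)
  check_scalar(foveal_pit$depth_px, "foveal_pit$depth_px", 0, Inf)
  check_scalar(foveal_pit$halfwidth_ascans, "foveal_pit$halfwidth_ascans",
               1e-6, Inf)
  structure(list(
    width_ascans = as.integer(width_ascans),
    depth_pixels = as.integer(depth_pixels),
    n_boundaries = 6L,
    layer_mean_depths = as.numeric(layer_mean_depths),
    layer_intensities = as.numeric(layer_intensities),
    boundary_waviness_amplitude = boundary_waviness_amplitude,
    foveal_pit = foveal_pit,
    speckle_noise_sd = speckle_noise_sd,
    edge_softness_px = edge_softness_px,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Specify a focal lesion to inject into a phantom B-scan
#'
#' A lesion perturbs one or more boundary surfaces inside a compact lateral
#' window: it can displace them (`amplitude`, in pixels, for the displacement
#' kinds), reduce the local reflectivity step across them (`amplitude` as a
#' contrast fraction in `[0, 1]` for `EZ_LOSS`), and/or blur the boundary edge
#' (`blur_sd`, pixels added to the local edge softness). The lateral weight is
#' a raised-cosine bump supported exactly on
#' `|x - lateral_center| <= lateral_halfwidth`, so the phantom is untouched
#' outside that window. A boundary counts as abnormal (its label is set) iff
#' some lesion targets it with `amplitude > 0` or `blur_sd > 0`.
#'
#' @param kind One of `names(lesion_kinds())`.
#' @param lateral_center Centre A-scan index.
#' @param lateral_halfwidth Support half-width in A-scans.
#' @param amplitude Displacement in pixels (contrast fraction in `[0,1]` for
#'   `EZ_LOSS`); must be `>= 0`.
#' @param blur_sd Local boundary-edge blur in pixels, `>= 0`.
#' @param target_boundaries Boundary indices to perturb; defaults to the full
#'   allowed set for `kind` and must be a subset of it.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(kind, lateral_center, lateral_halfwidth,
                        amplitude = 0, blur_sd = 0,
                        target_boundaries = NULL) {
  kinds <- lesion_kinds()
  if (!kind %in% names(kinds))
    stop_octamb("unknown lesion kind '%s' (known: %s)", kind,
                paste(names(kinds), collapse = ", "))
  allowed <- kinds[[kind]]
  if (is.null(target_boundaries)) target_boundaries <- allowed
  target_boundaries <- as.integer(target_boundaries)
  if (!all(target_boundaries %in% allowed))
    stop_octamb("lesion kind '%s' may only target boundaries {%s}", kind,
                paste(allowed, collapse = ","))
  check_scalar(lateral_center, "lateral_center", 1, Inf)
  check_scalar(lateral_halfwidth, "lateral_halfwidth", 1, Inf)
  check_scalar(amplitude, "amplitude", 0, Inf)
  if (kind == "EZ_LOSS") check_scalar(amplitude, "amplitude", 0, 1)
  check_scalar(blur_sd, "blur_sd", 0, Inf)
  structure(list(kind = kind,
                 target_boundaries = target_boundaries,
                 lateral_center = lateral_center,
                 lateral_halfwidth = lateral_halfwidth,
                 amplitude = amplitude,
                 blur_sd = blur_sd),
            class = "lesion_spec")
}

# Raised-cosine lateral weight with compact support
# |x - center| <= halfwidth. Returns a length-W vector.
lesion_bump <- function(width, center, halfwidth) {
  u <- (seq_len(width) - center) / halfwidth
  w <- numeric(width)
  inside <- abs(u) < 1
  w[inside] <- cos(pi * u[inside] / 2)^2
  w
}

# Accumulate the effect of one lesion onto the perturbation fields.
# disp/blur: 6 x W additive fields; contrast: 6 x W multiplicative field.
apply_lesion <- function(lesion, fields, width) {
  if (lesion$lateral_center < 1 || lesion$lateral_center > width)
    stop_octamb("lesion lateral_center %s outside image width %d",
                lesion$lateral_center, width)
  b <- lesion_bump(width, lesion$lateral_center, lesion$lateral_halfwidth)
  u <- (seq_len(width) - lesion$lateral_center) / lesion$lateral_halfwidth
  amp <- lesion$amplitude
  tb <- lesion$target_boundaries
  switch(lesion$kind,
    ERM = {
      # irregular upward wrinkling of the ILM
      fields$disp[1L, ] <- fields$disp[1L, ] - amp * b * (0.7 + 0.3 * cos(6 * pi * u))
    },
    EDEMA = {
      # fluid spreads the inner-retinal boundaries apart and darkens the gap
      if (3L %in% tb) fields$disp[3L, ] <- fields$disp[3L, ] - 0.4 * amp * b
      if (4L %in% tb) fields$disp[4L, ] <- fields$disp[4L, ] + 0.6 * amp * b
      fields$contrast[4L, ] <- fields$contrast[4L, ] * (1 - 0.3 * b)
    },
    DRUSEN_PED = {
      # dome-shaped elevation of the RPE/BM, dragging the EZ with it
      if (6L %in% tb) fields$disp[6L, ] <- fields$disp[6L, ] - amp * b
      if (5L %in% tb) fields$disp[5L, ] <- fields$disp[5L, ] - 0.7 * amp * b
    },
    EZ_LOSS = {
      # local attenuation / blur of the ellipsoid-zone step
      fields$contrast[5L, ] <- fields$contrast[5L, ] * (1 - amp * b)
    },
    OPL_DISTORTION = {
      fields$disp[4L, ] <- fields$disp[4L, ] + amp * b * sin(3 * pi * u)
    },
    SRD = {
      # neurosensory lift-off: EZ rises, the EZ..RPE step washes out (fluid)
      if (5L %in% tb) fields$disp[5L, ] <- fields$disp[5L, ] - amp * b
      if (6L %in% tb)
        fields$contrast[6L, ] <- fields$contrast[6L, ] *
          (1 - 0.5 * min(amp / 10, 1) * b)
    }
  )
  for (l in tb) fields$blur[l, ] <- fields$blur[l, ] + lesion$blur_sd * b
  fields
}

#' Generate one synthetic B-scan
#'
#' Renders a layered cross-section from a [phantom_config()]: smooth random
#' boundary undulations, a foveal pit indenting the inner boundaries, optional
#' lesions, logistic band transitions and multiplicative speckle. Deterministic
#' given `(config, lesions, seed)`; lesions draw no randomness, so columns
#' outside every lesion window are bit-identical to the lesion-free render of
#' the same seed.
#'
#' @param config A [phantom_config()].
#' @param lesions A list of [lesion_spec()] objects (or a single one).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `bscan_sample`: list with `image` (depth x width matrix in
#'   `[0, 1]`), `truth_boundaries` (6 x width real depths), `layer_labels`
#'   (logical 6), `global_label`, `config`, `lesions`.
#' @export
generate_bscan <- function(config, lesions = list(), seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  for (le in lesions) stopifnot(inherits(le, "lesion_spec"))
  W <- config$width_ascans
  H <- config$depth_pixels
  x <- seq_len(W)

  # waviness capped at 40% of the adjacent mean gaps so that independent
  # undulations can never make neighbouring boundaries cross
  md <- config$layer_mean_depths
  gaps <- c(md[1L], diff(md), H - md[6L])
  amp_l <- pmin(config$boundary_waviness_amplitude,
                0.4 * pmin(gaps[1:6], gaps[2:7]))
  with_seed(seed, {
    # smooth random undulation: 3 low-frequency sinusoids per boundary
    curves <- matrix(0, 6L, W)
    for (l in 1:6) {
      a <- runif(3); a <- a / sum(a)
      f <- runif(3, 0.5, 2.5)
      ph <- runif(3, 0, 2 * pi)
      wav <- amp_l[l] * colSums(a * sin(outer(2 * pi * f, (x - 1) / W) + ph))
      curves[l, ] <- md[l] + wav
    }
    noise <- matrix(rnorm(H * W), H, W)
  })

  # foveal pit: boundaries 1..3 converge toward the OPL/ONL surface
  pit <- config$foveal_pit
  if (pit$depth_px > 0) {
    cx <- pit$center_frac * (W - 1) + 1
    g <- exp(-0.5 * ((x - cx) / pit$halfwidth_ascans)^2)
    # contract toward the (wavy) OPL/ONL curve: preserves ordering for any
    # contraction fraction < 1
    frac <- min(pit$depth_px / (md[4L] - md[1L]), 0.95)
    for (l in 1:3)
      curves[l, ] <- curves[l, ] + frac * (curves[4L, ] - curves[l, ]) * g
  }

  fields <- list(disp = matrix(0, 6L, W),
                 blur = matrix(0, 6L, W),
                 contrast = matrix(1, 6L, W))
  for (le in lesions) fields <- apply_lesion(le, fields, W)

  truth <- curves + fields$disp
  d <- apply(truth, 2L, diff)
  if (any(d <= 1e-6)) {
    bad <- which(d <= 1e-6, arr.ind = TRUE)[1L, ]
    stop_octamb(paste0("boundaries %d and %d cross at A-scan %d ",
                       "(lesion displacement too large?)"),
                bad[1L], bad[1L] + 1L, bad[2L])
  }
  if (any(truth < 1) || any(truth > H))
    stop_octamb("boundary depths pushed outside the image frame")

  # render: seven bands joined by logistic transitions at each boundary
  ints <- config$layer_intensities
  z <- matrix(seq_len(H), H, W)
  img <- matrix(ints[1L], H, W)
  for (l in 1:6) {
    wdt <- config$edge_softness_px + fields$blur[l, ]
    step <- (ints[l + 1L] - ints[l]) * fields$contrast[l, ]
    s <- stats::plogis((z - matrix(truth[l, ], H, W, byrow = TRUE)) /
                         matrix(wdt, H, W, byrow = TRUE))
    img <- img + s * matrix(step, H, W, byrow = TRUE)
  }
  if (config$speckle_noise_sd > 0)
    img <- img * (1 + config$speckle_noise_sd * noise)
  img <- clamp(img, 0, 1)

  labels <- vapply(1:6, function(l) {
    any(vapply(lesions, function(le)
      l %in% le$target_boundaries && (le$amplitude > 0 || le$blur_sd > 0),
      logical(1L)))
  }, logical(1L))

  structure(list(image = img,
                 truth_boundaries = truth,
                 layer_labels = labels,
                 global_label = any(labels),
                 config = config,
                 lesions = lesions,
                 seed = as.integer(seed)),
            class = "bscan_sample")
}

#' Generate an ordered volume of B-scans
#'
#' Per-slice seeds are derived deterministically from the master seed, and a
#' `lesion_field` maps slice indices to lesion lists so a lesion can span
#' contiguous slices and form an en-face blob (see [lesion_blob()]).
#'
#' @param config A [phantom_config()] shared by all slices.
#' @param n_slices Number of slices, `>= 1`.
#' @param lesion_field Either a list of length `n_slices` (element `s` holds
#'   the lesions of slice `s`, `NULL` for none) or a named list keyed by slice
#'   index.
#' @param seed Master seed.
#' @return A `volume_sample`: list with `slices` (list of `bscan_sample`),
#'   `config`, `n_slices`.
#' @export
generate_volume <- function(config, n_slices, lesion_field = list(),
                            seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  check_scalar(n_slices, "n_slices", 1, Inf, integer = TRUE)
  slice_lesions <- vector("list", n_slices)
  if (length(lesion_field)) {
    if (!is.null(names(lesion_field)) && any(nzchar(names(lesion_field)))) {
      for (nm in names(lesion_field)) {
        s <- as.integer(nm)
        if (is.na(s) || s < 1L || s > n_slices)
          stop_octamb("lesion_field slice index '%s' outside 1..%d", nm, n_slices)
        slice_lesions[[s]] <- lesion_field[[nm]]
      }
    } else {
      if (length(lesion_field) > n_slices)
        stop_octamb("lesion_field longer than n_slices")
      slice_lesions[seq_along(lesion_field)] <- lesion_field
    }
  }
  seeds <- derive_seeds(seed, n_slices)
  slices <- lapply(seq_len(n_slices), function(s) {
    les <- slice_lesions[[s]]
    if (is.null(les)) les <- list()
    generate_bscan(config, les, seed = seeds[s])
  })
  structure(list(slices = slices, config = config,
                 n_slices = as.integer(n_slices), seed = as.integer(seed)),
            class = "volume_sample")
}

#' Build a lesion field forming a contiguous en-face blob
#'
#' Replicates a template lesion over slices `slice_center +/-
#' slice_halfwidth`, scaling its amplitude and blur by a raised-cosine profile
#' along the slice axis so the lesion fades in and out smoothly.
#'
#' @param template A [lesion_spec()].
#' @param n_slices Volume size.
#' @param slice_center,slice_halfwidth Blob centre and half-extent in slices.
#' @return A list usable as `lesion_field` in [generate_volume()].
#' @export
lesion_blob <- function(template, n_slices, slice_center, slice_halfwidth) {
  stopifnot(inherits(template, "lesion_spec"))
  w <- lesion_bump(n_slices, slice_center, slice_halfwidth)
  field <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    if (w[s] <= 0) next
    le <- template
    le$amplitude <- template$amplitude * w[s]
    le$blur_sd <- template$blur_sd * w[s]
    field[[s]] <- list(le)
  }
  field
}

#' Generate a labelled cohort of normal and diseased B-scans
#'
#' Diseased samples receive 1-3 lesions drawn from `lesion_menu` templates
#' with randomised lateral centre (20-80% of width), half-width (0.8-1.2x the
#' template) and amplitude/blur (0.6-1.4x the template). A draw whose
#' displacement would force boundaries to cross is redrawn (up to 20 times).
#'
#' @param n_normal,n_diseased Cohort sizes, `>= 0`.
#' @param lesion_menu List of [lesion_spec()] templates; required when
#'   `n_diseased > 0`.
#' @param config A [phantom_config()].
#' @param seed Master seed.
#' @return List of `bscan_sample` (normals first), each with an `id` field.
#' @export
generate_cohort <- function(n_normal, n_diseased, lesion_menu = list(),
                            config = phantom_config(), seed = config$seed) {
  check_scalar(n_normal, "n_normal", 0, Inf, integer = TRUE)
  check_scalar(n_diseased, "n_diseased", 0, Inf, integer = TRUE)
  if (n_diseased > 0 && length(lesion_menu) == 0L)
    stop_octamb("n_diseased > 0 requires a non-empty lesion_menu")
  for (le in lesion_menu) stopifnot(inherits(le, "lesion_spec"))
  n <- n_normal + n_diseased
  seeds <- derive_seeds(seed, max(n, 1L))
  W <- config$width_ascans
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    diseased <- i > n_normal
    smp <- with_seed(seeds[i], {
      render_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      if (!diseased) {
        generate_bscan(config, list(), seed = render_seed)
      } else {
        out <- NULL
        for (attempt in 1:20) {
          k <- sample.int(3L, 1L)
          idx <- sample.int(length(lesion_menu), k, replace = TRUE)
          les <- lapply(idx, function(j) {
            tm <- lesion_menu[[j]]
            amp <- tm$amplitude * stats::runif(1, 0.6, 1.4)
            if (tm$kind == "EZ_LOSS") amp <- min(amp, 1)
            lesion_spec(tm$kind,
                        lateral_center = stats::runif(1, 0.2, 0.8) * W,
                        lateral_halfwidth =
                          tm$lateral_halfwidth * stats::runif(1, 0.8, 1.2),
                        amplitude = amp,
                        blur_sd = tm$blur_sd * stats::runif(1, 0.6, 1.4),
                        target_boundaries = tm$target_boundaries)
          })
          out <- tryCatch(generate_bscan(config, les, seed = render_seed),
                          error = function(e) NULL)
          if (!is.null(out)) break
        }
        if (is.null(out))
          stop_octamb("could not place lesions without boundary crossing")
        out
      }
    })
    smp$id <- sprintf("%s_%03d", if (diseased) "dis" else "nrm", i)
    samples[[i]] <- smp
  }
  samples
}
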