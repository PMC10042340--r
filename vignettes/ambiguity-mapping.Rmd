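---
title: "Quantifying and mapping boundary-detection ambiguity in retinal OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and mapping boundary-detection ambiguity in retinal OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octamb)
```

## The idea

Automatic segmentation of retinal layer boundaries in OCT B-scans is routine,
but the *confidence* of the segmentation carries clinical information of its
own. Where the retina is healthy, a boundary-detection network concentrates
its probability mass on a single depth per A-scan; where tissue is disrupted
— edema, drusen, ellipsoid-zone loss — the boundary becomes genuinely
ambiguous and the predicted depth distribution spreads out. `octamb`
quantifies that spread and turns it into an anomaly-localization signal,
without ever training on lesion annotations.

For A-scan $x$ and boundary layer $l$, the network emits a distribution
$p_{x,z,l}$ over depth $z$ (a vertical softmax, so $\sum_z p_{x,z,l} = 1$).
Its Shannon entropy

$$ e_{x,l} \;=\; -\sum_z p_{x,z,l} \, \log p_{x,z,l} $$

is zero when detection is certain and $\ln Z$ (with $Z$ depth bins) when it
is maximally ambiguous. Averaging $e_{x,l}$ over the A-scans of an image
gives a per-layer **ambiguity index**; the mean of the six per-layer indices
is the overall index. Arranged over the slices of a volume, the per-A-scan
entropies of one layer form an en-face **ambiguity map** whose hot spots
localize abnormal tissue.

The six boundaries, in fixed anatomical order, are ILM, NFL/GCL, IPL/INL,
OPL/ONL, EZ and RPE/BM.

## The segmentation network

The boundary detector (`model_config()`, `build_model()`, `train_model()`)
is an encoder–decoder with skip connections:

* every convolution is **7×1 (vertical)** — the features of interest are
  horizontal edges, i.e. vertical brightness transitions along an A-scan;
* lateral context enters through a 2×2 average-pooling pyramid
  (`n_levels = 3` by default);
* the bottleneck is a **multiple-dilated-convolution (MDC) block**: parallel
  7×1 convolutions with dilations {1, 2, 4, 8}, summed, which widens the
  vertical receptive field enough to see an entire retinal cross-section at
  the coarsest scale;
* the head is a per-boundary **softmax along the depth axis**, giving one
  depth distribution per (A-scan, boundary).

Training (`train_config()`) follows the stated recipe: each annotated
B-scan is cut laterally into four tiles, each tile is augmented
(left–right flip, 0.9–1.1× scaling, ±15° rotation), targets are one-hot
depths per (A-scan, boundary), the loss is cross-entropy along depth, and
the optimizer is AMSGrad (learning rate 1e-3, batch size 5). Boundary
positions at inference are the per-A-scan argmax, ties resolving to the
smallest depth.

Implementation note: with vertical-only kernels a convolution factorizes
into one channel-mixing matrix product (BLAS) plus a cheap row-shifted
accumulation (a small C++ kernel), so the whole network trains in minutes
on one CPU core without any deep-learning framework. Minibatches are formed
by concatenating tiles along the A-scan axis; because tile widths are
divisible by $2^{\text{levels}-1}$, pooling windows never straddle a tile
border and the concatenation is exactly equivalent to independent forward
passes.

### Parameters that matter

| parameter | default | why |
|---|---|---|
| `base_channels` | 8 | smallest width that recovers phantom boundaries to well under 2 px MAE; one minibatch ≈ 0.6 s on one CPU core. Double it for harder data. |
| `n_levels` | 3 | /4 lateral downsampling; deeper pyramids buy little on 128-px-deep frames |
| `mdc_dilations` | 1, 2, 4, 8 | max dilation × kernel span ≈ the full depth at the coarsest scale |
| `learning_rate` | 1e-3 | the optimizer's customary default; stable for all tested seeds |
| `epochs` | 10 | the default recipe (~100 phantoms) converges in 5–8 |

## The synthetic phantom

The clinical images the method was designed for are not redistributable, so
`octamb` ships a first-class phantom generator (`phantom_config()`,
`generate_bscan()`, `generate_volume()`, `generate_cohort()`). A phantom is
seven reflectivity bands joined by logistic intensity transitions at six
boundary curves:

* smooth random undulation per boundary (three low-frequency sinusoids;
  amplitude capped at 40 % of the adjacent mean gaps so boundaries can
  never cross by construction);
* a **foveal pit** that contracts the inner boundaries (ILM … IPL/INL)
  toward the OPL/ONL curve near the image centre — included by default
  because the pinched inner retina inflates entropy at the fovea even in
  healthy eyes, and tests must face that confound;
* multiplicative Gaussian speckle, clipped to [0, 1] (sd 0.1 by default;
  the source material never characterizes its noise, so this is a single
  fixed choice, not a tuning knob);
* optional **lesions** (`lesion_spec()`): ERM, EDEMA, DRUSEN_PED, EZ_LOSS,
  OPL_DISTORTION, SRD. Each perturbs only its allowed boundaries inside a
  compact raised-cosine lateral window — displacing them, blurring their
  edge, and/or reducing the local reflectivity step. A boundary is labelled
  abnormal iff a lesion displaces or blurs it, a programmatic stand-in for
  expert adjudication.

The default frame is 128 × 256 (depth × width), a desk-scale surrogate for
a 512 × 1024 clinical export; the generator is resolution-agnostic.

What the phantom does **not** emulate: physically realistic speckle
statistics, motion artifacts, vessel shadows, choroidal texture, and the
full morphological diversity of real lesions (the lesion shapes are
plausible caricatures). A green test on the phantom therefore establishes
that the machinery behaves as specified and that the entropy signal
separates intact from disrupted anatomy of the kinds injected — not
clinical performance.

## Ambiguity indices

`ascan_entropy()` uses the natural logarithm by default: ambiguity indices
reported in clinical use of this statistic sit in the low units against a
512-bin ceiling (ln 512 ≈ 6.24), which is only consistent with nats; base 2
is available via `log_base`. `0·log 0` is taken as 0, with
probabilities clamped at 1e-12 inside the logarithm only.

The overall index is the mean of the six per-layer means, which equals the
pooled mean over all (A-scan, layer) cells when no mask is applied — the
two readings of the published "All" row coincide here. An optional A-scan
mask (`fovea_mask()`) excludes a centred window from the averages; it is
**off** by default since the original handling of the foveal confound is
unstated.

## En-face maps

`ambiguity_map()` runs a fixed pipeline per layer:
raw slice×A-scan grid → isotropic Gaussian smoothing (σ = 1 grid units,
kernel truncated at 4σ, reflect padding) → min–max normalization to [0, 1]
(a constant map normalizes to all zeros) → classical jet colorization
(piecewise-linear anchors 0→(0,0,0.5), 0.125→(0,0,1), 0.375→(0,1,1),
0.625→(1,1,0), 0.875→(1,0,0), 1→(0.5,0,0)).

Choices the source leaves open, fixed here: smoothing is 2-D isotropic on
the en-face grid even though slice spacing differs physically from A-scan
spacing; normalization is per layer per volume (each map independently),
with the min/max recorded in the map object and the export manifest so raw
entropies remain recoverable; truncation radius and padding mode are the
conventional ones stated above.

## Evaluation

`mann_whitney_u()` implements the rank-sum U with midrank ties and a
two-sided tie-corrected normal approximation with continuity correction
(the original analysis names only its statistics package, not its options).
`roc_curve()` sweeps unique scores with higher-index ⇒ diseased
orientation and integrates trapezoidally; `auc_equivalence_check()` asserts
the exact duality AUC = U′/(n₁n₂) with ties counted one half — the two
statistics are kept as independent code paths precisely so this identity is
a meaningful cross-check. `run_cohort_study()` ties everything together:
per-layer indices against per-layer labels, the overall index against the
global label.

On the default synthetic cohort (60 normal + 60 diseased, EZ-loss and edema
lesions) the acceptance suite verifies the qualitative pattern of the
published result: diseased mean overall index above normal (Mann-Whitney
p < 0.01), AUC ≥ 0.8 at the lesioned EZ layer, and never-lesioned layers
nearer chance. Clinically reported values of these statistics are not
reproduction targets — the underlying dataset is not deposited — and no
synthetic quantity is tuned toward them.

## Numerical and degenerate-input rules

* probability volumes are validated on entry: entries ≥ 0, per-(A-scan,
  layer) sums within 1e-5 of 1;
* argmax ties break to the smallest depth index;
* min–max normalization of a constant map returns zeros;
* a lesion whose displacement would force boundaries to cross is rejected
  with a diagnostic rather than silently clipped;
* training aborts on non-finite loss;
* every stochastic entry point takes an explicit seed, runs under a
  temporary RNG state, and restores the caller's stream; volumes and
  cohorts derive per-item seeds from the master seed, so outputs are
  bit-reproducible in single-threaded mode.

## Known limitations

* The architecture's published internals (channel widths, depth, exact
  dilation rates) are unspecified; this package's defaults are the smallest
  configuration that honours the named components and trains on a CPU.
  Results at other scales may differ quantitatively.
* "Divided vertically into 4 segments" is read as lateral tiling (cuts are
  vertical lines); a depth-wise reading would conflict with the per-A-scan
  softmax over the full depth.
* Entropy from a single softmax is a calibration-dependent uncertainty
  measure; alternative estimators (MC-dropout, depth variance) are out of
  scope by design.
* TIFF input and vendor OCT formats are not supported; images travel as
  BMP or PNG.
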