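# octamb — ambiguity quantification for retinal layer boundaries in OCT

`octamb` is an R package for clinicians' "wayfinding" analysis of optical
coherence tomography (OCT): instead of emitting a diagnosis, it points at
the retinal locations where a segmentation model finds the anatomy
*ambiguous* — which is where lesions tend to be.

A compact encoder–decoder network (7×1 vertical convolutions, skip
connections, a multiple-dilated-convolution bottleneck) outputs, for every
A-scan `x` and each of six retinal boundaries `l` (ILM, NFL/GCL, IPL/INL,
OPL/ONL, EZ, RPE/BM), a probability distribution `p[x, z, l]` over depth
`z` via a softmax along the A-scan. The core statistic is the Shannon
entropy of that distribution,

    e[x, l] = − Σ_z p[x, z, l] · log p[x, z, l]        (nats)

averaged over A-scans into a per-layer **ambiguity index** (Amb-I) and
over layers into an overall index. Across the slices of a volume, the
entropies of one layer form an en-face **ambiguity map** (Gaussian σ = 1
smoothing → min–max normalization → jet colormap) whose hot spots localize
abnormal tissue. Discrimination of normal vs diseased images is evaluated
with Mann-Whitney U tests and ROC/AUC, per layer and overall.

Because the clinical dataset this method was developed on is not
redistributable, the package includes a first-class synthetic phantom:
layered retinal cross-sections with known boundary geometry, a foveal pit,
speckle noise, and injectable labelled lesions (ERM, edema, drusen/PED,
EZ loss, OPL distortion, serous detachment). Everything — training,
evaluation, acceptance tests — runs end-to-end on generated data on one
CPU core.

## Worked example

```r
library(octamb)

# 1. a labelled synthetic cohort (60 normal / 60 diseased)
pc     <- phantom_config()                     # 128 x 256 B-scans
menu   <- list(
  lesion_spec("EZ_LOSS", lateral_center = 128, lateral_halfwidth = 32,
              amplitude = 0.7, blur_sd = 3.84),
  lesion_spec("EDEMA",   lateral_center = 128, lateral_halfwidth = 32,
              amplitude = 7.68, blur_sd = 1.28))
train  <- lapply(1:100, function(i) generate_bscan(pc, list(), seed = i))
cohort <- generate_cohort(60, 60, menu, pc, seed = 20240101)

# 2. train the boundary detector (~5 min on one core)
model <- train_model(build_model(model_config()), train,
                     train_config(epochs = 6, seed = 2024))

# 3. ambiguity of one image
ep <- ascan_entropy(predict_probabilities(model, cohort[[1]]))
overall_ambiguity_index(ep)

# 4. cohort discrimination
study <- run_cohort_study(cohort, model)
study$overall$roc$auc
study$overall$mwu$p_value
```

Output of the run above (seeds as shown):

```
loss history:                  2.0801 1.1425 0.8326 0.7317 0.6960 0.6565
per-boundary MAE (50 held-out): 0.284 0.361 0.511 0.282 0.261 0.268  px
overall Amb-I: normal 0.635 ± 0.013, diseased 0.737 ± 0.063 (nats)
overall AUC 0.994, Mann-Whitney U 3578, p ≈ 1e-20
per-layer AUC vs own label:    IPL/INL 0.985, OPL/ONL 0.876, EZ 1.000
```

Reading: the trained model recovers clean-phantom boundaries to ~0.3 px,
diseased phantoms carry clearly higher ambiguity, and the layers the
lesions actually disrupt are the ones whose Amb-I discriminates — the
qualitative behaviour the method is built on. (Absolute values depend on
model scale and phantom contrast; they are not clinical numbers.)

En-face maps for a volume:

```r
vol      <- generate_volume(pc, n_slices = 12,
                            lesion_field = lesion_blob(menu[[1]], 12, 6, 3),
                            seed = 7)
profiles <- lapply(vol$slices, function(s)
                   ascan_entropy(predict_probabilities(model, s)))
am <- ambiguity_map(profiles, layer = 5)   # EZ
write_bscan_image(am$rgb, "ez_map.bmp")    # hot spot at the lesion blob
```

## Command line

The installed script `inst/cli/octamb` (or `octamb_cli()` in R) chains the
pipeline: `simulate`, `train`, `segment`, `ambiguity`, `map`, `evaluate` —
e.g.

```sh
octamb simulate --out data/ --n-normal 20 --n-diseased 20 --seed 1
octamb train    --data data/ --epochs 6 --seed 1 --out model.rds
octamb evaluate --data data/ --ckpt model.rds --out report/
```

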