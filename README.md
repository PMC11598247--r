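# aernet

Simultaneous **nuclei instance segmentation and classification** for H&E
histology patches, built around an attention-enhanced residual refinement
network and its watershed post-processing — implemented end to end in R,
with the tensor machinery (tape autodiff, im2col/BLAS convolutions,
attention gates, Adam) written in the package and compiled kernels under
`src/`.

Histology patches pose two coupled problems: nuclei aggregate into
touching clusters whose boundaries must be resolved into *instances*, and
nucleus types are heavily imbalanced, so rare classes drown during
training. The pipeline here addresses both:

* **Network** — a shared residual encoder whose four stages each end in
  channel + spatial attention (CBAM-style), feeding three structurally
  identical decoder branches: nuclear probability, horizontal–vertical
  (HV) distance regression, and classification. Each branch carries a
  compact encoder–decoder **refinement head** emitting a residual
  correction: `refined = coarse + head(coarse)`. Both predictions are
  supervised: `L = α·L1 + L2`, with per-branch terms
  `β3·CE + β4·Dice` (probability), `β1·MSE + β2·MSGE` (distance; MSGE
  compares finite-difference gradients over nucleus pixels), and
  `β5·CE + β6·GDL` (classification). The **generalized Dice loss** weights
  class *l* by `w_l = 1/(Σ_n r_ln)²`, up-weighting rare nucleus types.
* **HV encoding** — each nucleus pixel's signed offset to its instance's
  center of mass, normalized per instance and per side to [−1, 1];
  gradients of these maps peak between touching nuclei.
* **Post-processing** — Sobel boundary energy
  `Sm = max(Hx(px), Hy(py))` (responses rescaled so inter-nuclear
  transitions map to 1), markers `M = σ(τ(q,h) − τ(Sm,k))`, energy
  `E = 1 − τ(Sm,k)·τ(q,h)`, and a marker-controlled watershed confined to
  `τ(q,h)`, followed by majority-vote typing per instance.
* **Metrics** — unique IoU > 0.5 matching, Panoptic Quality
  `PQ = DQ × SQ`, detection F-score `Fd`, and per-type classification
  F-score `Ft`.
* **Synthetic scenes** — a seeded generator of shaded elliptical nuclei
  with controllable counts, sizes, touching clusters and skewed class
  frequencies, so every stage is testable without external data.

## Worked example

Generate a scene, encode the distance targets, and run the watershed
round-trip on the ideal maps:

```r
library(aernet)

sc <- generate_scene(scene_spec(128, 128, n_nuclei = 8, seed = 42))
hv <- compute_hv_map(sc$instances)          # H x W x 2, values in [-1, 1]
q  <- (sc$instances > 0) * 1                # ideal foreground probability

pred <- watershed_instances(q, hv, postproc_config())
m    <- match_instances(sc$instances, pred)
pq   <- panoptic_quality(m)
sprintf("recovered %d/%d instances, DQ %.3f SQ %.3f PQ %.3f Fd %.3f",
        nrow(m$tp_pairs), m$n_gt, pq$DQ, pq$SQ, pq$PQ, detection_f1(m))
#> "recovered 8/8 instances, DQ 1.000 SQ 1.000 PQ 1.000 Fd 1.000"
```

With ideal inputs every non-touching nucleus is recovered pixel-perfectly
(each foreground component holds one marker, so the flood refills it
exactly); touching clusters are split along the HV-gradient ridge. A
desk-scale model can be trained and applied with:

```r
data <- make_synthetic_dataset(64, scene_spec(64, 64, n_nuclei = 6,
                                              radius_range = c(4, 8)))
cfg <- model_config(residual_units_per_stage = c(1, 1, 1, 1),
                    base_width = 4, growth = 4, arrm_width = 8,
                    attention_reduction = 4, arrm_pool_stages = 4)
fit <- train_model(cfg, data, stages = 1, epochs_per_stage = 8,
                   batch_size = 4, lr = 1e-3, drop_after = 8)
res <- infer(fit$model, list(data[[1]]$image))   # instances + types + maps
```

A thin command-line front end over the same functions ships in
`inst/cli/aernet.R` with verbs `fixtures`, `train`, `infer`, `postproc`
and `eval`, e.g.

```sh
Rscript inst/cli/aernet.R postproc --prob prob.npy --hv hv.npy \
        --out inst.png --h 0.5 --k 0.4
```

Label maps travel as 16-bit PNG or NPY; HV maps as float32 NPY; images as
8-bit PNG.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "aernet",
                               load_package = "installed")'
```

The suite covers the scene generator's invariants, the HV encoding and
its flip symmetry, loss formulas against brute-force oracles, matching
against an optimal-assignment oracle, the watershed round-trip, the
published input/output geometries (270→80, 256→256, 256→164), checkpoint
round-trips, and finite-difference gradient checks through the full
network.

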