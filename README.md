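# ipbalance

Semi-supervised classification of phase-contrast stem-cell colony images
under severe class imbalance, by **iterative pseudo-balancing (IPB)**: a
student–teacher meta-pseudo-label loop whose pseudo-labels drive
per-epoch multinomial resampling with inverse-proportion class weights,
so the student always trains on a balanced stream of colony patches.

## Who this is for

Labs doing non-invasive live-cell imaging rarely have large, balanced,
fully annotated datasets: colony phenotypes (pluripotent *dense*
colonies, *spread* progenitors, *differentiated* neurons, *debris*)
arise at wildly uneven rates, composite colonies contain several
phenotypes in one image and cannot carry an image-level label, and
expert annotation is expensive. This package implements a training
scheme that needs labels for only a small balanced subset and exploits
the rest — including multi-label composites — through teacher-assigned
pseudo-labels.

## The method

Let `θ_T`, `θ_S` be teacher and student parameters, `x_u` unlabeled and
`x_l` labeled patches. Each epoch:

1. The teacher pseudo-labels one random in-mask patch per unlabeled
   image; soft predictions below a confidence threshold `τ = 0.65` are
   dropped.
2. Kept pseudo-labels give class proportions `p_i`; items of class `c`
   are drawn from a multinomial with replacement with weight
   `w = 1 / (m · p_c)`, so the expected class share of the student's
   stream is `1/m` for every populated class.
3. Student update (cross-entropy against hard pseudo-labels):
   `θ'_S = θ_S − η_S ∇_{θ_S} L_S(θ_T(x_u), θ_S(x_u))`
4. Teacher update along the meta-gradient of the **updated** student's
   labeled loss, optionally plus a confidence-masked weak/strong-view
   consistency term:
   `θ'_T = θ_T − η_T ∇_{θ_T} L_T(x_l, θ'_S(x_l))`

Patches are multi-scale — a 224×224 view paired with its exact 112×112
centre crop (179.2 and 89.6 μm at 0.8 μm/px) feeding two convolutional
streams whose 512-feature vectors are concatenated — or single-scale
128×128 (102.4 μm). Colony foreground comes from a six-step
morphological pipeline (3×3 Gaussian blur → local entropy, disk r=3 →
Otsu → opening, disk r=3 → hole filling → removal of objects under
2000 px). Evaluation reports per-class true positive rate
`TPR = TP/(TP+FN)` and `F1 = 2TP/(2TP+FP+FN)`.

Because the real dataset is available only on request, the package
ships a seeded synthetic generator: four texture-separable colony
classes on a bright background, multi-label composites, and severe
imbalance, with sizes spanning the real extremes (55×85 to 771×1298
px). A scalar texture statistic (mean local 3×3 variance) separates
the four classes by construction, so learning tests are well-posed.

## Worked example

```r
library(ipbalance)

cfg <- default_config()
cfg$outdir <- "demo_run"; cfg$seed <- 31
cfg$data$synthesize <- TRUE
cfg$data$class_counts <- list(dense = 16, spread = 16, diff = 16, debris = 16)
cfg$data$multilabel_count <- 2
cfg$data$size_range <- list(min = c(110, 110), max = c(130, 130))
cfg$split$fractions <- c(0.5, 0.25, 0.25)
cfg$model$arch <- "tiny_test"; cfg$patch$size <- 48
cfg$train$pretrain_epochs <- 40; cfg$train$ipb_epochs <- 20
cfg$train$lambda <- 0
res <- run_experiment(cfg)
res$metrics$confusion
#>       actual
#> pred   [,1] [,2] [,3] [,4]
#>   [1,]    4    0    0    0
#>   [2,]    0    4    0    0
#>   [3,]    0    0    4    0
#>   [4,]    0    0    0    4
round(res$metrics$tpr, 3)
#> [1] 1 1 1 1
```

The confusion matrix counts test-set predictions (rows) against actual
classes (columns; order dense, spread, diff, debris). With 16 images
per class split 50:25:25, each class contributes 4 test images, and the
trained student classifies all 16 correctly. Patch scale matters, which
is the point of the multi-scale input: the same run with 32 px patches
misclassifies the differentiated class, whose sparse dark cell bodies
and thin axon-like strokes are easily missed in a small window.
`demo_run/` contains
the config snapshot, manifest, per-epoch loss/selection traces
(`trace.csv`), the teacher's estimated class proportions per epoch
(`p_trace.csv`, the distribution-tracking diagnostic), metrics and
input hashes.

The scaled-down effectiveness experiment in
`tests/testthat/test-acceptance.R` reproduces the method's headline
contrast: at 30:10:10:1 unlabeled imbalance, the IPB student beats an
otherwise-identical run with balancing disabled on minority-class TPR
in 5/5 paired seeds (e.g. 0.79 vs 0.58 at seed 3).

## Command line

```sh
Rscript inst/cli/ipb.R synth --counts dense=20,spread=50,diff=5,debris=15 \
    --multilabel 5 --out data/ --seed 1
Rscript inst/cli/ipb.R segment --input img.pgm --out-mask mask.pgm --out-rois rois.csv
Rscript inst/cli/ipb.R ipb-train --config cfg.json --outdir run/
Rscript inst/cli/ipb.R ipb-eval --checkpoint run/best_student.rds \
    --manifest data/manifest.csv --out metrics.json
Rscript inst/cli/ipb.R compare --a 0.81,0.84,0.80 --b 0.78,0.80,0.77
```

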