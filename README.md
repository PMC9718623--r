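# grainsight

Identifying cereal grain varieties from single-grain photographs is a
routine quality-control task in rice trading and seed certification, yet
the visual differences between varieties — kernel length, width, aspect
ratio, surface texture — are subtle enough that manual grading is slow and
inconsistent. `grainsight` implements a two-stage image-analysis pipeline
for this problem, aimed at researchers who want a transparent, fully
scripted R implementation of each stage rather than a black box:

1. **Saliency-based segmentation.** Each image is oversegmented into
   superpixels (SLIC-style clustering in CIELAB + position space). On the
   region adjacency graph, background saliency is estimated by manifold
   ranking from border seeds: with affinity
   `w_ij = exp(-||lab_i − lab_j|| / σ_c)` and ranking
   `r = (D − αW)^{-1} y`, the top, left and right border nodes are used in
   turn as queries, the three rankings are multiplied, min-max normalised
   and complemented (`I_b = 1 − norm(I_q · I_u · I_x)`). A diffusion
   compactness term `I_f = 1 − norm(I_v + I_d)` (score-weighted spatial
   variance plus distance to the score-weighted centre) is added, the
   combined map `I_1 = norm(I_b + I_f)` re-ranked on a saliency-augmented
   affinity (`m_ij^{J2} = m_ij^{J1} + exp(-|I_1(i) − I_1(j)|/σ_s)`), and the
   refined map `I_2` is thresholded by Otsu's method into a grain mask; the
   masked image is exported as a CIELAB colour map.
2. **Feature extraction, fusion, selection, classification.** Reference
   layer tables for the DarkNet19 and SqueezeNet backbones are provided
   with exact shape inference (and a deterministic mock extractor for
   weight-free desk-scale work). The two feature views are fused by a
   maximum-correlation rule — near-duplicate columns (`|r| ≥ τ_high`) enter
   once, columns uncorroborated by the other view (`max |r| ≤ τ_low`) are
   dropped — and a compact subset is selected by a butterfly optimization
   algorithm (fragrance `f = c·I^a`, global move
   `P' = P + (rn²·b_p − P)·f`, local move `P' = P + (rn²·P_k − P_l)·f`)
   hybridised with the cross-entropy method (elite-refreshed Bernoulli
   distribution, smoothing `a_{k+1} = α·a⁺ + (1−α)·a_k`). The fitness is
   cross-validated 5-NN error plus a cardinality penalty. A panel of ten
   classifiers (linear/quadratic SVM, weighted and cosine kNN, LDA, five
   ReLU multilayer perceptrons) reports macro recall, precision, F1, FNR
   and accuracy.

A seeded synthetic generator produces grain-like images with ground-truth
masks and labelled feature matrices with planted informative / redundant /
noise columns, so the whole pipeline runs and is tested without any
external download.

## Worked example

```r
library(grainsight)

# ten synthetic grain images, two per variety
grains <- gen_grain_images(n_per_class = 2, n_classes = 5, hw = 128, seed = 7)
res <- segment_image(grains[[1]]$image)
res
#> <segmentation_result> 128x128 px, threshold 0.5, mask area 299 px
mask_iou(res$mask, grains[[1]]$mask)
#> [1] 0.9598662

# the full pipeline on 200 synthetic images (5 classes x 40)
run <- run_pipeline(pipeline_config(seed = 1))
run$manifest[, c("stage", "dims")]
#>   stage     dims
#> 1 synth     200 images 128x128, 5 classes
#> 2 segment   200 masks
#> 3 extract_a 200 x 128
#> 4 extract_b 200 x 128
#> 5 fuse      200 x 222
#> 6 select    200 x 5
#> 7 classify  10 classifiers

dplyr::select(run$metrics, classifier, recall, f1, accuracy)
#>    classifier          recall     f1 accuracy
#>  1 linear_svm              98  98.0        98
#>  2 quadratic_svm          100 100          100
#>  3 weighted_knn           100 100          100
#>  4 cosine_knn              97  97.1        97
#>  5 linear_discriminant     99  99.0        99
#>  6 medium_nn              100 100          100
#>  7 narrow_nn               99  99.0        99
#>  8 wide_nn                100 100          100
#>  9 bilayer_nn             100 100          100
#> 10 trilayer_nn            100 100          100
```

The fusion report shows 256 extracted columns reduced to 222 (34 dropped as
cross-view redundant), and the optimizer then selects 5 columns that
already classify the separable synthetic varieties essentially perfectly —
on such fixtures the cardinality-penalised wrapper collapses to a minimal
zero-error subset, which is the expected optimum of its objective.

A command-line front end with verbs `synth`, `segment`, `extract`, `fuse`,
`select`, `classify` and `run-all` is installed at
`system.file("cli", "grainsight.R", package = "grainsight")`.

## Vignette

`vignettes/grainsight-methods.Rmd` documents the models and the numerical
choices: the ranking operator and its normalisation, the affinity
construction, what the synthetic generator does and does not emulate, the
fusion rules, the BOA/CE hybrid and its fitness, and known limitations.
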