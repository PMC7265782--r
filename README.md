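# tilscope

Whole-slide tumor-infiltrating lymphocyte (TIL) mapping, spatial
statistics, and outcome association — as a tested, reusable R package.

## The problem

The density and spatial arrangement of lymphocytes inside tumor tissue
carry prognostic and treatment-response information, but routine
assessment is manual and semi-quantitative. tilscope implements a fully
automatic pipeline for H&E-stained slide rasters:

1. **Field of view** — downsample 16:1, cluster pixels in CIELAB space by
   K-means (k = 3), call the upper-left-corner cluster background, and
   take the bounding box of the largest connected tissue component back at
   full resolution.
2. **Lymphocyte segmentation** — a five-stage residual encoder / five
   upsampling-block decoder network (2×2 transposed conv + skip
   concatenation + two 3×3 convs per block), trained on center-annotated
   patches whose points are dilated to 32-px discs (a lymphocyte nucleus
   is ~8 µm ≈ 32 px at 40×), with a *cascade* refinement loop in which
   predicted masks on new patch groups are corrected (here: by a
   programmatic refiner standing in for expert review) and fed back as
   labels.
3. **TIL map and score** — tile the FOV into 200×200 patches, drop
   patches with >80% background, and score the slide as the ratio of sums

   ```
   TIL% = Σᵢ Lᵢ / Σᵢ Tᵢ
   ```

   over the K valid patches, where Lᵢ = predicted lymphocyte pixels ∩
   tissue and Tᵢ = tissue pixels in patch i.
4. **Spatial features** — TIL patches (Lᵢ/Tᵢ ≥ 0.1) become points,
   clustered by affinity propagation (median preference, damping 0.9);
   42 internal cluster-validity indices (Gamma, G+, Tau, Banfeld–Raftery,
   the generalized Dunn family GDI11–GDI53, PBM, silhouette, …) plus TIL%
   form the slide's 43-value feature vector.
5. **Association machinery** — Spearman screening of expression against
   the TIL score (|ρ| > 0.3), Wilcoxon rank-sum tests against mutation
   status (≥10 carriers), log-rank survival comparison with a 20th–80th
   percentile cutoff scan, K-means risk groups, and Lasso-Cox feature
   selection — per ER+/ER−/triple-negative subtype.

A synthetic-data module generates slides, annotated patches and cohort
tables with known ground truth (planted correlations, mutation shifts,
hazard ratios), so the entire pipeline is exercisable and testable with no
external downloads. The segmentation network is implemented from scratch
in RcppArmadillo (no deep-learning runtime required); its gradients are
verified against finite differences in the test suite.

## Worked example

```r
library(tilscope)

# a synthetic slide with known ground truth (1600x1600 at nominal 40x)
spec <- slide_spec(seed = 5)
gen  <- generate_slide(spec)

# train a desk-scale model on annotated 200x200 patches (about 25 s)
aps <- generate_annotated_patches(60, spec, seed = 5)
sp  <- split_patches(aps, 0.8, seed = 5)
ck  <- train_model(seg_model_config(epochs = 8, seed = 5), sp$train, sp$test)
evaluate_checkpoint(ck, sp$test)$f1
#> [1] 1

# end-to-end: FOV -> TIL map -> score -> spatial features
res <- run_slide(gen$slide, ck, pipeline_config(seed = 5),
                 out_dir = "til_out", slide_id = "demo")
til_score(res$map)
#> [1] 0.1553073
res$features$values[c("til_score", "gamma", "g_plus", "banfeld_raftery")]
#>       til_score           gamma          g_plus banfeld_raftery
#>      0.15530728      0.87672131      0.01940144     -3.60082600
```

The TIL score says 15.5% of the tissue area in the 24 valid patches is
lymphocytic; 19 patches pass the TIL-patch threshold and affinity
propagation groups them into 4 clusters. `gamma` near 1 says
within-cluster patch distances are almost always smaller than
between-cluster ones (tight, well-separated TIL aggregates), `g_plus`
near 0 is the same story as a discordance rate, and `banfeld_raftery`
summarizes total within-cluster spread. `til_out/` contains the FOV JSON,
the per-patch TIL map CSV, the feature vector CSV and a JSON-lines stage
log.

Cohort-side, with planted ground truth:

```r
co <- generate_cohort(cohort_spec(n_patients = 150, n_genes = 100,
                                  n_correlated_genes = 5, planted_rho = 0.6,
                                  seed = 7))
rep <- run_cohort(co, pipeline_config(seed = 7), out_dir = "cohort_out")
head(rep$er_positive$screen, 3)   # genes recovered by the |rho| > 0.3 screen
#>       gene       rho   abs_rho
#> 1 GENE0005 0.6516097 0.6516097
#> 2 GENE0001 0.6214166 0.6214166
#> 3 GENE0003 0.6079927 0.6079927
```

## Command line

```sh
Rscript inst/cli/tilscope.R simulate --seed 3 --out slide
Rscript inst/cli/tilscope.R fov --in slide.ppm --out fov.json
Rscript inst/cli/tilscope.R run-all --seed 3 --out run_dir
```

Slides are plain PPM rasters (P3/P6) standing in for vendor slide formats;
all outputs are CSV/JSON with seed-carrying metadata headers.

## Layout

```
R/            implementation (synthetic data, FOV, segmentation, TIL map,
              spatial indices, omics association, pipeline)
src/          RcppArmadillo: convolution network, component labeling
inst/cli/     command-line entry point
tests/        testthat suite incl. the acceptance criteria
vignettes/    methods vignette (models, assumptions, design decisions)
scripts/      acceptance report script
```
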