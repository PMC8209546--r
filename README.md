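# itfpipe

Morphometric and epigenomic profiling of the invasive tumor front (ITF).

The ITF — the zone where tumor tissue meets the adjacent host tissue (in
uterine tumors, the myometrium) — is where invasion, desmoplastic matrix
remodeling and immune engagement happen.  `itfpipe` re-implements, as a
tested and reusable R package, a computational workflow for characterizing
the ITF from two directions:

* **Tissue morphometry** — probabilistic segmentation of reticular
  (collagen-III) fibers in silver-stained brightfield histology, a
  fifteen-parameter per-fiber morphometry suite, and two-scale ROI group
  statistics; plus immune cell density profiling from phenotyped
  multiplex-immunofluorescence cell tables.
* **Omics integration** — EPIC-style differential DNA methylation calling
  (per-CpG Wilcoxon rank-sum, Benjamini–Hochberg FDR < 5%), a promoter
  CpG-island methylation signature, and its intersection with
  differential expression to yield an epigenetic gene signature
  (hypermethylated-and-downregulated plus hypomethylated-and-upregulated
  genes).

Because the original study's slides and omics matrices are not
reproducible at desk scale, a first-class **synthetic-data module**
generates all four input modalities with known ground truth: fiber images
with per-fiber geometry, marked point patterns of immune phenotypes,
bimodal beta-value matrices with planted differentially methylated CpGs,
and negative-binomial count matrices anti-coupled to the methylation
truth.  Every analysis stage therefore has a parameter-recovery test
surface.

## The core statistics

* **Fiber probability.** Pixels are scored by a logistic model
  `p = logistic(w0 + w·x)` on a six-feature neighborhood stack of the
  optical density `OD = −log10(I / I0)` after iterative enhancement
  (median-background subtraction + multiscale Hessian ridge response).
  Segmentation quality is summarized by the pixel-wise ROC AUC (the
  rank-sum statistic); the benchmark threshold is the 0.9563 AUC reported
  for the original fiber-detection model.
* **Morphometry.** Per fiber: area, Crofton perimeter, convex perimeter,
  perimeter ratio, medial-axis width, maximum Feret diameter (height),
  skeleton length, aspect, branch vertices, box-counting fractal
  dimension, shape `P²/(4πA)`, deformity `P² − 4πA`, solidity; per ROI:
  fiber density (fibers/mm²) and % stained area.
* **Group comparison.** Fisher–Snedecor variance F-test (two-sided)
  gates the choice between pooled-variance Student and Welch t-tests;
  stars at 0.05 / 0.01 / 0.001.
* **Methylation.** Per-CpG two-sided Wilcoxon rank-sum (exact for small
  groups), BH FDR; the promoter-CGI signature is the significant CpGs in
  islands at TSS1500/TSS200; integration intersects per-gene methylation
  direction (mean signature-CpG Δβ) with DE direction at adjusted
  p < 0.05.

## Worked example

```r
library(itfpipe)

img  <- generate_fiber_image(fiber_image_spec(seed = 7))   # 512 px, 0.46 um/px
od   <- optical_density(img$image)
enh  <- enhance_fibers(od, resolution = 0.46)
fs   <- pixel_features(od, enh, resolution = 0.46)
model <- fit_pixel_logit(fs, as.vector(img$truth_mask), seed = 1)
prob  <- probability_map(model, fs)
roc_auc(prob, img$truth_mask)
#> [1] 0.9999777

seg  <- segment_fibers(prob, resolution = 0.46)
core <- tissue_area(optical_density(img$image, I0 = 255), resolution = 0.46)
summarize_roi(measure_fibers(seg), core)[
  , c("total_fibers", "density", "pct_sa", "mean_width", "mean_height")]
#>   total_fibers  density pct_sa mean_width mean_height
#> 1           19  359.911 15.953      5.539      51.782
```

19 fibers are recovered from 18 planted (one was split by a tissue hole);
the mean medial-axis width of 5.5 µm recovers the planted 5 µm mean, and
density/%SA are the two ROI-level members of the fifteen-parameter suite.

The omics arm end-to-end:

```r
sb <- signature_benchmark(seed = 7)
sb[c("n_genes", "hyper_down", "hypo_up", "ari")]
#> $n_genes    [1] 20
#> $hyper_down [1] 9
#> $hypo_up    [1] 11
#> $ari        [1] 1
```

The default simulation plants 9 hypermethylated-downregulated and 11
hypomethylated-upregulated coupled genes; the pipeline recovers exactly
that 20-gene signature and its clustering separates the two sample groups
perfectly (adjusted Rand index 1).

A full multi-stage run with a manifest:

```r
run_pipeline(pipeline_config(seed = 1), "out/")   # or: exec/itf run --out out/ --seed 1
```

## Layout

* `R/` — synthetic generators (`synth_*`), segmentation, morphometry,
  ROI statistics, immune densities, methylation, integration, pipeline,
  CLI (`exec/itf`).
* `src/` — Rcpp raster primitives: separable convolution, running-median
  filter, connected components, exact Euclidean distance transform,
  Zhang–Suen thinning.
* `vignettes/itf-methods.Rmd` — the methods notes: model assumptions,
  parameter choices, numerical conventions, limitations.
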