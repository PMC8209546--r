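---
title: "Methods: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`itfpipe` profiles the invasive tumor front (ITF) along two arms: fiber
morphometry on silver-stained brightfield histology (plus immune cell
densities), and a promoter CpG-island methylation–expression integration.
This vignette records the models, the tunable parameters with their
defaults and units, the numerical conventions, and the design decisions
taken where the workflow left genuine freedom.  It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. Fiber segmentation

**Optical density.** `OD_c = −log10(I_c / I0_c)` per channel, clipped to
`[0, od_max]` with `od_max = 3` (an 8-bit sensor cannot resolve more than
about three decades), and `OD = od_max` where `I = 0`.  The reference
white `I0` defaults to the per-channel 99th-percentile intensity of the
tile — a robust background estimate for tiles dominated by pale tissue.
For *tissue-area* measurement we instead recommend `I0 = 255` (pure
white): there the relevant contrast is pale-tissue vs. bright holes, and a
tile-derived `I0` would zero out the tissue itself.

**Iterative enhancement.** The underlying workflow describes an
iteratively computed optical density that enhances the reticular fibers
but does not specify the operator.  We chose, per iteration: (i) subtract
a running-median background (kernel radius 20 µm, implemented as a
quantized Huang running-histogram median in C++), keeping the positive
part; (ii) add a multiscale ridge response — `σ²·max(0, −λ_min)` of the
Gaussian-smoothed Hessian, maximized over scales matched to fiber widths
(`scales_um = c(2, 5, 8)`, converted to `σ = scale/(2·resolution)`
pixels); (iii) cap the result at the input OD maximum (never re-amplify a
flat map — early versions that renormalized by the running maximum blew
white-noise tiles up to full range).  Two iterations are the default; the
test suite checks that iterating does not degrade fiber/background
separability.

**Pixel model.** Six features per pixel: raw OD, enhanced OD, local mean
and SD of the enhanced OD in a 9-px window (integral images), a
single-scale ridge response, and the structure-tensor anisotropy in the
window.  "Topology" in the source description is not defined; this
neighborhood stack is our concrete reading — it describes whether a pixel
sits on an elongated dark structure.  A maximum-likelihood logistic model
is fitted on a class-balanced random pixel sample (default 20,000,
seeded).  The probability map is thresholded at 0.5 and 8-connected
components below 10 µm² are dropped; both values are exposed because the
source states neither.  Evaluation is pixel-wise ROC AUC via the rank-sum
statistic (ties count one half), checked in the tests against explicit
pairwise concordance.

## 2. Morphometry

Thirteen per-fiber parameters plus two ROI-level ones (density, %SA) make
the fifteen-parameter suite.  Conventions:

* **Perimeter**: 4-direction Cauchy–Crofton estimate from axis and
  diagonal crossing counts, `P = π/8·(n_h + n_v + (n_d1 + n_d2)/√2)`.
  Exact for rasterized disks (the disk test asserts the isoperimetric
  identities `shape ≈ 1`, `deformity ≈ 0`); about 5 % low for axis-aligned
  rectangles.
* **Convex hull** is taken over boundary-pixel *corner* points, so
  `solidity = area/convex_area ≤ 1` holds structurally.
* **Width** is `2·mean(EDT)` over medial-axis (Zhang–Suen skeleton)
  pixels.  At exactly 45° the lattice quantizes the EDT upward by up to
  `√2/2` px; the rotation-invariance test therefore averages over
  sub-pixel placement phases, which is the meaningful expectation.
* **Vertices**: skeleton pixels with ≥ 3 skeleton neighbors, merged
  within a 3-px radius (thinning produces adjacent junction pixels).
* **Fractal dimension**: least-squares slope of `log N(s)` vs `log s`
  over dyadic box sizes.  Applied to the *filled mask* this is not
  scale-stable for ribbons (boxes below the fiber width see a 2-D
  cross-section), so `measure_fiber()` box-counts the *medial axis*: a
  straight fiber gives 1.0 and wavy/branched fibers give larger values,
  independent of rendering resolution.  The raw-mask primitive
  `box_count_dimension()` is kept and satisfies the thin-segment (≈ 1)
  and filled-square (≈ 2) identities.
* **Shape / deformity**: the isoperimetric factor `P²/(4πA)` and deficit
  `P² − 4πA` (µm²).  The source never prints formulas for these; the
  isoperimetric pair matches the printed orders of magnitude without any
  claim of numeric equivalence.  Likewise the published perimeter-ratio
  convention could not be recovered from the text; we use
  convex-perimeter / perimeter, which is ≤ 1 and decreases with waviness.
* **Tissue area** thresholds channel-averaged OD at 0.05 (vs. white) and
  fills background components smaller than 20 µm across — the "holes and
  damaged tissue" exclusion.
* Aggregation before statistics is per-fiber → per-ROI mean → per-sample
  mean, and the density unit is fibers/mm² (the per-µm² figure printed
  once in the source text is physically impossible at the stated values;
  the figure captions' mm⁻² is adopted).

## 3. Group statistics

`compare_groups()` computes the Fisher–Snedecor F (larger over smaller
sample variance, two-sided p — sidedness was unstated; two-sided is the
conservative choice) and gates the t flavor on it: pooled-variance
Student when `f_p ≥ 0.05`, Welch otherwise — the classical reason the two
tests are reported together.  Stars at 0.05/0.01/0.001 on the t p-value.
No multiplicity correction across parameters by default, mirroring the
source presentation; `adjust = "BH"` is available.  Degenerate inputs
(two identical constant groups) return `t = 0, p = 1` rather than error.
ROI categories follow tumor-polygon coverage of the rectangle: tumor
≥ 0.95, myometrium ≤ 0.05, ITF within [0.4, 0.6] (a tolerance band around
the stated 50/50 composition, since exactness is impossible on real
polygons); anything else is uncategorized.  Polygon clipping is
Sutherland–Hodgman against the rectangle; GeoJSON coordinates are microns,
origin top-left, y down.

## 4. Immune densities

Phenotypes are the closed set CD68, CD3, CD8, CD20, CK, other, treated as
mutually exclusive labels (as emitted by an upstream classifier); CD8 is
*not* folded into CD3 because the populations are reported separately.
Cells within 20 µm of an ROI edge are removed (the margin is unstated in
the source; 20 µm is about one cell diameter) and densities use the
trimmed effective area `(w−2m)(h−2m)` — consistent denominator choice for
the trimmed counts.  `total_immune` sums the four immune markers.

## 5. Methylation arm

Quantile normalization is delegated to `limma::normalizeQuantiles(ties =
TRUE)`, which implements exactly the sort/rank-mean/reassign contract
(the tests check it against a hand-coded oracle).  Filtering removes
SNP-flagged probes, then any probe with detection p > 0.01 in *any*
sample — whole-probe removal keeps the matrix rectangular where the
source is ambiguous between masking and removal.  The per-CpG test is a
two-sided Wilcoxon rank-sum: exact when the pooled sample size is ≤ 25
and tie-free, a tie-corrected normal approximation otherwise, `p = 1` for
fully tied rows; groups are independent patients, so the unpaired test is
assumed.  The group labeled first *alphabetically* is group A in
`delta_beta = mean(A) − mean(B)`; with this convention relabeling the
groups exactly negates effect signs (a property the tests assert).
BH q-values below 0.05 define significance.  "Promoter" means TSS1500 ∪
TSS200 (5'UTR/1stExon excluded, configurable); the promoter-CGI signature
is the significant island-promoter CpG set with its gene map.  Clustering
is Euclidean/average-linkage (unstated in the source; exposed as
arguments), and the concordance R² is the squared Pearson correlation of
per-CpG group means over all valid CpGs.

## 6. Integration

The DE stand-in (`surrogate_de()`) is deliberately simple plumbing —
median-of-ratios size factors, Wilcoxon on `log2(normalized + 1)`, BH —
because the original used a full NB engine that is out of scope here;
externally computed DE tables can be supplied instead.  Per gene, the
methylation direction is the sign of the mean Δβ over its signature CpGs,
dropped below a 0.05 floor or when positive and negative CpGs tie with no
majority.  The signature intersects direction +1 with significantly
negative log2FC (`hyper_down`) and −1 with positive (`hypo_up`) at
adjusted p < 0.05 (the threshold for the integration step is not printed
in the source; the conventional 0.05 is adopted and exposed).  Separation
is measured as the adjusted Rand index of a 2-cut average-linkage
clustering on the signature CpGs against the true groups.

## 7. The synthetic world

The generators' defaults are the stated world and are not tuned to tests:

* **Fiber images**: 512 px at 0.46 µm/px (the canonical 20× scan
  resolution); 20 fibers per tile ≈ 360 fibers/mm², within the reported
  83–307 mm⁻² order; mean width 5 µm (CV 0.2), mean length 60 µm
  (matching reported fiber heights of ~43–48 µm), waviness 0.25 rad per
  2-px step, one branch per 100 µm, fiber gray 90 on background 200
  (holes 250), noise SD 8, blur σ 1 px, 5 % holes.  Centerlines are
  spline-smoothed random walks dilated to width; placement uses rejection
  sampling against an occupancy mask (fibers avoid holes and each other)
  and *refuses* collisions after 25 tries rather than forcing them, so
  `truth_table` — not `n_fibers` — is the authoritative planted set.
* **Cell fields**: Poisson counts at category-specific densities (e.g.
  tumor CD8 132 vs 12 cells/mm² for the two tumor types — the reported
  contrast used as a generator default, not as a reproduction claim);
  optional Thomas clustering preserves expected counts while inflating
  quadrat variance.
* **Methylation**: 5,000 CpGs (a 850 K-array stand-in scaled so the
  pipeline runs in minutes), 10 vs 10 samples, 3.5 % planted DMCpGs
  mirroring the printed fraction.  `delta_beta = 0.2` is interpreted as
  the planted *β-scale* group difference, applied as the equivalent
  logit-scale shift of group B at each CpG's baseline; a literal logit
  shift of 0.2 would be a β difference of ~0.05, which contradicts the
  same specification's power expectations at n = 10 vs 10.  Planted
  baselines are drawn in [0.25, 0.75] so shifted means stay inside (0,1)
  without clamping.  Beta noise uses concentration κ = 50 (β-value SD
  0.04–0.07, typical of array replicates).  Forty promoter-island genes
  receive 3 planted CpGs each with per-gene consistent direction; SNP
  flags (2 %) avoid planted probes; detection failures are 0.2 % of
  cells.
* **Expression**: NB counts (dispersion 0.1), planted |log2FC| = 2,
  library-size factors in [0.7, 1.3]; 9 hyper-down + 11 hypo-up coupled
  genes (the composition the integration must recover) plus 40 + 40
  methylation-independent DE genes drawn from genes with no planted
  methylation, so signature recovery is a real intersection test rather
  than a tautology.

What a green test does *not* establish: the synthetic tiles have
homogeneous backgrounds (no counterstain gradients, folds, or stain
batch effects), cells are single points without segmentation error, and
β-values have no probe-type chemistry structure; recovery on this world
bounds algorithmic correctness, not robustness to real FFPE artifacts.

## 8. Scale choices and limitations

The acceptance segmentation benchmark renders its twenty 1-mm² tiles at
0.92 µm/px — half the canonical sampling, same physical world — to fit a
single-CPU budget; fiber widths remain ≈ 5.4 px, comfortably above
Nyquist for the ridge scales used.  Known limitations: fiber orientation
relative to the tumor–myometrium boundary is out of scope; the published
perimeter-ratio definition is unrecoverable from the source text (our
convex/actual convention is documented above); images are exchanged as
ASCII PGM/PPM because no binary image codec is assumed in the runtime
environment.
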