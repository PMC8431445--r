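---
title: "Methods: models, parameters and design choices in melcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in melcpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`melcpipe` turns cyclic immunofluorescence (MELC) acquisitions into a
clustered single-cell atlas. This vignette documents the models behind each
stage, the parameters that matter, the numerical choices, and what the
bundled simulator does and does not emulate. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## The acquisition and artifact model

One MELC cycle stains one marker, acquires a fluorescence tag image,
photobleaches, and acquires a post-bleach image; a phase-contrast image
precedes every cycle and a brightfield/darkframe pair is acquired once per
field of view. The simulator (`make_scene()`, `render_run()`) renders this
process with an explicit forward model. With specific signal $S_c(x,y)$ in
cycle $c$, multiplicative shading $g(x,y)$, darkframe offset $d$, and
bleach-residual fraction $\rho \in [0,1)$:

$$\mathrm{tag}_c = g\,(S_c + \rho\,S_{c-1}) + d, \qquad
  \mathrm{postbleach}_c = g\,(\rho\,S_c) + d,$$

with brightfield $B\,g + d$ and darkframe $d$. Poisson shot noise and
Gaussian read noise are applied last, when enabled. The shading field is
the simplest smooth radial model matching the "dimmer toward the
periphery" phenomenology: $g = 1 - \alpha (r/r_{\max})^2$, centered, with
$r_{\max}$ the center-to-corner distance, so a corner pixel retains
$1-\alpha$ of the central brightness.

Two consequences are deliberate:

* **The corrections are exactly invertible in the noiseless limit.**
  Flat-fielding with the calibration pair removes $g$ and $d$
  algebraically, and subtracting the previous cycle's (flat-fielded)
  post-bleach image removes $\rho S_{c-1}$ exactly. The acceptance suite
  verifies recovery of $S_c$ (up to the global scale
  $\mathrm{mean}(\mathrm{bright}-\mathrm{dark})/B$) to a relative error
  below $10^{-6}$.
* **Because the simulated brightfield captures the full multiplicative
  shading, stack-based vignetting estimation is redundant whenever
  calibration images exist.** `correct_run(vignette = "auto")` therefore
  estimates a gain from the tag stack only when flat-fielding is off or no
  calibration is present; re-estimating residual gain from already-flat
  images would only inject estimation noise. The estimator itself is
  exercised on a dedicated dense-signal fixture (`render_gain_stack()`):
  cells-on-black scenes have zero background at most pixels, which is
  exactly the regime where retrospective shading estimation is
  ill-posed, whereas everywhere-positive textured fields are its intended
  input.

Unspecific binding is modeled as a per-cell log-normal factor $u_i$
(mean 1, log-sd `unspecific_sigma`) that multiplies both a marker with a
declared negative-control pairing and its NC channel. This makes NC-ratio
normalization exactly corrective in expectation and lets the tests probe
that contract directly.

### What the simulator does not emulate

No point-spread function, chromatic shift, focus drift, non-rigid tissue
deformation, 3-D structure, autofluorescence spectra, or cell-cell contact
(cells are placed with a hard non-overlap margin). Passing tests on
synthetic scenes therefore demonstrate correctness of the algorithms under
the stated artifact model, not performance on real tissue, where touching
cells and segmentation errors dominate. Magnitudes of the artifacts
(defaults: $\alpha = 0.3$, $\rho = 0.2$, `unspecific_sigma = 0.3`, read
noise 2 counts, Poisson on) are plausible for a cooled-CCD 20× setup but
are not fitted to any measured instrument; no quantitative artifact
magnitudes are published for this class of acquisition.

### Simulation defaults

The reference fixture (`easy_scene(seed = 0)`) plants ~400 cells of four
phenotypes (T-cell-like, B-cell-like, myeloid with banded nuclei via a
concavity notch, and large tumor-like cells co-expressing GD2/CD56/CD24/
FAIM2) on a 768 px field over a 9-marker panel plus one NC channel and a
nuclear stain. Positive markers average ~200–400 counts against a ~5-count
negative baseline, with per-cell biological scatter log-normal at
`sdlog = 0.15` — tight but non-degenerate phenotypes, chosen once as the
"well-separated types" regime the end-to-end recovery contract (ARI ≥ 0.9,
F1@IoU0.5 ≥ 0.95) is defined on. Desk-scale problem sizes throughout the
tests (hundreds of cells, 128–768 px fields, 8–20 consensus repeats) were
chosen so the full suite and acceptance script run in minutes on one core
while keeping every statistical check comfortably away from its threshold.

## Correction stage

* **Registration**: integer-pixel phase correlation of each cycle's
  phase-contrast image against a reference cycle (default: first). One
  rigid translation per cycle is applied to tag, post-bleach and phase
  images alike; out-of-frame pixels are zero-filled and tracked in a
  validity mask. Estimated shifts beyond `max_shift` (default 30 px) flag
  the cycle; the failure policy (error / drop / keep) is configurable.
  Sub-pixel refinement is intentionally absent: the simulator plants
  integer shifts and real MELC stage drift is of that order.
* **Flat-field**: `(I - dark) / max(bright - dark, eps) * mean(bright -
  dark)`, negatives clipped to zero. The `eps` guard defaults to $10^{-6}$
  of the brightfield dynamic range; the `mean` rescaling keeps corrected
  images on the input intensity scale.
* **Bleach subtraction**: pixelwise `max(tag_c - postbleach_{c-1}, 0)`;
  the first cycle has no predecessor and passes through. Run-level order
  is flat-field first, then subtraction, so both operands are on the
  calibrated scale; in the noiseless limit the order is immaterial.
* **Vignetting**: each image is normalized by its mean, a per-pixel median
  across the stack gives a robust raw shading estimate, and a degree-2
  polynomial surface fit supplies the heavy smoothing (the quadratic family
  contains the radial model exactly). The mean-normalized gain divides
  every image. At least 8 images are required; a precomputed gain map is
  accepted in place of estimation. This stands in for published
  regularized-energy-minimization estimators, whose parameters are not
  reproducible from the literature; the testable contract — flatten
  multiplicative shading — is preserved.

## Segmentation and reconciliation

The classical baselines (Gaussian smoothing → Otsu threshold →
distance-transform watershed → small-object removal; a local-sd texture map
replaces intensity for phase contrast, with an erosion of half the texture
window compensating the map's dilation) stand in for trained
instance-segmentation networks, which are out of scope. Externally produced
label masks (16-bit TIFF) are accepted anywhere a baseline mask is. When a
nucleus mask is available, cells may instead be grown from nuclei by
Voronoi propagation over the thresholded foreground
(`seed_cells_with_nuclei`, on by default in the pipeline) — the standard
seeded strategy in cell-image analysis.

"A cell object counts only if reproduced in the nucleus mask" is
operationalized as: the cell must contain **more than 50 %** of the pixels
of at least one nucleus; each kept cell is paired with its
largest-overlap qualifying nucleus, and each nucleus is assigned to the
single cell holding its largest share (majority rule; a 60/40 straddling
nucleus goes to the 60 % cell). The >50 % criterion guarantees the
cell–nucleus pairing is one-to-one. The published rule names no threshold;
this choice is documented, not ground truth. Cells touching the image
border are retained but flagged. Exclusion regions (file-supplied polygons)
remove cells by strict centroid interior; an on-edge centroid is kept.

## Features

Six morphological features (cell size and perimeter; nucleus size,
perimeter, roundness $4\pi A/P^2$, solidity $A/A_{\mathrm{hull}}$) and, per
marker, ME/TO/M20 in nucleus, whole cell and cytoplasm/membrane
(cell − nucleus), nine intensity features per marker. Numerical choices:

* Perimeter is the count of unit pixel edges on the object/background
  interface — exactly testable against a brute-force pixel loop, at the
  cost of a known overestimate on curved shapes (a digital disk's
  edge-count perimeter exceeds $2\pi r$); acceptable because features are
  used comparatively.
* Solidity uses the convex hull of the union of unit pixel squares (hull
  of the 4 pixel corners), so a plus-shaped 5-pixel cross has solidity
  exactly $5/7$.
* M20 uses $k = \max(1, \lceil 0.2n \rceil)$ pixels, the ceiling with a
  floor-of-one guard for tiny compartments; $\mathrm{M20} \ge \mathrm{ME}$
  always, with equality only for constant compartments.
* An empty cytoplasm/membrane compartment (nucleus fills the cell) yields
  zero intensity features plus a `cyto_empty` flag; the cell is retained.
* Sizes are in pixels; physical areas follow from `pixel_size` and are
  deliberately not materialized as columns.

## Normalization

NC-ratio normalization divides each intensity feature of an NC-paired
marker by the same cell's matching NC feature (+`eps`); NC columns are then
dropped. Background levels: per image and marker, counterpart-positive
cells are those above the `q_counterpart = 0.8` quantile of the mutually
exclusive counterpart's reference feature (default `M20_cyto`), and the
background level $b$ is the `q_background = 0.95` quantile of the marker
among them; all of the marker's intensity features are divided by $b$, so
1.0 means "at background". Per-image estimation of $b$ *is* the batch
correction. Design choices: **division rather than subtraction** by $b$
preserves positivity and, after downstream z-scoring, is equivalent up to
affine terms; the quantile-on-exclusive-reference rule replaces published
classifier-based threshold estimators behind the same interface, because
only the contract (a threshold separating signal from background, derived
from a mutually exclusive counterpart) is reproducible. Markers without a
pairing, or with fewer than `min_reference_cells = 20` reference cells in
an image, pass through with a warning. Both normalizations are monotone
within an image (cell ranking preserved) and scale-equivariant
(multiplying an image's intensities by $c$ leaves results unchanged).
Note the quantile rule's intrinsic false-positive rate: $b$ is by
construction the $q$-quantile of the reference (non-expressing) population,
so ~$1-q$ of negative cells exceed it.

## Feature validation by consensus stability

Per repeat: draw $\lceil 0.8F \rceil$ feature columns without replacement,
z-score, embed to 2-D by t-SNE (perplexity 30, capped at $(n-1)/3$), fit a
$G$-component Gaussian mixture **on the embedding** (the cited
"model-based clustering of t-SNE-embedded data" reading). Defaults
$R = 100$, $G = 10$, rate 0.8. The consensus matrix is the co-clustering
frequency; the consensus partition is an average-linkage cut of
$1 - M$ into $G$ groups. The embedding is recomputed inside each repeat —
the subsampled features change it — under a repeat-deterministic seed.
Metrics: PAC is the fraction of off-diagonal entries strictly inside
(0.1, 0.9); CON is the mean **plain Rand index** between each repeat
partition and the consensus partition (the cited package's internal
definition is not published; the metric slot is configurable); MSS is the
mean silhouette width under distance $1 - M$, self-contained and
embedding-independent, defined as 0 with a warning for a single-cluster
consensus; and $\mathrm{MCS} = ((1-\mathrm{PAC}) + \mathrm{CON} +
\mathrm{MSS})/3 \in [-1/3, 1]$. A degenerate mixture fit is retried once,
then the repeat is skipped with a warning. Because these definitions are
self-contained, MCS values are comparable *within* this package across
feature subsets, but not numerically interchangeable with other consensus
implementations' scores.

F-tests are one-way ANOVAs per feature across cluster labels with BH
adjustment; all-zero within-cluster variance reports $F = \infty$ with
$p = 0$. PCA runs on autoscaled features (constant columns dropped with a
warning); contributions are squared loadings normalized per component.

## Atlas

t-SNE (perplexity 30) on z-scored features, excluding the nuclear-stain
channel from phenotyping. Gaussian mean shift is implemented on a gridded
kernel-density estimate of the embedding (default 128 × 128) with
steepest-ascent hill climbing and basin labeling — deterministic and fast;
mode pairs closer than `mode_merge_tol` (default: one bandwidth,
single-linkage chain merging) are fused. Numerical hardening beyond the
textbook algorithm, both added because the trivial single-blob case
otherwise fragments: the default bandwidth `extent/15` takes a
Silverman-type floor $\bar\sigma\, n^{-1/6}$, and basins holding fewer than
$\max(3, 0.01n)$ points are reassigned to the nearest retained mode.

The interactive tool this stage mirrors specifies its mean-shift kernel as
$\sigma = 45$ in internal units of its own embedding scale; that constant
does not transfer to any reimplementation. The bandwidth here is defined in
embedding units. The default was calibrated once on the reference fixtures
and then frozen: on the 4-type fixture the recovered cluster count is
stable (4, ARI 1.0 against planted types) for bandwidths between extent/20
and extent/8, and `extent/15` sits mid-plateau; `extent/30` splits t-SNE
islands. Exact cluster counts of any particular study (e.g. a 10-cluster
atlas, 30 tumor-cell sub-clusters) are configuration here, not targets.

Sub-clustering is complete-linkage agglomeration on Euclidean distance
over the selected (normalized) feature columns — the linkage is the cited
method, the metric is this package's documented choice — cut into
`n_subclusters` groups. Cluster profiles are per-cluster feature medians,
min–max scaled per feature across clusters to [0, 1] (all-equal medians map
to 0); scaling preserves each feature's ranking of clusters. Composition
summaries report counts and within-sample proportions, with an optional
sample-grouping factor.

## Orchestration and determinism

`run_pipeline()` runs correction → segmentation → features → normalization
→ atlas in fixed order from a single nested config; one global seed fans
out to per-stage seeds. Re-running with identical inputs and seed
reproduces the feature CSVs byte-identically (asserted in the tests). The
config is fingerprinted (MD5 of its YAML serialization) into every result
and artifact log, so mixed-parameter artifact sets are detectable. The
`exec/melcpipe` script is a thin wrapper over these functions with exit
codes 0/2/3 (success / validation error / processing error). Feature
tables, masks, gain fields, background levels, embeddings and composition
tables are written as CSV/TIFF/YAML; FCS export is not provided (no FCS
writer in the dependency set) — the CSV carries the same per-cell content.

## Known limitations

* The segmentation baselines are deliberately simple; on real tissue with
  touching cells they will under-perform trained instance models — use the
  external-mask interface for production masks.
* Background-level estimation needs a genuinely exclusive counterpart and
  enough counterpart-positive cells per image; panels without such pairs
  fall back to unnormalized features (warned).
* Stability metrics follow self-contained definitions (see above) and are
  not numerically comparable to other consensus-clustering packages.
* The simulator's noise model is per-pixel and spatially uncorrelated;
  structured artifacts (dust, smears, tiling seams) must be handled with
  exclusion regions.
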