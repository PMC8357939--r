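---
title: "Segmentation variability and radiomic feature robustness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation variability and radiomic feature robustness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrobust)
```

## The problem

Radiomic analyses mine hundreds of quantitative descriptors from a delineated
tumor volume. Because the delineation sits upstream of everything else, any
disagreement between the humans who draw it propagates into every feature.
For low-contrast tumors — pancreatic lesions on contrast CT are the
motivating case — that disagreement is large, and it differs systematically
*between professional disciplines*: radiation oncologists, who contour
treatment volumes daily, tend to draw larger and mutually more consistent
volumes than radiologists, whose practice emphasizes labeling over full
volumetric segmentation.

`segrobust` implements the complete analysis chain needed to quantify this:

1. simulate a multi-observer, two-discipline delineation cohort on phantom
   volumes (`generate_cohort()`);
2. form a per-patient consensus segmentation with STAPLE and grade each
   observer's agreement with the Dice similarity coefficient
   (`per_patient_agreement()`);
3. extract a 1277-feature radiomic panel per (image, mask) pair
   (`extract_panel()`);
4. score per-feature robustness with ICC(2,1), overall and per discipline
   (`feature_icc_table()`), and compare the disciplines
   (`discipline_icc_wilcoxon()`, `rank_agreement()`).

No public dataset accompanies the motivating study, so the synthetic cohort
generator is a first-class, tested component: it defines the study
conditions under which every downstream claim is checked.

## The consensus model: STAPLE

Given binary delineations $D_{ij} \in \{0,1\}$ of voxels $i$ by observers
$j$, STAPLE treats the true segmentation $T_i$ as latent and each observer
as a channel with sensitivity $p_j = P(D_{ij}=1 \mid T_i=1)$ and specificity
$q_j = P(D_{ij}=0 \mid T_i=0)$. EM alternates between the posterior

$$W_i = \frac{g \prod_j p_j^{D_{ij}}(1-p_j)^{1-D_{ij}}}
{g \prod_j p_j^{D_{ij}}(1-p_j)^{1-D_{ij}} +
 (1-g) \prod_j q_j^{1-D_{ij}}(1-q_j)^{D_{ij}}}$$

and the rater-parameter updates
$p_j = \sum_i W_i D_{ij} / \sum_i W_i$,
$q_j = \sum_i (1-W_i)(1-D_{ij}) / \sum_i (1-W_i)$.

Numerical choices (all configurable):

* initialization $p_j = q_j = 0.99999$, the standard near-perfect start;
* a **global scalar prior** $g$ equal to the mean foreground fraction across
  observers — the simplest defensible choice; a spatially varying prior is a
  known alternative but introduces coupling that the downstream analysis
  does not need;
* convergence when no $p_j$ or $q_j$ moves by more than `tol` ($10^{-6}$),
  at most 100 iterations; parameters are clamped to $[10^{-7}, 1-10^{-7}]$
  so degenerate unanimity cannot produce $\log 0$;
* the consensus mask is $W_i \ge 0.5$, ties counting as foreground.

Because the posterior depends on a voxel only through its label pattern,
voxels are grouped by pattern ($\le 2^J$ groups): the EM is exact and its
cost is independent of grid size. The test suite checks it against an
independently coded per-voxel EM to $10^{-8}$.

Agreement is measured per observer against the all-observer consensus with
$\mathrm{DSC} = 2|A \cap B|/(|A|+|B|)$ and graded High ($\ge 0.85$), Medium
($\ge 0.70$), Low ($\ge 0.5$), Very Low ($< 0.5$). DSC of two empty masks is
defined as 1 (never reached in normal runs). DSC and STAPLE are computed on
the **native** mask grid: that is where the contours exist; isotropic
resampling is strictly a feature-extraction concern.

## The feature panel

`extract_panel()` reproduces a fixed 1277-feature panel:

| image | features |
|---|---|
| original | 24 first order + 17 shape + 26 GLCM + 16 GLRLM + 22 NGTDM/NGLDM + 16 GLSZM + 22 IVH = 143 |
| Laplacian of Gaussian | 126 (shape excluded — invariant to filtering) |
| 8 wavelet subbands (LLL..HHH) | 126 each = 1008 |

Preprocessing follows the study protocol: resample image and mask to
isotropic 5 mm voxels (windowed-sinc for the image, linear + 0.5 threshold
for the mask), discretize in-mask intensities with a fixed bin width of 25,
and accumulate GLCM/GLRLM over the 13 symmetric 3D directions at voxel
offset 1 into a single merged matrix; GLSZM zones and NGLDM dependencies use
26-connectivity.

Parameter choices worth calling out:

* **Sinc window.** "Sinc interpolation" admits many windows; we fix a
  Lanczos window of radius 3, widened by the downsampling factor for
  anti-aliasing, with edge-clamped boundaries and per-sample weight
  normalization so constants are interpolated exactly.
* **Mask resampling.** Linear interpolation of the 0/1 field thresholded at
  0.5 (ties → foreground) preserves volume far better at a 5 mm target than
  nearest-neighbor.
* **LoG scale.** `sigma = 5` mm — one voxel at the target spacing. LoG
  features are scale-sensitive, so this default is prominent in
  `extraction_config()`.
* **Wavelet family.** Coiflet-1, single-level, **undecimated**, so every
  subband keeps the input grid and can be masked directly. Subband labels
  are low/high-pass per axis in (x, y, z) order.
* **Discretization anchor.** The ROI minimum, per filtered image. Filtered
  responses have arbitrary signed ranges; a fixed absolute anchor would be
  undefined for them. A consequence worth knowing: the bin grid moves with
  the ROI minimum, which couples histogram features to the darkest in-mask
  voxel.
* **Surface area** uses the voxel-face definition (sum of exposed face
  areas). It is exact for voxel-aligned cuboids and upper-bounds the true
  area of smooth bodies, so sphericity of a rasterized ball saturates
  around 0.65-0.8 rather than approaching 1; features derived from surface
  area must be read with that convention in mind.
* **IVH grid.** $I_x$ and $V_x$ at deciles $x = 10,\dots,90$ plus four
  absolute-threshold volume fractions at intensities 0, 25, 50, 75 — 22
  features. $I_{50}$, $I_{30/40}$, $V_{30}$ and the absolute-0 variant are
  the members that matter most downstream.
* **Degenerate ROIs.** Families with no valid voxel pairs (single-voxel
  ROI) return 0 by convention; entropy of a single-level ROI is 0;
  variance-normalized quantities with zero variance return 0. Nothing
  crashes on a degenerate ROI; the conventions are documented per function.

The panel's cardinality (1277 = 143 + 126 + 1008) and its per-class counts
are asserted exactly in the tests, as is equality of every texture matrix
with an exhaustively enumerated brute-force matrix on small ROIs.

## Robustness: ICC(2,1)

For each feature and each observer group (all six observers, discipline A,
discipline B) a patients-by-raters matrix is assembled and

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}
{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

is computed from explicit sums of squares — deliberately not via a
linear-model fit, both because the formula itself is the quantity of
interest and because the explicit decomposition is what the brute-force
oracle in the tests recomputes. Values can be negative and are reported as
computed; clipping would hide pathology. A feature with zero between-subject
variance in a group, or a vanishing denominator, gets a flagged `NA`:
never robust, excluded from paired tests and rank regressions.

A feature is **robust** when ICC exceeds 0.75 — strict inequality, following
the normative wording of the protocol (an "$\ge$" appears once in a results
summary; with continuous features the boundary has probability zero, but the
strict reading is implemented). Discipline ICCs are compared per image
filter with a two-sided Wilcoxon signed-rank test (zero differences dropped;
exact null for small tie-free samples, normal approximation otherwise — the
base-R convention), and relative robustness rankings are compared per
feature class by regressing B-ranks on A-ranks (average ranks on ties;
identical rankings give slope 1, $R^2 = 1$).

## What the synthetic cohort emulates

`cohort_config()` defaults encode the study conditions: 21 patients, six
observers in two disciplines, 5 mm slices with 0.9 mm in-plane voxels, and
low-contrast tumors of mean volume 50 cm³ (SD 15 cm³, truncated to
[15, 100]).

Each phantom tumor is a sphere modulated by a low-order random directional
field (degree ≤ 2 polynomials in the direction cosines, relative amplitude
0.10), calibrated by quadrature so the enclosed volume hits its target, and
rasterized with a sub-voxel center jitter that makes voxel-center counting
volume-unbiased in expectation. The background is a soft-tissue level plus a
mild random linear gradient, spatially correlated texture (Gaussian-smoothed
noise, 4 mm correlation), white noise, and a +40 intensity offset inside the
tumor — deliberately low contrast.

An observer's contour error is modeled as a **smooth radial displacement of
the truth surface** plus a global volume bias: the observer mask is the
level set $\{x : d(x) - \psi(u(x)) \le b\}$ where $d$ is the signed
Euclidean distance to the truth boundary, $\psi$ is a Gaussian-process-like
directional field (random cosine features, correlation length 10 mm of
surface arc), and $b$ is chosen so the delineated volume hits
`volume_bias` × truth volume × a lognormal per-delineation jitter. Spatially
correlated boundary errors are the realistic regime; independent per-voxel
label noise would make STAPLE trivially accurate and robustness trivially
high.

Default profiles (three observers per discipline):

| discipline | volume_bias | boundary_noise_sd (mm) | volume jitter (log-sd) |
|---|---|---|---|
| A (radiation-oncology-like) | 0.98, 1.00, 1.02 | 3.0, 3.5, 4.0 | 0.05 |
| B (radiology-like) | 0.60, 0.66, 0.72 | 5.0, 6.0, 7.0 | 0.12 |

These were tuned once so that the default cohort lands near the reported
agreement levels (mean DSC ≈ 0.88 for A, ≈ 0.68 for B; mean volumes ≈ 55 vs
≈ 37 cm³) — realism anchors, not correctness assertions. The analysis
claims that the tests verify are directional: DSC(A) > DSC(B), volume(B) <
volume(A), robust-feature count(A) > count(B), each required in ≥ 90% of 20
master seeds.

Determinism is structural: per-patient and per-observer seeds derive from
the master seed by a counter scheme
(`master + 104729 * patient + 7919 * observer`, mod $2^{31}-1$), so adding a
patient or observer never reshuffles existing ones, and two runs with the
same configuration write byte-identical tables.

**What the simulator does not model** — and hence what passing tests do not
establish about real data: anatomy (neighboring organs, vessels, stents),
scanner and reconstruction effects, the contouring software's smoothing
behavior, observer review/editing after outlier flagging, and intraobserver
variability. The phantom's contrast boundary is statistically uniform along
the surface, whereas real pancreatic tumor margins are conspicuous in some
directions and invisible in others; real interdisciplinary differences are
plausibly larger and more structured than the model's.

## Problem sizes and runtime choices

The default study (21 patients × 6 observers, full 1277-feature panel) runs
in well under a minute; the test suite's Monte-Carlo checks use 20 master
seeds for the direction-of-effect criteria and 10 seeds × 3 noise levels ×
8 patients for the ICC monotonicity sweep. These sizes were chosen so the
whole suite completes on a laptop-class single core while keeping every
stochastic assertion comfortably powered (the direction effects are
recovered in essentially all seeds, not 90%).

## Known limitations

* The feature catalog matches the study's printed per-class counts; where
  the underlying tool's exact feature list is not printed, the choice of
  members within a class (e.g. the 26th GLCM feature, the IVH grid) follows
  the standard nomenclature but is a reconstruction, documented in
  `extraction_config()` and the feature functions.
* Oblique NIfTI orientations are rejected, not resliced.
* The Wilcoxon implementation follows base R's convention for ties and
  exactness; the study does not state its convention.
* ICC confidence intervals are out of scope (not used in the analysis).
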