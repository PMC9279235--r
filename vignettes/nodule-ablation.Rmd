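---
title: "Attributing image-classifier performance to Brock-model features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing image-classifier performance to Brock-model features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(noduleablate)
```

## The question this package operationalises

Image-based malignancy classifiers for screen-detected lung nodules
outperform clinical logistic models such as the Brock (PanCan) model, but
they are opaque: one cannot read off how much of their accuracy comes from
nodule size, how much from margin morphology, and how much from the
surrounding lung. This package implements a feature-ablation framework
that makes that attribution measurable. The idea is symmetric:

* on the **regression side**, terms are removed from the published Brock
  linear predictor (without refitting), producing feature-reduced variants
  whose AUCs quantify what each covariate block contributes;
* on the **image side**, the corresponding information is removed from the
  CT volume itself — the nodule deleted (leaving parenchyma), the nodule
  replaced by a volume- and density-matched sphere (deleting margin
  morphology), or all internal texture and background flattened (leaving
  only size, shape, and type) — and a classifier is retrained per
  condition under a fixed cross-validation protocol.

Comparing the per-condition AUC drops on the image side with the
term-removal drops on the regression side says which image features carry
the predictive signal.

Everything runs on a synthetic CT-nodule cohort with known generative
truth, so every pipeline stage is testable end to end: the rank ordering
of the ablation conditions is a property the generator provably encodes,
and the tests check that the pipeline recovers it.

## The Brock model and its variants

The package ships the published full-with-spiculation coefficient set
(McWilliams et al., *N Engl J Med* 2013) as a versioned JSON file. The
linear predictor sums an intercept and per-predictor terms: age (per year,
centred at 62), female sex, family history, emphysema, nodule size through
the transform $(d/10)^{-1/2} - (4/10)^{-1/2}$ of the diameter $d$ in mm,
upper-lobe location, part-solid type, nodule count (centred at 4), and
spiculation. Malignancy risk is the logistic transform of the linear
predictor and is strictly increasing in size.

The three reduced variants drop terms *without refitting*:
`non_morphological` keeps age, sex, family history, emphysema, location,
and count; `morphological_only` keeps size, type, and spiculation;
`no_spiculation` keeps everything except spiculation. Because AUC is
rank-based, a dropped term contributes exactly its coefficient times its
covariate, so drops are interpretable term by term. A refit mode
(`brock_refit()`) exists for sensitivity analysis; the published
"parsimonious" coefficient set is deliberately not bundled — the
`no_spiculation` variant is defined by term removal, which is what the
phrase "all covariates ... except spiculation" describes. Three size
inputs can feed any variant: the manual calliper diameter, the automated
maximal axial diameter, or the equivalent spherical diameter (ESD).

## Automated size measurement

Given a binary segmentation mask with voxel spacing, the package computes:

* **volume**: foreground voxel count times voxel volume;
* **ESD**: $\sqrt[3]{6V/\pi}$, the diameter of the volume-matched sphere;
* **pairwise maximal axial diameter**: per axial slice, the largest
  distance between any two voxel-footprint corners (exact via convex
  hull), maximised over slices. Corners rather than centres are used so a
  single voxel has its rendered (diagonal) extent; the estimator therefore
  carries a deliberate upward bias of up to one voxel diagonal, and spike
  tips enter the boundary — this is the calliper semantics;
* **ellipse-fit maximal axial diameter**: per slice, a sub-voxel contour
  is traced at the 0.5 membership level (`grDevices::contourLines` on the
  zero-padded slice) and a direct conic-constrained least-squares ellipse
  is fitted; the major axis is maximised over slices. Slices with fewer
  than six contour points, or degenerate fits, fall back to the pairwise
  value for that slice. Averaging over the whole contour makes this
  estimator much less sensitive to spiculation, which is why it (unlike
  the pairwise method) tracks the smooth body of a spiculated nodule.

Only in-plane diameters are computed; z-spacing never enters a per-slice
diameter. All lengths scale exactly with spacing, which the tests assert.

## The three image ablations

All operators act on a (volume, mask, hilum landmark) triple and emit the
cubic window the classifier consumes (default side 44 mm — it must exceed
the largest includable nodule, 30 mm, plus spiculation):

* **parenchyma only** — the window is centred 15 mm (default) beyond the
  mask surface point that lies furthest along the direction from the
  nodule centroid to the hilum. If the nominal offset still overlaps the
  mask (generic for windows wider than 30 mm), the offset grows in 1 mm
  steps until window and mask are disjoint; the realised offset is
  recorded on the result. The window is provably nodule-free.
* **uniform density** — background voxels are set to −825 HU (the
  average lung density used as fill), nodule voxels to the nodule's mean
  density; with component-labelled masks (solid core = 1, part-solid
  shell = 2) each component receives its own mean by default, so the
  nodule-type cue survives. The mask is untouched: size, margin shape and
  the core/shell split are exactly preserved, and the operator is
  idempotent.
* **implanted sphere** — a sphere with the nodule's volume and mean
  density is rasterised at the centre of the parenchyma-only window. The
  radius is calibrated by bisection on the voxel count, with ties on the
  boundary shell (whole shells of grid-symmetric voxels enter at once)
  resolved deterministically, so the implanted volume matches the
  measured nodule volume to within one voxel. A
  volume-preserving sphere has diameter equal to the nodule ESD, which
  the tests verify via the ellipse estimator.

Two readings of the source procedure were genuinely open. First, whether
"a region ... towards the hilum was evaluated" means a translated
classifier window or in-place erasure: the translated-window reading is
implemented, since it matches "an image containing background lung
parenchyma" and guarantees the nodule is invisible. Second, whether
part-solid nodules should be flattened with one global mean or one mean
per component: both modes exist; per-component is the default because the
uniform-density condition is meant to retain nodule type as visible
information.

## The surrogate classifier and fold protocol

The proprietary CNN the framework probes cannot be part of a desk-scale
artifact, so the trainable scorer is a fixed-feature L2-regularised
logistic model. Its features see only the window's HU values: the window
is smoothed with a separable 3×3×3 box mean (the fixed-feature analog of
the local averaging a CNN's early layers learn), and the smoothed signal
yields intensity moments, quantiles, low-density tail fractions
(emphysema-pocket burden), gradient statistics and a radial profile;
the largest above-threshold (−600 HU) connected component is segmented
from the *raw* values — parenchyma noise cannot cross that threshold, and
raw segmentation preserves thin spikes — and described by volume, ESD,
maximal slice extent, and dimensionless irregularity measures
(sphericity, opening-residue fraction, convex deficiency, spike count);
the smoothing residual provides texture descriptors. Segmenting shape
from raw values while reading intensities from smoothed ones matters:
without it, the uniform-density condition enjoys a spurious advantage
(its windows are noise-free, so its size readout is cleaner), and with
smoothed segmentation the spikes vanish and spiculation becomes
invisible.

The fold protocol is participant-level and stratified: participants are
shuffled within label class and dealt round-robin into k = 8 groups, so
group sizes differ by at most one and malignant fractions balance. Fold i
tests on group i, validates on group i+1 (mod k), trains on the rest —
the 6/8 : 1/8 : 1/8 split. The validation group is used only to select
the ridge regularisation strength (by validation AUC, ties toward
stronger regularisation), which is the one unspecified role a validation
partition can defensibly play here. Each ablation condition gets its own
independently trained models, and pooling test scores over folds yields
exactly one out-of-fold score per nodule per condition.

## Statistics

AUC is the Mann–Whitney probability with midrank ties. Two scorers on the
same nodules are compared by (a) a percentile bootstrap of the AUC
difference over 10,000 draws by default, resampling *participants* with
replacement — nodules within a participant are correlated, so the
participant is the exchangeable unit; nodule-level resampling is a flag —
and (b) a two-sided permutation test whose null swaps each nodule's score
pair independently with probability ½, with the add-one estimator
$p = (1 + \#\{|T^\ast| \ge |T|\})/(n_{perm}+1)$ so p can never be zero.
The paired-swap scheme is the exchangeability-respecting null for
comparing two scorers on common nodules; it is a design decision of this
package, not an attribution of any published scheme. Degenerate
resamples (single-class labels) are redrawn and counted. Subgroup
comparisons (solid vs part-solid) run the identical machinery per
stratum and skip single-class strata with a warning.

The permutation test's size is checked by Monte Carlo (500 null
datasets, rejection rate within [0.03, 0.07] at α = 0.05), and the
bootstrap CI width is checked to shrink with n over 100/400/1600.

## The synthetic cohort: what it emulates and what it does not

`cohort_config()` defines the study conditions. Participants carry 1–4
nodules; covariate rates mirror a screening population (39% female, 50%
emphysema, 33% upper-lobe, 25% spiculated, 12% part-solid — spiculation
and part-solid rates are set high enough that their effects are
recoverable at cohorts of several hundred participants). True diameters
are log-uniform on 6–30 mm; manual diameter is the true diameter plus
0.5 mm SD calliper noise; inclusion filters keep manual readings in
[6, 30] mm (inclusive — the source excludes strictly below 6 and strictly
above 30) and solid/part-solid types only.

Malignancy labels come from a logistic model on centred log-size,
spiculation, part-solid type, upper-lobe location, age and emphysema,
with weights (2.2, 1.2, 0.6, 0.4, 0.03/yr, 0.6) — directions and rough
relative magnitudes mirror the Brock coefficients, with size dominant —
and an intercept calibrated by bisection so expected prevalence hits the
12% target (realised prevalence is within ±20% relative for n ≥ 500,
asserted over ten seeds). A `size_feature = "log_volume"` switch makes
labels depend on the volume-equivalent diameter instead of the calliper
diameter. The size-measure experiment built on it uses smooth,
non-spiculated ellipsoids with a wide axis-ratio range (0.4–1): the
calliper reads only the longest axis while the ESD reads the volume the
labels are driven by, so ESD-fed Brock should outrank calliper-fed
Brock. Spiculation is excluded from that cohort by design: spikes
inflate the calliper reading of precisely the higher-risk nodules (the
overestimation that motivates the ellipse-fit method), which confounds
the measurement-geometry question the experiment isolates.

Volumes are rendered per nodule from a per-nodule seed: truncated
Gaussian parenchyma around −825 ± 30 HU; emphysema participants get
low-density (−950 HU) pockets at 0.04 per cm³ with 3–7 mm radii; the
nodule is an axis-aligned ellipsoid whose longest axis (the nominal
diameter) lies in the axial plane, with solid interiors near +30 HU,
part-solid shells near −500 HU, and tapering radial spikes (2 mm base,
5 mm length, 8 per nodule) when spiculated. Spiculated nodules get more
heterogeneous interiors (texture SD 55 vs 18 HU): aggressive nodules
having irregular internal texture is the phantom's way of carrying the
texture information the unablated condition is supposed to contain, and
the uniform-density ablation to remove. HU values are integers clipped to
[−1024, 600]. The hilum landmark sits near the −x face, ≥ 25 mm from the
nodule centroid, so the parenchyma-only translation always has room; the
nodule centre is offset toward +x for the same reason.

What the generator does **not** emulate: airways, vessels, lobe anatomy,
partial-volume blur, scanner-dependent slice thickness, reader
variability beyond additive calliper noise, or any texture difference
between benign and malignant nodules of equal attributes. Passing the
ordering test therefore shows the *pipeline* recovers an information
hierarchy that the generator encodes; it says nothing about how a CNN
ranks nodules on real screening CT.

## Problem sizes and numerical choices

Cohort-scale experiments (the ordering recovery and the size-measure
comparison) run at 2 mm isotropic voxels, 92 mm rendered cubes, 700 and
1000 participants respectively, ten seeds each; geometry and conservation
tests run at 0.5 mm voxels where the analytic tolerances (2% on ESD and
ellipse diameters, 0.5% on implanted volume) are meaningful. Bisection
tolerances: 1e−8 on calibrated prevalence, voxel-exact on the implant
radius. Ties in the ridge-strength selection go to the strongest
regularisation; degenerate ellipse fits fall back to the pairwise
diameter per slice; empty feature components yield documented zero/floor
defaults. All randomness flows from per-stage seeds derived from one
master seed (`derive_seeds()`), and every artifact records the seed and a
configuration hash.

## Known limitations

The surrogate is linear in fixed features; its absolute AUCs (≈ 0.73 at
2 mm rendering) sit well below a CNN on real data, and only the ordering
and its approximate margins are claimed. The pairwise diameter's
footprint-corner bias is intentional but means it cannot be compared to
sub-voxel methods at the 2% level. The uniform-density ablation assigns
real-valued means into an otherwise integer-valued HU volume. The
implanted "sphere" is a sphere only up to its partially filled boundary
shell. Bootstrap CIs are percentile,
not BCa, matching the "distribution of differences" definition. The
rendered 92 mm cube is sized so that the translated parenchyma window of
the largest includable spiculated nodule still fits; tighter volumes make
the parenchyma-only operator fail loudly rather than silently crop.
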