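---
title: "Transmural perfusion metrics: model, geometry and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmural perfusion metrics: model, geometry and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transperf)
```

## Scope and model

`transperf` analyses pixel-wise myocardial blood flow (MBF) maps — 2D
short-axis grids in mL/min/g, one per slice (basal, mid, apical) and state
(adenosine stress, rest) — together with endocardial/epicardial contours
and an RV-insertion landmark. It does **not** estimate MBF from dynamic
image series: maps are inputs, as produced by in-line quantitative
perfusion reconstruction. Its job is everything downstream: splitting the
wall into endocardial (ENDO) and epicardial (EPI) layers, parcellating it
into AHA segments and coronary territories, computing the transmural
metrics, and deriving cohort-level normal values.

The transmural quantities are ratios of layer means:

* `MPR = sMBF / rMBF`, per layer `MPR_ENDO`, `MPR_EPI`;
* `sGRAD = sMBF_ENDO / sMBF_EPI` and `rGRAD = rMBF_ENDO / rMBF_EPI`;
* `RPP = HR × SBP`; `rMBF_c = rMBF / (RPP/10000)`; `MPR_c = sMBF / rMBF_c`,
  so `MPR_c = MPR × RPP/10000` identically.

In healthy myocardium autoregulation raises resting endocardial flow
(`rGRAD > 1`) while under hyperaemia the compressive load of the blood
pool flattens or inverts the gradient (`sGRAD ≈ 1` or below), so
`MPR_ENDO < MPR_EPI`. These orderings, not absolute values, are what the
validation suite checks on simulated cohorts.

## Layer geometry

The decomposition follows a centre/ray/midline construction:

1. the blood-pool centre is the **area centroid of the endocardial
   polygon** — the source description ("centre of the LV blood pool")
   fixes no formula, and the centroid is deterministic, robust to vertex
   density, and interior for star-shaped LV borders;
2. the map is resampled to 1 mm (bilinear, pixel-centre aligned; the
   kernel and alignment are our choice, the source being silent);
3. 360 rays are cast at 1-degree increments; on each ray the midline
   vertex is the midpoint of the endocardial and epicardial border
   crossings;
4. a pixel belongs to the myocardium when its centre is inside the
   epicardial and outside the endocardial polygon, and to the ENDO layer
   when additionally inside the midline polygon. The two layers partition
   the myocardium by construction.

Numerical choices worth recording:

* **Background sentinel.** Non-myocardial pixels are `NA`. Any masking bug
  that lets a background pixel into a mean surfaces as `NA` instead of a
  silently biased value; region means drop `NA`s and error when nothing
  valid remains.
* **Interpolation support.** Bilinear interpolation next to the background
  boundary would mix `NA` into myocardial values; those pixels fall back
  to the nearest source pixel, so the sentinel never bleeds inward nor
  myocardial values outward.
* **Ray/vertex degeneracy.** With 1-degree rays and 1-degree contour
  vertices a ray regularly passes exactly through a vertex, touching two
  adjacent edges; crossings closer than 1e-6 mm along the ray are merged
  before the crossing count is enforced. Rays that genuinely cross a
  contour more than once (non-star-shaped borders) abort with the ray
  angle named — real LV contours are star-shaped from the centroid, and
  silent mis-splitting would corrupt every downstream metric.
* **Ties.** Pixel centres exactly on the midline follow the even-odd rule
  of the point-in-polygon test; on floating-point grids this is a
  measure-zero event.

## AHA parcellation

Basal and mid slices get six 60° sectors (IDs 1–6, 7–12), the apical slice
four 90° sectors (13–16); the 17th apical-cap segment does not exist in
the 16-segment model and requesting it is an error. Sector boundaries are
anchored at the anterior RV-insertion angle and numbering proceeds
counter-clockwise in the (x, y) frame, the standard display convention;
the landmark is required input — inferring it from images is out of scope.
Territories are fixed: LAD {1,2,7,8,13,14}, RCA {3,4,9,10,15},
LCX {5,6,11,12,16}.

Global and territory MBF are **pixel averages** over the pooled
(three-slice) masks; slice-specific metrics are **unweighted means of the
slice's segment values**, and slice-specific ratios (gradients, layer
MPRs) average the segment-level ratios. The two aggregation rules differ
deliberately — they mirror how the quantities are defined for reporting.
Ratios guard their denominators: a non-positive denominator is a contract
error, anything below 1e-9 mL/min/g is reported as missing, never as
infinity.

## The phantom generator

`make_phantom()` builds an elliptical annulus whose myocardial values
follow a transmural profile of normalized ray depth *d* (0 at the
endocardial border, 1 at the epicardial): `uniform`, `linear`, or `step`
at mid-wall, plus optional Gaussian noise, with matching contours and an
RV landmark. Ground truth (`layer_truth()`) is the area-weighted mean of
each half-annulus, closed-form per angle and integrated over a dense
angular grid for ellipses — exact for circles.

Phantoms validate the geometry: layer-partition invariance on randomized
geometries, recovery of constructed step gradients to ±0.01 at 0.5 mm,
agreement with radial-distance classification on circles, midline accuracy
against a 0.01 mm ray-march oracle, and convergence of layer means to the
analytic truth as spacing shrinks. Note one benign artefact of circular
step phantoms: the value step and the layer boundary coincide at the
mid-radius, so gradient recovery there is exact rather than merely within
quantization error; the ±0.01 bound is doing real work only for
off-centre, elliptical or noisy geometries.

## The cohort simulator

`make_cohort()` draws wide per-subject records (demographics,
hemodynamics, and wall/ENDO/EPI MBF for global, slices and territories at
both states). The generative form — chosen as the simplest one matching
mean ± SD tables — is a truncated normal base MBF per state and sex, an
additive age effect on the stress mean, multiplicative slice and territory
factors normalized to weighted mean one, and a wall-to-layer split
`endo = wall·2g/(1+g)`, `epi = wall·2/(1+g)` from the endo/epi ratio `g`.

Defaults are the study conditions the simulator emulates: n = 138 with
54 female / 84 male; ages uniform on 19–79; rest MBF 0.68/0.56 and stress
2.41/2.12 mL/min/g (female/male); per-slice rest gradients 1.08/1.09/1.16
and stress gradients 0.98/0.92/1.03 (basal/mid/apical); hemodynamics per
sex around rest HR 65/63 bpm, rest SBP 112/120 mmHg, stress HR 95/86,
stress SBP 116/125. The stress age slope of −0.014 mL/min/g per year makes
the stress-MBF/age rank correlation about −0.47 under the uniform age
distribution while rest MBF carries no age effect; the stress *residual*
SDs (0.40/0.47) are set so that residual plus age-slope variance
reproduces the reported total SDs (0.47/0.53). Two deviations from a
minimal parameterization were necessary: slice factors are
**state-specific** (a single factor pair would cancel in MPR and could
never produce the depressed mid-slice MPR that systolic acquisition
causes), and layer ratios are **per-slice** (apical gradients run higher).
Territory factors (LAD > LCX > RCA) are anchored to the reported regional
means; the true covariance among regions is unknowable from printed
summaries and is a free parameter held at simple multiplicative noise.

What the simulator does *not* emulate: dynamic contrast passage, spatial
noise structure, partial-volume effects, contour errors, or realistic
between-region correlation. Passing cohort-level tests therefore shows the
statistical machinery recovers a known generative structure — not that the
pipeline is robust to real-world image artefacts.

## Cohort statistics

One Shapiro–Wilk gate (α = 0.05) drives both the summary presentation
(mean ± SD vs median ± IQR) and the test choice (t-tests vs rank tests;
repeated ANOVA vs Friedman for the three slices), so a metric is never
summarized under one distributional assumption and tested under another.
Constant samples are treated as non-normal; beyond the test's 5000-value
limit a deterministic subsample is used. The **95% cohort range**
(2.5th–97.5th percentiles, linear interpolation) is the normal range; the
95% CI of the median is a seeded percentile bootstrap (2000 resamples) —
the CI's construction is our choice where the source states none. Raw
p-values are reported without multiplicity correction except for the
pairwise slice contrasts, which are Bonferroni-adjusted. Both mean ± SD
and median ± IQR are always emitted; which is canonical is left to the
reader. `build_report()` assembles seven tables (demographics, global +
regional MBF, layer MBF/MPR, slice MPR, gradients, slice gradients, slice
normal values), overall and by sex, dropping and counting QC-excluded
subjects.

## Problem sizes and determinism

Validation runs use 0.25–2 mm phantoms up to 280×280 pixels, 200-phantom
randomized suites, and 200-replicate simulated cohorts of n = 138 —
sizes at which every property is measurable in seconds to a few minutes
on one CPU. All stochastic stages (phantom noise, cohorts, bootstrap)
take explicit seeds and restore the caller's RNG state; fixed seeds give
bit-identical maps, tables and CSVs.

## Limitations

* Contours are inputs; no segmentation, motion correction or dark-rim
  handling.
* The equidistant midline halves the wall geometrically; it is not a
  flow-weighted or angle-resolved transmural profile, and with strongly
  nonlinear transmural variation a two-layer split loses information.
* Normal values derived from simulated cohorts inherit every
  simplification listed above; they demonstrate the reporting machinery,
  not population truth.
* The parcellation's angular anchoring follows the published convention;
  matching a specific vendor implementation bit-exactly may require
  calibrating the anchor.
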