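# transperf

Transmural analysis of quantitative myocardial perfusion CMR: endocardial /
epicardial layer decomposition of pixel-wise myocardial blood flow (MBF)
maps, AHA 16-segment parcellation, layer-specific perfusion metrics, and
cohort-level normative statistics.

## The problem

Modern in-line quantitative perfusion cardiovascular magnetic resonance
produces pixel-wise MBF maps (mL/min/g) of the left ventricle at stress and
rest. Because CMR resolves the wall transmurally, perfusion can be split
into the subendocardial (ENDO) and subepicardial (EPI) halves of the wall —
and the balance between them carries diagnostic information: coronary
stenosis and microvascular disease depress endocardial perfusion first.
Using these layer metrics clinically requires (a) a reproducible geometric
definition of the two layers and (b) normative values from healthy cohorts.
`transperf` implements both halves as a testable pipeline, with an analytic
phantom generator and a cohort simulator so that every stage can be
validated without patient data.

## What it computes

For each short-axis slice with endocardial/epicardial contours and an RV
insertion landmark:

1. **Layer geometry** — the map is resampled to 1 mm, rays are cast at
   1-degree increments from the blood-pool centre (the endocardial area
   centroid), and a *midventricular line* is placed equidistantly between
   the two contours along each ray. Pixels inside the midline polygon form
   the ENDO layer, the rest of the myocardium the EPI layer.
2. **AHA parcellation** — 6/6/4 angular sectors on basal/mid/apical slices
   anchored at the RV insertion, grouped into LAD {1,2,7,8,13,14},
   RCA {3,4,9,10,15} and LCX {5,6,11,12,16} territories.
3. **Perfusion metrics** — with sMBF and rMBF the stress and rest layer or
   region means:

   - myocardial perfusion reserve `MPR = sMBF / rMBF` (per layer:
     `MPR_ENDO`, `MPR_EPI`)
   - transmural gradients `sGRAD = sMBF_ENDO / sMBF_EPI`,
     `rGRAD = rMBF_ENDO / rMBF_EPI`
   - rate-pressure product `RPP = HR x SBP`, workload-corrected rest flow
     `rMBF_c = rMBF / (RPP / 10000)` and `MPR_c = sMBF / rMBF_c`
   - slice-specific values as the mean over each slice's AHA segments;
     global and territory values as pixel averages.
4. **Cohort statistics** — Shapiro–Wilk-gated summaries (mean ± SD or
   median ± IQR) and tests (t / Mann–Whitney / Wilcoxon / Friedman /
   repeated ANOVA), Pearson/Spearman age correlations, 95% cohort ranges
   (2.5th–97.5th percentiles) as normal values, and bootstrap CIs of the
   median, assembled into a seven-table normative report.

## Worked example

A rest phantom with a midwall step (inner half 0.66, outer half
0.60 mL/min/g — a true rGRAD of 1.10), decomposed and measured:

```r
library(transperf)

ph <- make_phantom(phantom_spec(
  grid_shape = c(136, 136), pixel_spacing = 0.5,
  endo_radius = 20, epi_radius = 30,
  endo_value = 0.66, epi_value = 0.60, profile = "step"))

masks <- assign_layers(ph$map, ph$contours)
endo <- region_mean_mbf(ph$map, masks$endo_layer)
epi  <- region_mean_mbf(ph$map, masks$epi_layer)
transmural_gradient(endo, epi)
```

```
<layer_masks> 136x136 grid: 6280 myocardial pixels (2836 endo / 3444 epi)
rMBF_ENDO = 0.660, rMBF_EPI = 0.600, rGRAD = 1.100 (truth 1.10)
```

The endo/epi pixel counts (2836/3444) match the analytic half-annulus area
ratio 225:275, and the recovered gradient equals the constructed truth.

A simulated healthy cohort and its normative report:

```r
co  <- cohort_metrics(make_cohort(cohort_spec(), seed = 1))
rep <- build_report(co, boot_seed = 1)
rep$tables$slice_normal_values
```

```
<cohort_report> 138 subjects used (0 excluded of 138)
  metric slice  median   iqr ci_low ci_high
1 sgrad  basal   0.989 0.114  0.974   1.00
2 sgrad  mid     0.935 0.123  0.921   0.956
3 sgrad  apical  1.06  0.123  1.04    1.07
```

Here the stress gradient sits at or below 1 (endocardial flow no longer
exceeds epicardial flow under hyperaemia) and is lowest in the
systolically-acquired mid slice — the structure the simulator is
parameterized to emulate. `run_pipeline(run_config("out"))` runs
simulation, metrics and report end to end and writes CSV/JSON outputs.

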