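---
title: "Evaluating automatic radiotherapy plans: DVH indices, PQM scoring and goal-setting robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating automatic radiotherapy plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planqc)
```

## The problem

Volumetric-modulated arc therapy (VMAT) plans for rectal cancer are judged
on a small panel of dose-volume quantities: how well the prescription
(5000 cGy in 25 fractions here) covers the planning target volume (PTV),
how homogeneous and conformal the target dose is, and how well the bladder,
femoral heads and small bowel are spared. Automatic planning systems differ
in how they turn *clinical goals* — a prescription goal plus mean/max-dose
limits per organ at risk (OAR) — into an optimized dose:

* **script-based planning** executes a fixed optimization recipe from the
  goals as given, so its output tracks the goal setting;
* **hybrid planning** first predicts an *achievable* dose distribution for
  the patient's anatomy (in the clinic, with a deep-learning model trained
  on prior plans), replaces each OAR goal with the corresponding predicted
  dose-volume index, and only then runs the script — personalising the
  goals before optimization.

This package implements the full evaluation methodology for comparing such
strategies — the DVH engine, the conformity/homogeneity indices, the
nine-metric plan-quality-metric (PQM) score, the hybrid goal-update
machinery and the paired statistical protocol — and exercises it end to end
on a synthetic pelvis-phantom cohort, because clinical plan sets are
proprietary. The `analysis/` scripts run the whole comparison; every
computational step lives in the package and is unit-tested against
independent oracles.

## Dose-volume indices

All doses are carried in cGy on a regular (z, y, x) grid (default 2.5 mm
isotropic); volumes are voxel counts. The engine uses a deliberately simple,
exactly testable convention:

* **Dx** — minimum dose to the hottest *x*% of a structure: with the
  in-mask voxel doses sorted descending, element `ceiling(x/100 * N)`.
  Full-voxel counting, no interpolation, no partial volumes.
* **Vx** — percent of the structure receiving at least a threshold,
  inclusive (`dose >= threshold`), so tie behaviour is deterministic.
* **Dmean / Dmax** — arithmetic mean and maximum of in-mask doses.
* The cumulative DVH curve is reported on a dose grid (default bin width
  10 cGy), but indices are always computed from the raw sorted voxel doses,
  never from the binned curve, to avoid binning bias.

The plan-level indices follow the standard definitions:

* **Conformity index** `CI = (TV_RI/TV) * (TV_RI/V_RI)`, where `TV` is the
  PTV volume, `V_RI` the reference-isodose volume and `TV_RI` their
  intersection; `CI = 1` iff the isodose coincides with the target.
* **Homogeneity index** `HI = (D2 - D98) / prescription`; 0 is perfectly
  homogeneous.

**Reference isodose ambiguity.** "The 95% prescription isodose" can be read
as the 4750 cGy surface or as the 5000 cGy surface that must cover 95% of
the PTV. Both readings are defensible; the package defaults to 4750 cGy
(`reference_fraction = 0.95` in `metric_panel()`) and exposes the fraction
as an explicit argument rather than resolving the ambiguity silently.
`V_RI` is counted inside the body contour, since dose outside the patient
is non-physical in the phantom model. An empty reference isodose yields a
flagged `CI = 0` with a warning instead of an error, so cold plans do not
abort a cohort run.

## PQM scoring

Each of nine metrics (PTV D2, HI, CI; bladder D15, D50; femoral head D25,
D40 per side) is scored on a value window: the favorable end earns the
maximum (10 points), the unfavorable end the minimum (0), linear in between
and clamped outside. CI is the one higher-is-better metric; orientation is
an explicit field of the scoring table (`pqm_table()`), never inferred from
the metric name. Linear interpolation is the standard reading of a PQM
"value range" and is what the endpoint/midpoint tests pin down; the plan
total is the sum, in [0, 90]. A plan with a missing metric is reported
unscored (NA total, with a warning) rather than silently dropped or
zero-filled.

```{r pqm}
pqm_table()
```

## Clinical goals and the hybrid update

`preset_goals()` returns the three goal levels used to probe robustness.
All levels prescribe PTV D95 >= 5000 cGy; they differ in the PTV max dose
(easy/moderate/hard: 5500/5250/5100 cGy) and in the mean-dose limits for
bladder (4500/4000/2000 cGy) and each femoral head (2700/1800/900 cGy).

`update_goals()` implements the hybrid step: every goal with role `"oar"`
has its limit replaced by the same index evaluated on the predicted dose;
`"target"` and `"auxiliary"` goals pass through untouched, and the count,
order, kinds and roles of goals are never altered. Replacement is
**unconditional** by default: when the prediction says a preset goal is
unachievable (e.g. a bladder largely overlapping the PTV), the goal is
*loosened* to the achievable value — this is the behaviour that makes the
hybrid method robust to over-ambitious settings, and it is why a
`tighten_only` mode exists as an explicit alternative rather than as the
default. For max-dose OAR goals the predicted *true maximum* is used (a
near-max percentile would be another defensible choice; the true max
matches the engine's Dmax definition and is declared here once).

Auxiliary conformity goals come from `ring_goals()`: max 4200 cGy on body
minus (PTV + 5 mm) and max 3000 cGy on body minus (PTV + 15 mm). "+ 5 mm"
is an isotropic 3-D Euclidean expansion of voxel centers
(`expand_mask()`), computed with an exact distance transform and tested
against exhaustive ball enumeration; the 2-D/3-D and isotropy choice is the
package's own, as margin conventions differ between planning systems.
`additional_goals()` supplies the five extra OAR goals (small bowel
V45Gy < 5% and V15Gy < 30%, femoral head V10Gy < 75% per side, bladder
Dmax < 5250 cGy). Pass rules are strict for printed "<" limits — a tie at
the limit fails — while the prescription goal is inclusive (D95 >= limit).

## The synthetic cohort

`generate_phantom()` builds a schematic pelvis per patient: ellipsoidal
body, a posteriorly centered ellipsoidal PTV (~150-200 cc at the default
80^3 x 2.5 mm grid), a CTV one voxel shell inside it, an anterior bladder,
two lateral spherical femoral heads disjoint from the PTV, and a
superior-anterior small bowel. Anatomy is sized relative to the grid
extent, so the smallest supported grid (40 voxels per axis at 2.5 mm)
still contains every structure. Per-patient jitter and one deliberate
design point — the bladder-PTV overlap fraction is drawn uniformly in
[0, 0.3] and realised by bisection on the bladder position — give the
cohort both easy anatomies and the high-overlap cases where preset bladder
goals are unachievable.

`simulate_dose()` is a parametric stand-in for the planning system's
optimizer output:

* inside the PTV: `prescription * coverage_scale * (1 + hotspot)` plus
  i.i.d. Gaussian noise (`ptv_noise_sd`, as a fraction of prescription);
* outside: the PTV boundary dose decays as `exp(-d / falloff_length)` with
  `d` the Euclidean distance-transform distance to the PTV, multiplied by a
  per-OAR sparing factor in (0, 1] (minimum factor where OARs overlap);
* `coverage_scale` is calibrated per plan so PTV D95 lands within 1% of the
  prescription (bounded iteration; failure to converge is an error, not a
  silent miss). Note that a *uniform* hotspot term is absorbed by this
  calibration, so PTV inhomogeneity across strategies is carried by the
  noise sd.

`predict_dose()` evaluates the same model noise-free — the surrogate for
the knowledge-based dose predictor of the hybrid workflow.

### Strategy presets

`strategy_presets()` ships one parameter set per strategy, chosen once so
that the cohort reproduces the qualitative behaviour of the three planning
methods and then frozen:

| strategy | noise sd | falloff (mm) | sparing (bladder / femur / bowel) |
|---|---|---|---|
| manual | 0.013 | 38 | 0.82 / 0.62 / 0.80 |
| script_easy | 0.025 | 34 | 0.93 / 0.80 / 0.90 |
| script_moderate | 0.013 | 40 | 0.88 / 0.70 / 0.80 |
| script_hard | 0.026 | 48 | 0.45 / 0.42 / 0.55 |
| hybrid_easy | 0.019 | 40 | 0.76 / 0.66 / 0.68 |
| hybrid_moderate | 0.012 | 42 | 0.72 / 0.62 / 0.65 |
| hybrid_hard | 0.0135 | 43 | 0.68 / 0.58 / 0.62 |

The encoded behaviour: script-based planning tracks its goal setting (weak
sparing and a hot, inhomogeneous PTV when goals are easy; aggressive
sparing bought with PTV homogeneity and conformity when goals are hard),
while the hybrid strategies sit close together because their OAR goals are
pinned to the same achievable prediction regardless of the preset level.
Falloff lengths sit in the 34-48 mm range so the 4750 cGy reference
isodose extends one to two voxel shells beyond the PTV — this is what
makes CI land mid-window (~0.85) and respond to the strategy, with the
long script_hard falloff dropping it to ~0.75. The sparing-factor spacing
keeps the per-seed ordering "hard spares at least as well as easy" true
voxel-wise over the whole OAR extent, not just on average.

### What the phantom does and does not emulate

The phantom reproduces the *structure* of the evaluation problem: correct
containment relations, prescription-calibrated target coverage, distance-
driven dose falloff, organ-specific sparing, strategy-dependent homogeneity
and conformity, and a clinically motivated spread of bladder-PTV overlap.
It does not emulate beam geometry, arc delivery, fluence modulation,
heterogeneity corrections, or inter-planner variability; its dose texture
is i.i.d. noise rather than the spatially correlated ripple of real
optimizers. Passing tests therefore validate the evaluation and comparison
machinery and the *direction* of strategy effects under the stated model —
they say nothing about absolute clinical dose levels, and the study's
published cohort values are not reproduction targets.

## Statistical protocol

`paired_compare()` mirrors the study protocol: a Shapiro-Wilk test on the
paired differences (alpha 0.05, configurable) selects a paired t-test for
normal differences and a Wilcoxon signed-rank test otherwise; tests are
two-sided at alpha 0.05, per metric, with no multiple-testing correction
(matching per-metric reporting at p < 0.05). Numerical edge cases are
pinned down explicitly:

* all-zero differences: degenerate, p = 1, never significant;
* constant non-zero differences (Shapiro-Wilk and the t statistic are both
  undefined): routed to the Wilcoxon path;
* Wilcoxon: zero differences dropped; exact null for n <= 25 without ties,
  normal approximation with continuity correction otherwise. The exact path
  is tested against full 2^n sign-assignment enumeration.

Whether the original protocol chose the test per metric or globally is not
stated; per metric is implemented. Robustness is summarised by
`robustness_spread()`: for each metric and method, the spread (max - min)
of the cohort means across the easy/moderate/hard settings; the smaller
spread marks the more robust method.

## Determinism and problem sizes

Every stochastic step takes a seed. Cohorts derive per-patient and per-plan
seeds from one master seed via a fixed linear mixing rule
(`seed * 48271 + index * 7919 + 1 mod 2^31 - 1`), so cohorts are
reproducible bit-for-bit and extensible without reshuffling earlier
patients. The default study size — 20 patients x 7 strategies on an 80^3
grid — was chosen as the smallest cohort where the paired comparisons are
decisively powered (systematic PQM differences of 7-14 points against
~5-point patient sd); the test suite uses 40-44 voxel grids for unit-level
checks. `analysis/` scripts and `scripts/acceptance.R` both run the
20-patient cohort in well under a minute.

## Known limitations

* No DICOM import/export: no RT-DOSE/RT-STRUCT reader is bundled, and the
  internal `dose_grid`/`structure_set` containers are the documented
  mapping target for external data.
* The dose model has no optimizer: "hybrid" and "script" differ only
  through their calibrated parameter presets, which is sufficient for
  evaluating the *methodology* but not for studying optimizer internals
  (cold/hot-spot suppression, objective weighting) — those are explicit
  non-goals.
* Full-voxel DVH conventions mean indices on very small structures (tens of
  voxels) are step functions of the data; the CTV (eroded PTV) is carried
  for completeness but not scored.
* CI is quantized by the voxel lattice: the reference isodose grows in
  discrete shells around the PTV, so per-patient CI moves in visible steps
  where a continuous-dose system would move smoothly.
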