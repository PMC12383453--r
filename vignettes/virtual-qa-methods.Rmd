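---
title: "Virtual patient-specific QA for SRS arcs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual patient-specific QA for SRS arcs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-isocenter stereotactic radiosurgery (SRS) of multiple brain
metastases is delivered with volumetric modulated arcs whose multileaf
collimator (MLC) patterns are extremely modulated. Such arcs fail
measurement-based patient-specific QA (PSQA) — summarized by the gamma
passing rate (GPR) at 3%/1 mm with a 10% dose threshold, global
normalization, and a 95% per-arc action limit — more often than standard
treatments. `arcqa` implements a *virtual QA* pipeline: it predicts an
arc's GPR from plan-complexity features alone, so that likely failures can
be reoptimized before any measurement time is spent.

The package covers the whole chain: RTPLAN (dynamic-arc subset) I/O,
eighteen complexity metrics, a 2D gamma engine, a calibrated synthetic
cohort generator, correlation-based feature decimation, a weighted
random-forest GPR regressor validated under a hybrid
time-series/stratified protocol, threshold-limit calibration, and
regression/classification/interpretability/workload evaluation.

## Delivery-time model

RTPLAN stores geometry and cumulative meterset, not time. Per segment
(between adjacent control points) we reconstruct

$$t_k = \max\!\left(\frac{\Delta MU_k}{DR_{\max}}\,60,\;
\frac{|\Delta\theta_k|}{GS_{\max}},\;
\frac{\max_i |\Delta x_{ik}|}{10\,v_{\max}}\right),$$

i.e. the slowest axis is the bottleneck and runs at its limit. Default
limits are Edge-like and configurable (`machine_spec()`): 1400 MU/min,
4.8 deg/s, 2.5 cm/s, with the HD120 leaf layout (14x5, 32x2.5, 14x5 mm =
220 mm). Dose rate, gantry speed and leaf speeds follow by division; all
dynamic metrics derive from these.

## The eighteen features

Two static parameters (`Area`, `MUOverDosePerFraction`), six dynamic
parameters (means and modulations of MLC speed, dose ("repetition") rate
and gantry speed), and ten aperture metrics (gap quartiles, small-aperture
score SAS10, tongue-and-groove index, modulation complexity score MCS,
total modulation index, beam irregularity BI, beam modulation BM, edge
metric, leaf travel per arc length). Conventions the upstream literature
leaves open, decided once here:

* **Segment attribution.** Dose is delivered *between* control points, so
  per-control-point quantities are combined into segment values by
  averaging the two bounding control points, weighted by the segment
  meterset increment.
* **Closed pairs.** A pair is closed when its gap is at most `min_gap`
  (default 0.5 mm) or it lies outside the Y-jaw aperture; closed pairs are
  excluded from all aperture statistics. "In-field" leaves for a segment
  are pairs open in at least one bounding control point.
* **Gap pooling.** Quartiles and SAS10 pool all open gaps over all control
  points unweighted (an MU-weighted variant is available behind
  `mu_weighted = TRUE`).
* **Edge metric.** Uses exposed leaf-*side* edges only (side steps between
  adjacent pairs plus the outer horizontal edges), not leaf tips, per its
  definition as MLC side length over aperture area.
* **Modulation index.** The exceedance curve z(f) of in-field leaf speeds
  is integrated over f in [0, 2] standard deviations by trapezoid on a
  fixed 0.01 grid, each observation weighted by
  `1 + |dDR|/DR_max + |dGS|/GS_max`. Note z is a step function with jumps
  of order 1/n_obs, so agreement with finer grids is limited by
  (0.01/2) x total variation, about 5e-3 for toy arcs.
* **Reversal symmetry.** All metrics are invariant to reversing the
  control-point order except MITotal, whose segment weights pair with
  inter-segment differences; it is invariant for symmetric arcs, which is
  what the test suite asserts.

## Gamma engine

`gamma_map()` is a plain 2D global-gamma search: for each reference pixel,
the minimum over a disk (radius 3 x DTA) of
$\sqrt{(\Delta D/\Delta D_{tol})^2 + (\Delta r/DTA)^2}$, with the
evaluated image sampled at 1/10-pixel steps by bilinear interpolation.
Global normalization uses the reference maximum (the normalization point
is not published for the commercial system; equivalence with it is not
claimed — the proprietary EPID dose prediction is out of scope). The C++
kernel visits offsets in order of increasing distance and stops when the
distance term alone exceeds the current best, which makes it exact, not a
heuristic. Synthetic images default to 1 mm spacing (the real EPID panel
has 0.336 mm pixels; that resolution is tractable but slow at desk scale).

## Synthetic cohort: what it emulates, and what it does not

No clinical data are distributed, so all pipeline stages are exercised on
a synthetic cohort (`generate_cohort()`) built to match the *published
statistical structure* of a 4-year, 592-patient, ~2430-arc SRS program:

* patients occupy consecutive date blocks between 2020-12-01 and
  2024-12-31; arc counts per patient are drawn from 2-6 (mean 4.10);
* each arc has a latent complexity level in [0, 1], Beta(3.5, 1.8)
  distributed (left-skewed: most SRS arcs are complex) plus a mild linear
  drift (+0.12 over the date range) so the time-series split is genuinely
  non-exchangeable;
* `sample_arc()` maps the level monotonically onto geometry: smaller mean
  gaps and areas, more leaf travel and speed modulation at higher level.
  All modulation sources ramp to zero at level 0, whose limit is a static
  rectangular aperture — the only aperture with MCS = 1, since
  leaf-sequence variability is scale-invariant and any residual tip noise
  caps MCS near 0.8 regardless of its amplitude.

Measured GPRs come in two modes. The default **statistical mode** draws a
failure magnitude from a logistic-normal law,

$$d = d_{\max}\,\mathrm{logit}^{-1}(\mu + s + \sigma\varepsilon),
\qquad GPR = 100(1-d),$$

where the planted score $s$ loads negatively on standardized `Area` and
`Median MLCGap` and positively on `BM` and `MITotal` (standardization uses
committed reference moments from the default generator, so identical
feature rows always get identical GPR laws). $d_{\max} = 0.20$ was chosen
at design time so the simulated support matches the published distribution
(no arcs below 80%); the two remaining constants $(\mu, \sigma)$ were
fitted once by nested bisection to the published marginal (median 98.3%,
IQR 4.5 points) and committed as defaults. The resulting cohort reproduces
the published interval proportions (>=95 / 90-95 / 85-90 / 80-85) within
two percentage points each.

The **physical mode** builds planned and error-perturbed fluence images
(meterset-accumulated aperture masks, 1.5 mm Gaussian penumbra) and runs
the actual gamma engine; it exists to exercise the dose-comparison path
end to end and is priced for cohorts of tens of arcs, not thousands.

A green test on this cohort establishes that the *pipeline* recovers a
planted complexity-outcome relation under realistic marginals and temporal
drift. It does not establish clinical accuracy: the synthetic GPR law has
no EPID physics, no couch/gantry sag, no output drift beyond the planted
trend, and its feature-outcome link is by construction simpler than
reality. The published clinical headline numbers (test MAE 2.6%, R^2
0.27, AUC 0.85) are therefore *not* acceptance targets; the suite asserts
the arithmetic/analytic quantities and calibrated-simulation bands
instead.

## Feature decimation

Spearman correlations (rank-based, average ranks on ties) feed Ward
agglomeration on the distance 1 - |r_s|, cut at height 0.1 so features
with |r_s| >= 0.9 merge (two singletons merge at exactly their distance).
Ward linkage on a non-Euclidean precomputed distance matrix is a heuristic
use of the Lance-Williams update — implemented as standard
Ward-on-distances (`hclust(method = "ward.D2")`) because that is what the
published description prescribes. The representative of each cluster is
its medoid (largest mean |r_s| to the other members, ties broken in
canonical feature order); a `"preset"` rule returns the fixed published
fifteen-feature selection (dropping `Q1 MLCGap`, `SAS10`, `MCS`), since
the published choice within a perfectly correlated pair is not derivable
from any symmetric rule.

## Training protocol

* **Hybrid split.** Rows sorted by treatment date (ties by arc id); the
  newest 20% form the test set; the oldest 80% are split 80/20 into
  training/validation stratified on GPR deciles (bins under 2 rows merged;
  validation rows apportioned by largest remainder, which reproduces
  1555/389/486 exactly from 2430 rows).
* **Sample weights.** `w = 10^(k (0.1 - GPR))` with GPR a fraction; the
  printed weighting formula is typographically ambiguous, so the literal
  reading is the default (`k = 1`) and the strength `k` is exposed.
* **Robust scaling.** `(f - f50) / (f75 - f25)` with percentiles from the
  fitting partition only; inside cross-validation every fold fits its own
  scaler (the per-fold statistics are exposed for the leakage audit).
* **Random forest.** No tree-ensemble learner exists in the target
  environment, so the package ships a weighted CART forest in C++:
  bootstrap bagging, per-split mtry subsampling, weighted-SSE splits,
  min-split/min-leaf/max-depth controls, deterministic given a seed. The
  default search space (trees 100-1000, depth unbounded or 5-30, min leaf
  1-20, min split 2-20, features sqrt/log2/0.3-1.0) is a committed
  default — the published appendix with the tuned values is not available.
  Tests run the search at reduced iteration counts and tree budgets; this
  scales the compute, not the logic.
* **Threshold limit.** On validation predictions, candidates are all
  midpoints between distinct predictions; among those with sensitivity
  >= 0.90 and specificity >= 0.50, the maximum-specificity (then lowest)
  threshold is returned; infeasibility is flagged rather than silently
  relaxed. Arcs are flagged "fail" when predicted GPR < TL (strict).

## Evaluation

Residuals are measured minus predicted, so the documented overestimation
of low GPRs appears as negative residuals in the lowest quartile. ROC uses
the negated prediction as score with trapezoidal AUC (equal to the
concordant-pair probability, which the tests assert by brute force);
average precision uses step interpolation, the convention under which an
always-flag classifier scores exactly the fail prevalence. The workload
model prices every flagged arc at one 10-min reoptimization and every
missed failure at one 60-min replanning-and-measurement, relative to a
baseline of 60 min per true failure:

$$100\left[1 - \frac{t_{reopt}\,(p\,Se + (1-p)(1-Sp)) +
t_{replan}\,p\,(1-Se)}{t_{replan}\,p}\right]$$

This closed form is a reconstruction (the published appendix derivation is
unavailable); it reproduces the published 56% at the published operating
point (p = 0.25, Se = 0.93, Sp = 0.56), which is what committed it.

## Numerical choices and degenerate inputs

Quantiles are linearly interpolated (R type 7) throughout. A zero-IQR
feature scales to 0 with a warning. A fully closed arc is rejected by the
gap/aperture metrics and routed into the `failures` attribute of
`extract_features()` rather than aborting the batch. A control point with
no open pairs is skipped from meterset-weighted means (segments keep the
defined endpoint). Zero-duration segments (no MU, no motion) are an error.
LSV with fewer than two in-field pairs, or zero position range, is defined
as 1. RTPLAN round-trips are exact to 0.01 mm in positions and 1e-6 in
meterset weights, the precision the writer emits.

## Known limitations

* The DICOM codec reads/writes the dynamic-arc subset in Explicit VR
  Little Endian with defined-length sequences only; it is not a general
  DICOM implementation (files it writes parse cleanly in standard tools).
* The per-arc treatment date is carried in BeamDescription; RTPLAN has no
  per-beam date attribute.
* Ward-on-1-|r_s| inherits the conceptual caveat above; the dendrogram
  heights are not variance decompositions.
* MITotal and the tongue-and-groove index follow condensed definitions;
  the original formulations in their source papers may differ in detail.
* The physical GPR mode is a fluence-level emulation, not an EPID dose
  prediction.
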