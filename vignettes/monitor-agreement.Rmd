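---
title: "Methods: agreement and trending analysis for paired cardiac output monitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement and trending analysis for paired cardiac output monitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagree)
```

`coagree` implements the statistical pipeline of a two-monitor
method-comparison study in hemodynamics: a reference cardiac output monitor
(thermodilution-calibrated) and a test monitor (pulse-contour) observe the
same subjects at baseline and at post-resuscitation time points, and the
analysis asks whether the test monitor agrees with the reference in value
and in trend. This vignette documents the statistical model, the
measurement-rejection rules, the synthetic-data generator used to validate
the pipeline, and the design decisions taken where the underlying
conventions are genuinely open.

## Units and the unit of analysis

All quantities are body-surface-area-indexed: cardiac index CI (L/min/m²),
stroke volume index SVI (mL/m²), systemic vascular resistance index SVRI
(dyn·s·cm⁻⁵·m⁻²), stroke volume variation SVV (%), heart rate HR
(beats/min), systolic pressure SBP (mmHg). The unit of comparison is the
**paired sample**: one replicate-resolved value per monitor for one subject
at one time point. Time points are `baseline`, `rosc15`, `rosc30`,
`rosc60` (15/30/60 minutes after return of spontaneous circulation); pooled
analyses combine all pairs across time points, which ignores within-subject
correlation — deliberately, because that is how such studies conventionally
report, and the per-time-point strata are always reported alongside.

## Measurement quality control

Three rules, all implemented as *flags* on retained pairs rather than
deletions, so each exclusion is auditable and reversible
(`pair_and_filter()`):

1. **Replicate discrepancy** (`resolve_replicates()`). The reference
   monitor's replicate injections are scanned in order over overlapping
   consecutive pairs (1,2), (2,3), …; the first pair whose CI readings
   agree within 10 % — relative discrepancy |a−b|/mean(a,b) — is averaged,
   and all other variables are averaged over the same two replicates (those
   are the injections retained). The scan denominator is the pair mean: the
   symmetric convention standard for repeatability. If no pair agrees
   within `max_replicate_draws` (default 6, a cap that keeps simulation
   loops bounded) the group is `replicate_unresolved` and excluded from
   analysis. The test monitor's two simultaneous readings are always
   averaged as-is: the repeat-injection rule is a property of the
   thermodilution protocol, not of the pulse-contour device, and applying a
   10 % agreement scan to a monitor whose dispersion is of order 30 % would
   discard most of the dataset. The scan's scope is nevertheless
   configurable (`qc_policy(discrepancy_methods=)`).
2. **Systolic-pressure discrepancy.** A pair is flagged when
   |SBP_ref − SBP_test| / SBP_ref exceeds 10 % (strictly greater). The
   denominator is the reference value, consistent with expressing all
   percentages relative to the reference method.
3. **dP/dt resonance.** A baseline test-monitor dP/dt strictly above 1.7
   indicates possible waveform resonance, a property of the catheter-
   transducer system rather than of one measurement; the flag therefore
   covers **all** of that subject's samples. The other defensible reading —
   discarding only the baseline measurement — is recoverable by filtering
   on the flag per time point, which is why flags are kept per sample.

## Agreement statistics

For a variable with paired values, `pair_differences()` defines
d = ref − test (the reference-minus-test orientation used in the field's
agreement tables; configurable). `bland_altman()` then reports:

* bias = mean(d); SD with the n−1 denominator;
* 95 % CI of the bias: bias ± t₀.₉₇₅,ₙ₋₁·SD/√n;
* limits of agreement: bias ± 1.96·SD, with **1.96 as a fixed constant**
  (the conventional large-sample formula), not a t quantile;
* percentage limits of agreement: the same construction applied to the
  per-pair percent differences 100·d/ref. Percent limits computed instead
  as 100·LoA/mean(ref) are *not* equivalent and are not used: the per-pair
  definition is the only one consistent with expressing each difference
  relative to the reference measurement that produced it;
* per-method coefficient of variation, 100·SD/mean of that monitor's
  values;
* percentage error, 100·1.96·SD(d)/((mean_ref+mean_test)/2), with an
  acceptability verdict against the conventional 30 % bound
  (`percentage_error()`).

`paired_comparison()` gates on a Kolmogorov–Smirnov test of each monitor's
values against a normal with estimated moments at α = 0.05 (the global
significance level): both pass → paired *t* + Pearson; otherwise Wilcoxon
signed-rank + Spearman. This is the statistically standard pairing of
parametric/non-parametric procedures; the gate outcome is part of the
result so either branch is auditable. Degenerate inputs are handled
explicitly: exactly constant differences make the *t* statistic undefined,
so a zero constant reports p = 1 and a non-zero constant p = 0; constant
differences reaching the signed-rank branch are an error, since the test is
undefined there.

`back_calculate_hr()` recovers the internal heart rate a pulse-contour
monitor used, HR = CI·1000/SVI, and `hr_backcalc_comparison()` runs the
full paired machinery of the reference monitor's measured HR against it
(orientation: reference − calculated). A monitor that drops undetected
beats shows a calculated HR below the measured one.

## Polar-plot trending analysis

`consecutive_changes()` differences each variable between consecutive
*available* time points per subject (a missing middle time point is
bridged). `polar_transform()` maps each (Δref, Δtest) to a vector: the
angle is measured from the 45° identity line of the change–change plane
(the polar axis), and points with negative mean change are rotated 180°
onto the upper half circle, so angles lie in (−90°, +90°]. The radius is
|Δref + Δtest|/2 — the mean change, not the Euclidean norm, so it carries
the variable's units and matches the half-circle plotting convention.

Numerical conventions: a pair of exactly zero changes has angle 0 and
radius 0 by definition; an angle landing exactly on −90° is mapped to +90°
(the same line after half-circle identification); the concordance band is
closed (|angle| = 30° counts as concordant) while the exclusion zone is
open (radius exactly at the threshold is included, exclusion is strictly
below). The exclusion threshold is 10 % of the overall *reference*-method
mean — not the pooled mean of both methods, matching the convention of
anchoring percentages to the reference — and an explicit absolute radius
can override it. The mean angular deviation is the arithmetic mean of the
signed angles; no circular statistics are needed because the half-circle
construction confines angles to a single 180° arc.

## The synthetic-data generator

`simulate_measurements()` emulates the design such studies share: 24
subjects by default, all measured at baseline, each achieving ROSC with
probability 0.5 and then contributing the three post-ROSC time points.
The generative model, chosen so that every downstream statistic has a
closed-form population value:

* **Latent trajectory.** Subject i has a log-normal baseline cardiac index
  B_i (mean 4.5, SD 1.0 L/min/m²; log-normal because hemodynamic quantities
  are positive and their noise is CV-scaled). The latent CI at time t is
  B_i·m_t with fixed multipliers m = (1, 0.75, 0.85, 0.95): post-arrest
  myocardial depression with gradual recovery. The multipliers are a
  statistical skeleton, not a dynamical model — only the induced
  change-structure matters downstream.
* **Reference monitor.** Each replicate is latent × unit-mean log-normal
  noise with CV 0.10, consistent with an overall observed dispersion in the
  high-20s percent once between-subject and between-time-point spread is
  included. Replicates are drawn until two consecutive readings agree
  within 10 % (at most 6), reproducing the repeat-injection protocol.
* **Test monitor.** Its signal is scale·(f·latent + (1−f)·independent) +
  bias, observed through two replicates with CV 0.25. The *fidelity* f
  (default 0.3) is a convex mixture weight with an independent draw of the
  same marginal distribution: f = 1 gives a perfectly tracking monitor,
  f = 0 an uninformative one, and intermediate values span the near-zero
  correlations reported for pulse-contour devices in unstable
  circulations. Default bias −0.5 L/min/m² (the test monitor reads lower),
  default scale 1.
* **Coherence of the secondary variables.** Per monitor, SVI ≡ 1000·CI/HR
  (so the heart-rate back-calculation identity is exact in the generator)
  and SVRI follows the resistance identity 80·(MAP − CVP)/CI with
  MAP ≈ 0.75·SBP and CVP = 5 mmHg. Latent HR is ~N(150, 20) per subject
  with 5 % per-time-point jitter; SBP ~N(90, 15); SVV log-normal around
  17 % with CV 0.3. No deeper physiology is modelled: positivity and the
  resistance identity are the only constraints that matter downstream.
* **QC triggers.** Each monitor observes SBP with an independent 4 %
  jitter, making the 10 % SBP-discrepancy rule fire at a realistic
  single-digit rate, and dP/dt is log-normal (meanlog log 1.2, sdlog
  0.272), putting roughly 10 % of subjects above the 1.7 resonance limit.

`expected_summaries()` returns the analytic population values (bias,
difference SD, percentage error, pooled means, Pearson correlation)
assembled exactly from these variance components, pooling time points with
weights (1, p, p, p); it neglects only the small conditioning effect of the
replicate-agreement scan and the positivity clamps (both far below the
tolerances used anywhere). The expected trending concordance has no
convenient closed form and is computed by direct Monte Carlo on the delta
distribution — independently of the pipeline code, with the RNG state saved
and restored.

What the generator does **not** emulate: arterial waveforms, thermodilution
curves, CPR physiology, drift or recalibration of either monitor,
heteroscedastic (magnitude-dependent) disagreement, and the exact per-time-
point attrition pattern of any particular study. Passing recovery tests
therefore shows the *statistical machinery* is correct under the stated
model, not that any real device behaves this way.

## Numerical and testing choices

* Determinism: one seed drives the entire generator; analysis stages are
  seed-free, and report files are byte-stable (no timestamps in CSV
  output).
* Parameter-recovery tests run at 500 subjects over 20 seeds, where the
  bias standard error (≈0.04 L/min/m²) sits comfortably inside the ±0.1
  tolerance; oracle-equivalence tests compare 1000 random small instances
  against a naive two-pass Bland–Altman implementation (10⁻¹²) and a
  rotate-by-45° polar oracle (10⁻⁹). These sizes keep the whole suite
  around a minute on one core while leaving large statistical margins.
* Strata with fewer than 2 pairs (agreement) or 3 pairs (paired tests) are
  reported as unavailable rather than dropped, and an input emptied by QC
  is an explicit error naming the rules responsible.

## Known limitations

* Pooling pairs across time points ignores within-subject correlation; no
  repeated-measures adjustment of the limits of agreement is offered, by
  design, because the implemented conventions are the ones this literature
  reports.
* The KS normality gate uses estimated moments without a Lilliefors
  correction, making it conservative (slow to reject normality) at small n
  — again matching common practice in these studies.
* The generator's mean-of-percent-differences bias (reported as
  `bias_pct`) is one of several possible "bias as a percentage"
  definitions; it is labelled explicitly wherever it appears.
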