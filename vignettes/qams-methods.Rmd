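---
title: "Single-marker quantification of nucleosides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification of nucleosides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamsr)
```

## The problem

Targeted LC-MS/MS assays of natural products routinely quantify a family
of structurally related compounds — here nine nucleosides (adenosine,
cytidine, guanosine, inosine, uridine and their 2'-deoxy counterparts)
in dried *Tricholoma matsutake* fruiting bodies. The conventional
external standard (ES) route needs an authentic standard and a full
calibration curve for every analyte on every run. The single-marker
route (often called QAMS, quantitative analysis of multiple components
by a single marker) calibrates only one *internal reference* analyte —
guanosine in the bundled panel — and carries every other analyte through
a fixed, instrument-portable **relative correction factor** (RCF).

## The model

Over the linear range the detector response is proportional to
concentration, `f = A / C` with peak area `A`. For a target analyte `m`
and the reference `k`, both present in one standard solution, the RCF is

```
f_km = (C_k * A_m) / (C_m * A_k)
```

which under zero-intercept linear responses is exactly the ratio of
detector sensitivities (slopes) `a_m / a_k`. In an unknown sample the
reference is quantified by its own external-standard curve and each
target is back-calculated as

```
C_m = (C_k * A_m) / (f_km * A_k)
```

The two equations are algebraic inverses: an RCF computed from a
standard and immediately applied to that standard returns the input
concentration bit for bit, and `quantify_qams()` is tested against
`quantify_es()` under exactly those conditions.

Note the convention: `f_km` as implemented multiplies the *denominator*
of the back-calculation, so a target that is detected more sensitively
than the reference has `f_km > 1`. Writing the RCF as a ratio `f_k/f_m`
of response factors would give the reciprocal; the algebraic form above
is the one that is self-consistent with the back-calculation and with
the bundled three-column RCF table (e.g. inosine's RCF of about 1.9
against a slope ratio 11955 / 6564 of about 1.8), and it is the form
this package implements.

### Assumptions, and when RCFs are trustworthy

- **Linearity with negligible intercept.** The RCF is computed from raw
  areas and concentrations, never from fitted curves, so any intercept
  leaks into the per-level RCF as `b / C` bias. At the top of the
  dilution ladder this is negligible; at the lowest level it can exceed
  20% for analytes with large intercepts relative to their slope. The
  package therefore treats RCF estimation as a high-signal operation,
  and the simulator's accuracy claims (RCF means within 5% of true slope
  ratios) are stated for zero-intercept truth, which isolates the
  regime the method assumes.
- **Stable relative sensitivity across instruments.** The cross-column
  summary (`summarize_rcf()`: mean, n−1 SD, percent RSD over columns) is
  the robustness check: per-column RCFs from three different C18 columns
  in the bundled study spread by only 2.7–4.9% RSD.
- **Known peak identity.** The package starts at integrated peak areas;
  retention-time alignment, peak detection and spectral processing are
  out of scope.

## Stages and their parameters

| Stage | Function(s) | Key parameters (units, default) |
|---|---|---|
| Calibration | `fit_calibration()`, `quantify_es()` | unweighted OLS of area on conc (ng/mL); linear range = span of fitted points |
| LOD/LOQ | `estimate_lod_loq()` | S/N thresholds 3 and 10; log–log interpolation; injection volume (µL) converts ng/mL to on-column ng (÷1000) |
| RCF | `compute_rcf()`, `rcf_table()`, `summarize_rcf()` | per-column RCF = unweighted mean over shared ladder levels; SD is the sample (n−1) estimator |
| Quantification | `es_quantify_table()`, `qams_quantify_table()` | prep: mass (g), volume (mL), dilution; content (µg/g) = conc × volume × dilution / mass / 1000 |
| Validation | `rsd()`, `recovery_pct()`, `one_way_anova()`, `validation_report()` | schemes selected by explicit `design` labels, not timestamps |
| Agreement | `cos_theta()`, `similarity_report()` | pairwise deletion of censored slots; display rounding 5 decimals |

Unit conventions are fixed and explicit: stocks in mg/mL, working
solutions in ng/mL, contents in µg/g dry weight. Every conversion
(including the 10^6 at the stock boundary of the dilution ladder and the
ng→µg in the content formula) is written out once, in one place.

### Numerical and policy choices

- **Unweighted OLS.** The calibration reports a single `(a, b, r²)`
  triple per analyte; no 1/x or 1/x² weighting is offered. Nonlinear
  (quadratic, 4PL) models are deliberately out of scope.
- **Log–log S/N interpolation.** S/N spans orders of magnitude across a
  2.5–100× dilution ladder; interpolating `log(S/N)` against
  `log(conc)` is stable and reduces to linear interpolation whenever
  S/N is proportional to concentration. Outside the measured span the
  two nearest points are extrapolated, with a warning.
- **Censoring is a flag, never a number.** A below-LOQ or negative
  back-calculated result carries a reason (`below_loq`, `below_range`,
  `missing_area`) and no numeric value, so it can never contaminate a
  mean. The below-LOQ comparison is strict (`<`): a value exactly at
  the threshold is retained.
- **Negative back-calculations are censored, not clamped to zero**, so
  downstream statistics exclude them explicitly.
- **Pairwise deletion in the cosine.** When either method lacks a value
  for a sample, the pair is dropped. In the bundled study censoring
  always co-occurs in both methods, where deletion and zero-filling
  coincide (asserted in the tests); deletion is the safer general
  policy when they do not.
- **Single-marker dependency rule.** If the reference analyte is
  missing or censored in a sample, every target in that sample is
  censored (`missing_area`): the marker is the sample's only anchor.
  One bad sample censors that sample, never the run.
- **Stored precision exceeds displayed precision.** All CSV outputs are
  full precision; the paper-style rounding (contents 1 decimal, RCF 3,
  cos θ 5, RSD 2) is applied only in human-readable summaries. Rounded
  intermediates are exactly how last-digit inconsistencies creep into
  published tables, and the bundled study itself shows a few cells that
  cannot be reproduced from its own rounded neighbours.

## The synthetic-data generator

`simulate_areas()` emulates what the downstream statistics actually
consume — integrated areas — not chromatograms:

- **Response**: `area = (slope × column_factor × conc + intercept)`,
  floored at zero, per analyte and column.
- **Noise**: multiplicative log-normal, `× exp(N(0, cv))`, default
  `cv = 0.02` (a typical targeted-MS injection CV). Multiplicative
  rather than additive because observed precision is roughly constant
  in percentage terms across 30-fold concentration ranges.
- **Column drift**: per-analyte multiplicative gains. The default
  profile simulates three columns whose target-analyte sensitivities
  differ by ±5% in a fixed cyclic pattern (the reference's gain is 1),
  emulating manufacturing differences between C18 columns (carbon load,
  surface area, end-capping) without modelling retention. The pattern
  is deterministic so the cross-column RSD band it induces (≈5%) does
  not depend on the noise seed.
- **Dilution ladder**: stocks (mg/mL) → solution I (1:100) → II (1:100)
  → III–VIII (2.5, 5, 10, 20, 50, 100× from II). Calibration and RCF
  standards use levels II–VIII; solution I sits 100× above the linear
  range top and is excluded from fitting.
- **Ground truth**: per-sample true contents drawn uniformly within
  per-analyte ranges; the defaults span the uncensored contents of the
  bundled ten-batch study, so simulated specimens live on a realistic
  scale. A study uses 10 specimens by default, mirroring the bundled
  batch count.
- **Determinism**: the seed is mandatory and the draw order fixed;
  identical configurations give bit-identical peak tables.

What the simulator does *not* reproduce: retention-time behaviour,
co-elution, carryover, detector drift over a sequence, and
heteroscedastic S/N structure near the noise floor. Passing tests on
simulated data therefore demonstrate the *algebra and statistics* of the
pipeline (recovery of truth in the noiseless limit, ES/QAMS equivalence
under the method's assumptions, RCF robustness under gain drift), not
instrument performance. Instrument-dependent figures — r², LOD in ng,
recovery percentages — can only come from real injections, which is why
the bundled study ships them as data rather than the package recomputing
them.

## Design decisions that were genuinely open

- **RCF reduction over levels.** Whether a published per-column RCF is a
  single-level measurement or a ladder average is usually unstated; this
  package uses the unweighted mean over shared levels, which is unbiased
  under multiplicative noise in the high-signal regime and keeps every
  level's evidence.
- **ANOVA structure for extraction comparison.** The extraction
  comparison (ultrasonic vs boiling-water, n = 3 each) is run as a plain
  one-way ANOVA per analyte on user-grouped replicates;
  `one_way_anova()` takes explicit groups rather than guessing a design
  from metadata. The bundled extraction table stores mean ± SD with
  n = 3, treating the published "±" as an SD.
- **Validation schemes by label.** Intraday/interday schedules vary
  wildly between labs ("every 4 h for 16 h", "twice in the morning for
  three days", ...). A `design` column (`intraday`, `interday`,
  `repeatability`, `recovery_native`, `recovery_spiked`) generalises
  all of them without a timestamp parser.
- **m/z values are stored verbatim.** The panel records precursor and
  product m/z as configured on the instrument (negative-mode [M−H]⁻
  transitions); the package does not recompute adducts.
- **Command-line surface.** `qams_main()` is an exported R function
  dispatching `calibrate`, `rcf`, `quantify`, `validate`, `compare`,
  `simulate` and `fixtures`; the installed `exec/qams` script is a
  two-line wrapper. Options are plain `--key value` pairs parsed in
  base R; `simulate` refuses to run without an explicit `--seed`.

## Problem sizes used in the test suite

The suite runs entirely on generated data and the bundled CSVs: studies
of 3–10 specimens, ladders of 7 levels on 1–3 columns, 1000-draw
Monte-Carlo checks of the noise CV, and 10–25-instance property loops
for the statistical oracles. The whole suite completes in a few seconds.

## Known limitations

- No raw-file/mzML handling, peak detection or integration.
- Only simple linear calibration; no weighting, no nonlinear models.
- RCF accuracy degrades when intercepts are material at the working
  concentration; the package reports what the data give and leaves the
  judgement (e.g. restricting ladder levels) to the analyst.
- The cosine measures proportional agreement only; a constant relative
  bias between methods is invisible to it by design.
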