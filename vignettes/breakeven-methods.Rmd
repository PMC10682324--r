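---
title: "Methods: break-even pricing for DL-CAD lung-nodule reading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: break-even pricing for DL-CAD lung-nodule reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadbreakeven)
```

## The question

Commercial deep-learning computer-aided detection (DL-CAD) systems mark
candidate lung nodules on chest CT. In a lung cancer screening programme
the immediate, monetisable benefit of such software is radiologist time:
if CAD changes how long a read takes, the saved (or added) minutes have a
salary value that can be weighed against the software's price. This
package implements that break-even calculus for three reading paradigms:

* **concurrent reader** — CAD marks are shown during the read; published
  studies report time savings;
* **second reader** — the radiologist reads unaided first, then reviews
  CAD output; this always adds time, so no break-even exists;
* **pre-screening reader** — CAD triages away scans it deems nodule-free
  so a radiologist never opens them; no timing studies exist, so the
  saving is derived from nodule prevalence.

The pipeline has four stages: pooling of published reading times, the
pre-screening scenario derivation, the break-even economics, and
reporting. A simulator with known ground truth makes the pooling stage
testable end-to-end without external data.

## Evidence corpus

The packaged corpus (`load_corpus("table1")`) transcribes the published
study-level evidence: 8 observations (2 second-reader, 6
concurrent-reader, one study contributing two reader rows). Times are
stored as reported — mean ± SD, median (IQR), or a bare mean — together
with the signed difference (with-CAD − no-CAD; negative means saved) and
its CI when given. Validation enforces positive times, coherent
dispersion encodings, ordered CIs, and the sign convention per reading
mode. One study reports the dispersion of its *difference* as an IQR;
that is not a CI and is deliberately not stored as one.

## Pooling model

Median/IQR summaries are placed on the mean/SD scale with the Wan-type
moment estimators: mean ≈ (q1 + median + q3)/3 and SD ≈ (q3 − q1)/1.35
(or the sample-size-dependent denominator
2·Φ⁻¹((0.75n − 0.125)/(n + 0.25)) when n is known). Reported CIs become
standard errors via se = (hi − lo)/(2·z). Reader rows within a study are
averaged first so one cohort enters the pool once (switchable to
`treat_as_independent`).

Two pooling methods are exposed:

* **unweighted** (default): arithmetic mean of the k study estimates
  with a t-based 95% CI. This is the default because two of the six
  concurrent-reader observations carry no dispersion at all, so a
  complete inverse-variance pool does not exist without imputation.
* **DerSimonian–Laird**: Q = Σwᵢ(yᵢ − ȳ_FE)², τ² = max(0, (Q − (k−1)) /
  (Σw − Σw²/Σw)), re-weighting by 1/(seᵢ² + τ²), normal 95% CI. It
  requires every effect to have a standard error; a conservative option
  imputes missing SEs with the largest observed SE in the arm (off by
  default). The implementation is checked against `metafor::rma(method
  = "DL")` to 1e-10 in the test suite.

A deliberate caveat, asserted rather than hidden in the tests: at small
k with substantial heterogeneity the z-based DerSimonian–Laird interval
is known to undercover, so the calibration requirement (95% CI coverage
within [0.92, 0.98] over seeded replicates) is asserted for the default
t-based unweighted method; the DerSimonian–Laird route is checked for
unbiasedness and against the reference implementation instead.

The published pooled values (162 s without CAD, 95% CI 111–212; 118 s
with concurrent CAD; saving 77 s, 95% CI 47–107) **cannot be re-derived
from the printed summaries**: the original pooling weights are not
recoverable (the plain mean of the printed no-CAD times is ≈182–196 s
depending on reader handling). They are therefore carried as
authoritative inputs (`pooled_from_printed()`, shipped in the default
settings) and drive the economics in replication mode, while the pooling
machinery itself is validated by closed forms, properties, an external
reference, and simulation.

## Pre-screening scenarios

If a fraction *p* of screenees have a detectable nodule and the CAD
rules out a fraction *r* of the nodule-free scans (never a positive
one), the radiologist's workload drops by *r*(1 − *p*), and a scan never
read saves its whole reading time. With the published inputs
(prevalence 22–51%, *r* = 0.80) this brackets the reduction at 62%
(best case) and 39% (worst case). The saving and its CI scale the
pooled no-CAD time linearly; no uncertainty on *p* or *r* is propagated
— the best/worst pair is the sensitivity analysis.

Two reproduction subtleties, both kept explicit rather than guessed
away:

* the published derivation applies the *percent-rounded* reductions
  (0.62, 0.39), not the exact 0.624/0.392 — only the rounded fractions
  reproduce the printed scenario CIs (0.62 × 111 = 68.8 → 69 etc.).
  `reduction_policy = "exact"` restores full precision.
* 0.39 × 162 = 63.18 prints as 63, yet the published table says 64 s.
  The computed value is carried everywhere; replication runs substitute
  the published 64 only as a display override
  (`use_printed_worst_point`).

## Break-even economics

With hourly salary cost *S* (EUR/h) and per-scan saving Δt (s), the
break-even per-case price is C = S·Δt/3600 and the minimum workload to
recoup a fixed price *P* is W = P/(S·Δt/3600), so W·C = P identically —
an invariant the pipeline re-checks on every run at 1e-9 relative
tolerance. Both transforms are monotone in Δt, so the saved-time CI maps
bound-to-bound (the workload bounds swap, being a decreasing transform).
Second-reader rows carry a negative saving and short-circuit to "no
break-even" instead of producing negative workloads.

Default inputs: salaries of EUR 196/127/45 per hour (USA/UK/Poland,
converted at frozen 2022 rates 1 USD = 0.9518, 1 GBP = 1.1731,
1 PLN = 0.2135 EUR and rounded to whole euros as published), pay-per-use
EUR 5.9–8.8, one-off license EUR 51,616, subscription EUR 20,000/year
(against the annual fee alone; installation and hosting add-ons are
carried in the settings but excluded from default runs, matching the
published table). Yearly-subscription workloads are per year.

**Saved-time policy.** The grid's default (`saved_time_policy =
"display_rounded"`) feeds the display-rounded integer saved times
(77/47/107, 100/69/131, 64/43/83) into the arithmetic. This choice
follows from forensics on the published table: the rounded inputs
reproduce every pay-per-use cell and the concurrent-reader row exactly,
while full-precision inputs do not (e.g. Δt = 100.44 gives a USA
best-case cost of 5.5, not the printed 5.4). `"unrounded"` keeps full
precision for non-replication use.

**What still does not reproduce.** The published pre-screening
*workload* cells are internally inconsistent: they imply unrounded
savings of ≈101 s (best) and ≈63.5 s (worst), incompatible with the
printed 100/64 and with any single pooled mean. No input choice can
match them, so the renderer ships a first-class discrepancy report:
under the default configuration exactly the 12 pre-screening workload
cells differ from the published snapshot, each by less than 3% (one
display digit), and the test suite pins that set so any regression —or
silent "fix"— is caught.

Display conventions: costs to 1 decimal EUR, workloads to 0.1 thousand
scans, saved times to whole seconds, all rounded half-up (0.9625 → 1.0,
12,313 → 12.3), cells formatted `point (95% CI: lo–hi)` with an en dash.
Internal arithmetic is never rounded.

## Simulator

`simulate_corpus()` emulates the statistical structure behind the
evidence table: study-level true savings drawn from
Normal(μ_saving, τ²), per-scan reading times around the study means with
within-study SD σ, summarised per reader into corpus-schema rows (plus
an `n_scans` column so standard errors, and hence DerSimonian–Laird
pooling, exist downstream). Defaults — 6 studies, one reader, 100 scans,
μ_no-CAD = 160 s, μ_saving = 77 s, τ = 25 s, σ = 40 s — mirror the
magnitudes of the real corpus: the published per-study savings (18 to
106 s) scatter around their centre with an SD of roughly 25–35 s, and
per-scan SDs of 25–164 s are reported. The lognormal option matches the
right skew of real reading times by moment correction, preserving the
stated means. `simulate_screening_population()` draws the triage stage:
binomial nodule status, nodule-free scans ruled out with the stated
probability, positives never.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real data: reader-experience effects (junior readers
save more), heterogeneous definitions of "reading time" across studies
(detection only vs. full reporting), correlation between a reader's
paired with/without-CAD times, and any accuracy change from CAD.

## Problem sizes and numerical choices

Monte-Carlo checks use 1000 replicates at the default simulator settings
(bias within 2 Monte-Carlo SEs of the truth; 95% CI coverage within
[0.92, 0.98]); the screening-population check uses 10⁵ scans against the
analytic reduction at 3 binomial SEs. Every stochastic test and the
acceptance script fix their seeds. τ̂² is clamped at 0; a single-study
pool returns that study's estimate (with a degenerate CI under the
unweighted method, warned about); zero-width CIs convert to se = 0 with
a warning; degenerate IQRs give SD 0 with a warning.

## Limitations

The model monetises reading time only: no discounting or multi-year
amortisation, no downstream costs of nodule work-up, no value assigned
to detection-accuracy changes, and no modelling of abnormalities missed
by a rule-out CAD. Prices and salaries are single-point 2021/2022
figures for three countries; the settings file exists precisely so users
can substitute their own.
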