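---
title: "Effectiveness endpoints and quantitative bias analysis for self-managed misoprostol-alone abortion cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effectiveness endpoints and quantitative bias analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misoqba)
```

## The setting and the estimand

Cohort studies of self-managed medication abortion recruit callers to safe
abortion hotlines and accompaniment groups, follow them by phone at roughly
one and three weeks after the first misoprostol dose, and estimate
*effectiveness*: the proportion whose abortion completed **without**
procedural intervention (manual vacuum aspiration or dilation and
curettage/evacuation). Because abortion is legally restricted in these
settings, outcomes are self-reported and no ultrasound or clinical
confirmation exists; the raw data cannot be deposited. Two consequences
shape this package:

1. every inferential step must be robust and auditable from aggregate
   structure (hence the margin-matched `reference_cohort()` fixture), and
2. the headline proportion needs a **quantitative bias analysis** for
   self-report misclassification and outcome-dependent loss to follow-up,
   since neither can be checked against a gold standard.

## Endpoint derivation

`classify_effectiveness()` assigns one of four classes per participant and
time point: `complete_no_procedure`, `complete_with_procedure`,
`not_complete_or_unsure`, `missing`. The precedence rules are:

* an intervention reported by the queried time point, together with a
  "complete" self-report, yields `complete_with_procedure` — the two
  completed classes are disjoint, matching how such studies tabulate them;
* a "not complete or not sure" self-report keeps its own class even when an
  intervention was reported. Published aggregate tables contain no cell that
  identifies how the original analyses would treat this combination, so we
  follow the self-report rather than guess; the combination does not occur
  in the reference fixture;
* at the *last recorded follow-up* the 3-week class is used when the
  participant attended that interview, otherwise the 1-week class is carried
  forward. This keeps every enrolled participant in the denominator at the
  cost of a shorter evaluation window for the carried-forward subset —
  exactly the selection concern the bias analysis addresses.

The two site-specific question wordings ("Do you think your abortion is
complete?" / "Do you think you are still pregnant?") are harmonized into one
binary field at ingest, and "not complete" and "not sure" form a single
class, as the reference tables pool both. Participants who judged
completion only from symptom resolution are classified identically to those
with a negative pregnancy test: the endpoint is the self-assessment, not its
basis.

Safety composites are plain ORs: `composite_warning_sign()` over four signs
and `composite_adverse_event()` over three treatment-based events. A
participant with entirely missing safety data propagates `NA` but stays in
descriptive denominators (`missing_in_denominator` policy); inferential
comparisons drop missing categories (`missing_excluded`), mirroring the
respective footnote conventions of published tables.

## Confidence intervals and rounding

The primary endpoints use the **Wilson score interval** without continuity
correction. The choice is empirical: it reproduces, at one-decimal rounding,
both printed bounds of the two primary-endpoint cells we treat as golden
(625/637 → 96.7–98.9% and 605/635 → 93.3–96.7%), which an exact
Clopper–Pearson interval does not. Some small-count cells (e.g. 6/637)
round differently from any standard interval at one decimal, so the method
is configurable (`method = "clopper_pearson"`) and golden tests assert only
the verified cells. Percentages are rounded half-away-from-zero at one
decimal (`round_half_up()`), the convention of the published tables, rather
than R's banker's rounding.

## Contingency-table tests

`chi2_independence()` is the Pearson test without Yates correction — the
uncorrected statistic is the reproducible oracle definition (a direct
Σ(O−E)²/E summation), and the correction is exposed as a flag rather than a
default. `fisher_exact()` uses the probability-ordering two-sided
definition for 2×2 tables (the sum of hypergeometric probabilities of all
tables with the observed margins no more probable than the observed one),
which is the dominant convention but not the only one — hence it is
documented and pinned by an independent enumeration oracle in the tests.
For r×c tables the test is exact up to a total count of `mc_threshold`
(default 10,000) and falls back to a Monte Carlo p-value (default 10⁶
draws) with the seed and draw count recorded in the result.

One wrinkle worth recording: the claim that χ² and Fisher p-values agree
within 0.02 whenever all expected counts exceed 20 is folklore and false —
at expected counts of 20–75 the gap can reach ~0.10 at mid-range p-values,
and it decays only like the square root of the sample size. The
asymptotic-agreement test therefore samples tables with cell counts in the
thousands, where the 0.02 bound genuinely holds.

## The quantitative bias analysis

The QBA is **summary level**: it corrects the observed completion *count*
among followed participants, not individual records. Only marginal counts
enter the published result, and the summary-level form admits closed-form
oracles for every step. Per iteration:

1. draw (Se, Sp, a_c, a_i) from their priors, where Se/Sp are the
   sensitivity/specificity of self-report against true completion and
   a_c/a_i the probabilities of attending the final follow-up given a truly
   complete/incomplete abortion;
2. invert the misclassification: p = (p_obs − (1 − Sp)) / (Se + Sp − 1).
   Draws with Se + Sp ≤ 1 (uninformative classifier) or p outside [0, 1]
   (an (Se, Sp) pair arithmetically incompatible with p_obs) are discarded
   and tallied; a `truncate` policy clamps instead, but discarding keeps the
   simulation interval interpretable and is the default;
3. selection-adjust by inverse probability of attendance:
   p' = (p/a_c) / (p/a_c + (1−p)/a_i), which recovers the full-cohort
   proportion when attendance depends only on the true outcome — the
   Bernoulli-attendance selection model is deliberately minimal, matching
   the stated selection concern; covariate-dependent attrition is out of
   scope;
4. add random error by drawing the final count from Binomial(n, p').

Corrections are applied in the conventional order for probabilistic bias
analysis — misclassification, then selection, then random error. The point
estimate is the **median** of kept draws (configurable to the mean) and the
95% simulation interval the equal-tailed 2.5/97.5 percentiles.

Two behaviors deserve emphasis. First, the *null-bias identity*: point
masses at Se = Sp = 1 with equal attendance reproduce the crude estimate up
to binomial noise; this is a test, not an assumption. Second, with a crude
proportion near 1, the inversion discards every draw with Se below p_obs
(corrected p > 1), so wide sensitivity priors mostly measure their own
incompatibility with the data: under the package's deliberately wide default
priors, an 86% discard rate on a crude of 98.6% is expected, reported, and
should inform narrower, better-anchored priors in a real analysis. The
reference study's own adjusted estimate depended on prior distributions
published only in supplementary material; they are configuration here, not
hard-coded truth, and no test asserts that particular adjusted value.

Prior families supported: point mass, uniform, beta, and trapezoidal
(inverse-CDF sampler; flat top between two modes with linear shoulders),
all restricted to (0, 1].

## The synthetic-cohort generator

`generate_cohort()` emulates the data-generating process the analysis
assumes: a latent true completion status drawn per participant from a
duration × regimen probability matrix, then observed through the
self-report channel (Se, Sp) and the attendance channel (a_c, a_i). The
truth is returned separately and never written into the observed record
file — the synthetic data have the gold standard the real study lacks,
which is what makes parameter-recovery tests possible.

Default calibration (`default_cohort_config()`), chosen once:

* structural margins equal the reference study's printed margins — n = 637,
  site mix 591/45/1, duration mix 317/205/92/23, regimen mix 532/105,
  expulsion-time bins (uniform within each printed hour bin, because only
  binned data are published), symptom-duration and side-effect frequencies;
* true completion probabilities per duration × regimen stratum are the
  printed duration-stratum effectiveness rates shifted on the odds scale to
  match the endorsed/other split (529/532 vs 96/105);
* Se = 0.99 and Sp = 0.95: unanchored by the study itself (no gold
  standard), set high on the strength of validation work comparing
  post-abortion self-assessment to ultrasound;
* attendance 0.932 given complete and 0.80 given incomplete, calibrated so
  the expected number missing the second follow-up is 45 of 637;
* warning-sign probabilities conditional on true outcome are free knobs with
  unanchored defaults (no published table conditions warning signs on true
  completion); care seeking given warning-sign status uses the printed
  conditional rates (0.442 / 0.216).

Each field draws from its own RNG substream derived from the seed and a
fixed per-field offset, so extending the generator cannot silently perturb
existing draws; output is bit-identical given (config, seed). Configurations
round-trip through a YAML text format (`write_cohort_config()`).

What the generator does **not** emulate: gestational-age-dependent symptom
biology beyond printed conditional frequencies, covariate-dependent
attrition, correlation between warning signs and care-seeking content, or
any within-participant longitudinal coherence beyond the outcome fields.
Passing tests on synthetic cohorts therefore validate the *computational
chain* — classification, tabulation, correction, recovery — not the
realism of any particular epidemiological scenario.

## The reference fixture

`reference_cohort()` is built by constrained assignment, not sampling, so
that it *exactly* reproduces the published margins used as golden values:
effectiveness classes at both follow-ups and at last recorded follow-up
(overall, by duration, by regimen), the 45-participant attrition subset with
carried classes 41/0/3/1, warning-sign components 14/21/4/23 with composite
52 plus one participant with wholly missing safety data, adverse events
6/0/3, care seeking 23/52 vs 126/584, and expulsion-time bins summing to
544 within 24 h. Cross-cells the publications do not pin down (for
example, which completed rows carry the non-endorsed regimen) are fixed by
an arbitrary deterministic rule; they should not be read as estimates.

## Numerical and design choices

* Wilson bounds are clamped to [0, 1] and exact at x = 0 and x = n.
* Probability vectors validate to a 1e-9 sum tolerance; violations name the
  offending field.
* Monte Carlo Fisher p-values and the QBA record their seeds in the result
  objects; rerunning any stage with the same configuration is bit-identical
  (the pipeline writes input checksums to `manifest.json` to make this
  auditable).
* Cohort validation collects all row-level problems before failing, so a
  malformed file yields a complete diagnostic list rather than the first
  error.
* Test problem sizes: the Wilson root-finder comparison runs a dense
  deterministic grid (all numerators for n ≤ 100, boundary plus seeded
  numerators for n up to 1000); the Fisher enumeration check covers all 2×2
  tables with total ≤ 12 exhaustively plus 2000 seeded tables with total ≤
  200; QBA recovery uses a 20,000-participant synthetic cohort so the ±0.01
  recovery band measures the correction machinery rather than single-cohort
  sampling noise.

## Limitations

The QBA corrects a single marginal proportion; it does not propagate
misclassification into stratified or comparative results. The selection
model conditions attendance on the true outcome only. The misclassification
inversion is unstable as Se + Sp → 1 and near-degenerate when p_obs is
close to 1, where much of the prior mass may be incompatible with the data —
the discard tally is the diagnostic to watch. Finally, the synthetic
generator's unanchored parameters (Se, Sp, conditional warning-sign rates)
are modeling choices, not estimates, and analyses of real data should
replace them with values justified for their setting.

```{r example}
cohort <- reference_cohort()
derive_endpoints(cohort)
```
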