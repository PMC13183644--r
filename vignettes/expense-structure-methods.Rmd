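---
title: "Methods: expense structure and determinants under DRG payment reform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expense structure and determinants under DRG payment reform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgcost)
```

## The setting

China's DRG payment reform replaces fee-for-service reimbursement with a fixed
standard payment per case group, under the settlement principle that hospitals
keep surpluses and absorb overruns. For a chronic, admission-heavy condition
like heart failure this changes both the *level* of hospitalization expenses
and their *composition* — the split of the total across comprehensive medical
service, diagnosis, treatment, drug, blood-product, material and other fees.
`drgcost` analyses front-page inpatient records across three payment regimes:
a pre-DRG phase (admissions 2015-01-01 to 2017-08-31), a municipal DRG phase
(2017-09-01 to 2022-06-30) and a provincial DRG phase (2022-07-01 to
2025-07-31). Phase is assigned from the *admission* date, the natural reading
of an inclusion rule stated in admission terms, while yearly panels use the
*discharge* year, the billing convention under which annual expense totals are
booked. 2025 is a partial year (admissions through July 31) and is treated as
an ordinary panel year.

## Record coding and filtering

Inclusion requires an admission inside the study window, primary diagnosis
equal to the configured code (default `I50.9`), length of stay 1–60 days, and
completeness on every analysis variable. Filtering is total — every input row
lands in either the kept or the excluded set — and each exclusion carries
exactly one reason, resolved in the fixed priority order window > diagnosis >
length of stay > completeness, so the audit trail is deterministic even when a
record violates several rules at once. Missing values in any analysis field
(the field the data most often leaves empty is the admission route) are
completeness exclusions by default.

Coding follows the conventional variable assignment for this literature:
insurance in three classes against an uninsured reference, visit counts capped
at four, eight age bands (1–60, then five-year bands to >90), length of stay
banded at 3/6/9 days, other-diagnosis counts banded in threes up to ≥16,
surgery level 0–4, discharge method in five classes. Ages below one year and
other-diagnosis counts of zero are domain errors rather than silently coerced:
the coding table has no bin for them, and an input that produces one is a
data problem the user should see.

## CPI standardization and log outcomes

Expenses across discharge years are standardized to base-2015 yuan by the CPI
ratio `real = nominal × CPI(2015)/CPI(year)` before any statistics are
computed; the deflator is applied to the total, the out-of-pocket amount *and*
the seven items, so the share-based and gray-relational analyses also run in
real yuan (a `nominal = TRUE` switch preserves the alternative, since
share-based statistics are in fact invariant to any within-year rescaling).
Outcomes are natural logs: `Y1 = log(total)` with no offset (totals are
strictly positive), and `Y2 = log(out_of_pocket + 1)` because fully reimbursed
admissions genuinely pay zero and a pure log is undefined; the 1-yuan offset
is negligible against typical totals in the thousands and is recorded in the
coded table's metadata. Natural base makes coefficients read as approximate
relative effects.

## Univariate screening

Expense distributions in such cohorts are right-skewed and fail normality
tests, so group comparisons are rank-based: Mann–Whitney U for two-level
factors, Kruskal–Wallis H for three or more, both with midranks and the
standard tie corrections, two-sided, at α = 0.05. The Mann–Whitney Z uses the
large-sample normal approximation *without* continuity correction, matching
the convention of the major commercial packages at cohort sample sizes; Z is
negative when the first group's rank sum falls below its null expectation.
Group descriptives are medians and quartiles by linear interpolation
(`quantile` type 7).

Two numerical caveats the tests quantify explicitly. First, the normal and
chi-square approximations are validated against full permutation enumeration
only in the tail (separated samples), where the α = 0.05 decision actually
happens; mid-distribution the two-sided normal p can differ from the exact
permutation p by 0.1 or more at n ≈ 8, which is irrelevant to screening but
worth knowing before quoting small-sample p-values. Second, the screen applies
no multiple-testing correction across the fourteen factors, matching standard
practice in this literature; its type-I error is validated per factor, not
family-wise.

## Dummy-coded OLS

Each outcome is regressed on its own screened factor set (the two outcomes
select different factors and are fitted independently). Factors enter as
treatment-coded dummies against fixed references (pre-DRG phase, uninsured,
first visit, male, youngest age band, Han, single, emergency route, shortest
stay band, fewest other diagnoses, no surgery, transfer discharge). Standard
errors are classical homoskedastic ones — the output format this literature
reports — with t tests and 95% t-intervals on the residual degrees of freedom.
Rank deficiency is an error naming the collinear columns, not a silent drop.
The fit is verified against `lm()` and a normal-equations oracle to 1e-10, and
refitting under a relabelled reference is tested to leave fitted values
exactly unchanged.

## Structural variation statistics

Yearly item shares use the ratio of sums: `share_i(y) = Σ item_i / Σ total`
over the year's admissions. This equals the ratio of per-admission *averages*
(the quantity this literature tabulates) and is more stable than averaging
per-admission ratios; both modes are implemented, aggregate is the default.
For a period from `t0` to `t1`:

* `VSV_i = p_i(t1) − p_i(t0)` — positive means the item's share grew;
* `DSV = Σ_i |VSV_i|` — total compositional churn, reported in percent;
* `CRSV_i = |VSV_i|/DSV × 100` — the item's contribution to that churn.

Because shares sum to one at both endpoints, `Σ_i VSV_i = 0` exactly for
every period, consecutive-period VSVs telescope to the overall VSV, and CRSV
rows sum to 100 — all asserted as exact identities in the tests. Report
formatting rounds VSV to 4 decimals and DSV/CRSV to 2, half *up* (the
convention of published expense tables, hence `round_half_up()`; R's own
`round()` is half-to-even); internal arithmetic is never rounded.

One provenance subtlety: when DSV/CRSV are recomputed from an *already
rounded* published VSV table, the result can differ from the source's
unrounded arithmetic in the last printed digit (each printed VSV carries up to
±5e-5 of rounding, so a period's DSV carries up to ±3.5e-4, which is ±0.035
on a percent). `verify_reference_tables()` therefore compares at a tolerance
propagated from the input precision rather than demanding exact agreement;
with the packaged reference tables, most DSV cells (including every headline
period) agree exactly and the remainder differ by exactly one final-digit
unit.

## Gray relational analysis

The reference sequence `X0(k)` is the yearly mean per-admission total expense
and the comparisons `X_i(k)` the yearly mean item expenses, k indexing the 11
years. Deng's coefficient

```
ξ_i(k) = (Δmin + ρ·Δmax) / (Δ_i(k) + ρ·Δmax),  Δ_i(k) = |X_i(k) − X0(k)|
```

uses ρ = 0.5 (configurable) and *global* extremes over all items and years —
the standard convention, and the one consistent with a single coefficient of
exactly 1.0 appearing where Δ attains its global minimum. The relational
degree `γ_i` is the mean coefficient over years; items are ranked by
decreasing γ, ties keeping item order with a flag.

The "novel" aspect is the absence of dimensionless preprocessing: all series
are in the same yuan units, so Eqs. are applied to the raw mean series
directly. This makes γ scale-free under a *common* rescaling of all series
(CPI choice does not matter up to a common factor) but *not* under per-series
normalization; the classic initial-value-normalized variant is available via
`normalize = "initial"` for comparison, and ranks under the two modes can
legitimately differ. With ρ large, all coefficients approach 1 and
discrimination vanishes — property-tested as the documented behaviour of the
ρ knob.

## The synthetic cohort generator

Real front-page records are not redistributable, so the generator emulates
the study conditions and gives every estimator a known truth:

* **Composition**: phase weights (3.9% / 45.6% / 50.5%) and categorical
  covariate distributions follow the published cohort's composition
  percentages (~76% resident insurance, ~50/50 sex, ~78% of stays 4–9 days,
  81.7% without surgery, etc.). These are config, not constants.
* **Cost model**: `log(total_real) = intercept + Σ effects + ε`,
  ε ~ N(0, σ²). Per-level effects default to the published regression
  estimates for this setting (stay length and surgery level strongly
  positive, insurance negative, repeat visits mildly negative), making the
  generator and the estimator conjugate — OLS on the coded cohort recovers
  the generating coefficients, which the acceptance tests assert at n = 5000
  within 3 standard errors per coefficient (with a family-wise allowance:
  across ~38 simultaneous 3σ checks, about one marginal excursion per ten
  runs is expected by chance, so up to two ≤4σ excursions are tolerated).
  σ defaults to 0.25, chosen to put the model's explained variance near the
  0.6 adjusted-R² scale typical of such cohorts.
* **Item split**: per admission, a Dirichlet draw (concentration 200) around
  the discharge year's mean share vector; the yearly means drift linearly
  with the drug share falling 2 points/year and the treatment share rising
  1.5 — the signs this literature reports — while drifts sum to zero. Item
  amounts are rounded to fen with the last item absorbing the remainder, so
  items always sum exactly to the total.
* **Out-of-pocket**: a patient-level Beta-distributed retention rate around
  insurance-by-phase means (uninsured retain exactly 1.0 in every phase —
  the pattern visible in published phase-1 quartiles where totals and
  out-of-pocket coincide; insured retention falls across reform phases).
  This is a multiplicative model, not an itemized reimbursement rule: no
  claims adjudication is simulated.
* **Prices**: real amounts are inflated to nominal by a CPI series grown at
  2%/year, and the analysis deflates them back — an exact round trip that the
  recovery tests exploit.

What the generator does **not** emulate: within-year seasonality, correlation
between covariates (they are drawn independently, unlike real cohorts where
age and comorbidity count correlate), outcome-dependent censoring, DRG group
assignment itself, or genuine reimbursement schedules. Passing recovery tests
therefore demonstrates the estimators are correct, not that the synthetic
defaults are estimates of any real hospital's parameters.

## Problem sizes and determinism

The test suite validates type-I error of the screen with 1000 null replicates
at n = 2000 (observed rate required within 0.03–0.07 of the nominal 0.05),
parameter recovery and the end-to-end pipeline at n = 5000, and the
goodness-of-fit of generated covariate frequencies at n = 10000 — sizes at
which the whole suite runs in well under a minute while leaving Monte-Carlo
error comfortably inside the asserted bounds. Every random element descends
from a single integer seed: the generator seeds the global RNG on entry, and
`run_pipeline()` bundles seed, configuration and record counts into its
run-metadata JSON so a run can be replayed bit-for-bit.

## Known limitations

* Exact-string diagnosis matching only; no ICD hierarchy or DRG grouper.
* No interactions or mixed effects in the regression, and no model selection
  beyond the univariate screen.
* Shares are treated as population descriptives; no uncertainty is attached
  to VSV/DSV/CRSV or γ.
* The Mann–Whitney normal approximation is not meant for very small groups;
  exact enumeration is used only as a test oracle, not exposed as a fitting
  path.
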