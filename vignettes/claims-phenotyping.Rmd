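---
title: "Claims-based phenotyping and prevalence estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based phenotyping and prevalence estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprev)
```

## The model and its assumptions

phenoprev estimates the prevalence of lung cancer among insured adults from
two administrative tables: an **enrollment** table (one row per person:
sex, birth year, insurance regime, region for the contributory regime, and
a mid-year affiliation flag per study year) and a **claims** table (one row
per service line: person, service year-month, ICD-10 diagnosis code,
procedure category). Neither table records diagnoses authoritatively; the
working assumption is behavioral: *people living with lung cancer generate
C33/C34-coded services persistently across months of a year, and many have
received chemotherapy, radiotherapy or surgery in recent years, while
rule-out or miscoded encounters are transient*.

A candidate case definition (an `algorithm_spec`) therefore has two dials:

- `min_months` — the minimum number of *distinct calendar months* of the
  index year with at least one C33/C34-prefixed claim. Repeat claims within
  a month are collapsed; claims in other years never count.
- `require_procedure` — whether at least one oncological procedure is
  required in the lookback window, the `lookback_years` (default 3)
  calendar years *strictly before* the index year. The window excludes the
  index year deliberately: the source method's own example pairs index 2018
  with procedure years 2015–2017. Requiring past treatment makes the
  definition specific but blind to patients newly diagnosed in the index
  year — which is why both families are kept and compared.

The default grid crosses `min_months` 1–8 with the procedure requirement
off/on: 16 candidates, containing the two definitions of practical
interest, `sensitive-m4` and `specific-m4`.

**Denominator.** The population at risk in year *t* is everyone affiliated
on 30 June of *t* and aged ≥ 20, with age computed at year precision
(*t* − birth year) and the floor inclusive. Crude (not age-standardized)
rates per 100,000 are reported. The aggregate rate sums contributory
stratum numerators n<sub>ijk</sub> (region × age group × sex) and
subsidized numerators m<sub>jk</sub> (age group × sex — the subsidized data
carry no region, so region-specific strata are only valid for the
contributory regime) over the pooled mid-year denominator. By construction
this equals the union-case-set rate exactly, and the test suite asserts
that identity on random instances.

**Age groups** are the half-open bins [20, 45), [45, 65), [65, ∞),
labelled `20-44`, `45-64`, `65+`. Published layouts often print
overlapping labels ("20–45", "> 65"); half-open bins restore a true
partition so that stratum numerators add up.

## Uncertainty

"Bootstrap with B subsamples" underdetermines the resampling unit and the
interval type, so the package makes the simplest defensible choice and
exposes both: persons (enrollment rows, carrying their claims) are
resampled with replacement to the original population size, the full
estimator — eligibility, identification, stratification — is recomputed per
replicate, and the CI is the percentile interval (2.5th/97.5th at the
default `conf_level = 0.95`). Default `B = 1000`; everything is
deterministic given `seed`. A replicate in which a stratum comes up empty
contributes rate 0 with a single warning rather than aborting — the
alternative (dropping the replicate) biases the interval for rare strata.
On the synthetic world at its stated scale (200 datasets of 50,000 persons,
B = 200) the measured empirical coverage of the true rate is 0.96, computed
by the acceptance suite itself.

## Algorithm selection

"Closest to the official sources" is operationalized with CI containment
dominant: each algorithm's aggregate estimates are scored per index year by
the number of benchmark point values inside the bootstrap CI, scores and
absolute distances are summed over years (the published pair is constant
across years, so selection pools years by default), and ranking within
each family is by higher total score, then lower total distance, then lower
`min_months`. Ties beyond that cannot occur because labels are unique.
Selection is invariant to input order, and widening a CI can never lower a
score — both are asserted as properties. Benchmarks are compared at the
general stratum only: the external sources publish aggregated national
rates, and per-stratum benchmark rows (where available) are still rendered
side-by-side in the report table for visual comparison.

## What the synthetic generator emulates — and what it does not

`simulation_params()` states a world: persons are assigned multinomially to
strata (regime × sex × region × age band) with per-stratum true prevalence;
true cases draw their number of distinct coded months from an explicit
probability vector over 1–12 (an explicit vector rather than a named family
because it makes limit cases — point masses, truncated supports — exactly
testable); non-cases become transient false coders with a small
probability; procedures are emitted into the lookback window with separate
probabilities for cases and false coders. Defaults: persistence mass
concentrated at ≥ 4 months, `false_coding_rate = 0.002` with false months
almost all 1–2, procedure probability 0.6 for cases and 0.02 for false
coders, and age-band prevalence 1.2 / 14 / 60 per 100,000 — a steep age
gradient of the kind lung cancer shows. These are one-time choices of a
plausible claims world, not fitted quantities.

Deliberately **not** emulated: enrollment churn (everyone is affiliated at
every mid-year, because the denominator is a headcount and churn adds no
testable behavior), incidence/survival dynamics (case status is drawn
independently per index year; prevalence is the target), costs, realistic
non-target code mixtures, and insurer or municipality clustering. A green
test on this world therefore establishes that the *pipeline machinery* is
correct — identification equals its oracle, aggregation is exact, CIs are
calibrated under person-level exchangeability — not that any particular
real-world rate is right, and not that the bootstrap is calibrated under
cluster correlation it never simulates.

## Numerical and degenerate-input choices

- Rates use one final division (`1e5 * numerator / denominator` on integer
  counts); the sum-equals-union identity is asserted exactly, not to a
  tolerance.
- An empty stratum denominator at point estimation is an explicit error;
  `NaN` never propagates.
- Duplicate enrollment rows keep the first occurrence with a warning
  (deterministic and auditable); malformed claim rows are dropped with a
  per-row reason in the validation report, and counts satisfy
  retained + dropped = input.
- ICD-10 matching is prefix-based on normalized codes (upper-case, dots and
  internal whitespace removed), so `C34`, `C341` and `c34.1` behave
  identically; normalization is idempotent.
- Quantiles use R's default type 7; with B = 1000 the difference between
  quantile definitions is well below the 2-decimal rendering of the output
  files.
- Generation is Mersenne–Twister under the params seed; the claims stream
  uses seed + 1 so population and claims draws cannot interleave.

## Open design points, decided

- **Procedures in the index year** do not satisfy the specific criterion
  (the window is strictly prior). A treatment in the index year without any
  prior-year procedure most often marks an incident case being treated for
  the first time; excluding it keeps the specific family's meaning — known
  disease with a treatment history — sharp. The window is configurable.
- **Claim lines are treated uniformly** regardless of service type: the
  data model has no reliable marker distinguishing consultation diagnoses
  from, say, dispensation-attached codes, and month-distinctness already
  damps repeated lines from one episode.
- **Whether the published 16-algorithm grid also varied lookback length**
  is unknowable from the text; the grid here varies `min_months` only,
  with `lookback_years` configurable per spec object.

## Known limitations

Year-precision ages misclassify people near birthdays around the age-20
floor and bin edges; the bootstrap ignores any clustering by insurer or
geography; selection against aggregated benchmarks inherits those
benchmarks' own errors and cannot measure sensitivity or specificity
against a clinical gold standard; and the generator's independence
assumptions (across persons and across years) make the synthetic world
easier than real claims data.
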