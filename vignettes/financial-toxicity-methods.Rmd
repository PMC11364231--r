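---
title: "Measuring financial toxicity of acute injury care: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring financial toxicity of acute injury care: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fintox)
```

## The problem

Out-of-pocket (OOP) payments for acute injury care can push households in
low- and middle-income settings into financial crisis. Two WHO-style
indicators quantify this *financial toxicity*:

* **Catastrophic health expenditure (CHE)** — the OOP payment consumes an
  unsustainable share of what the household spends in a year.
* **Impoverishment (IMP)** — the OOP payment pushes the household's income,
  per adult equivalent, below a poverty line.

`fintox` implements the full measurement chain for a trauma-registry
cohort: itemized hospital costing from a fee schedule, the CHE and IMP
classifiers, stratified descriptive tables, and a Three-Delays summary of
the prehospital pathway, plus a synthetic-cohort generator so the whole
chain is testable without patient data.

## Itemized costing

Each patient's OOP expense is the sum of six components: consultations,
procedures, imaging, ward stay, consumables, and death expenses, all in
Tanzanian shillings (TZS) at citizen rates, pre-insurance reimbursement.
The rules:

* Every encounter is billed exactly one emergency-physician specialist fee
  — every patient saw the emergency physician — even with an empty service
  list. This is the floor of `total_oop`.
* A service that names a schedule code is billed at that unit price times
  its quantity (quantity defaults to 1; registries rarely record repeats).
* Imaging recorded only by modality is priced by **mean substitution**:
  with the subtype unknown (typical for MRI and ultrasound), the average
  price of all schedule items of that modality is used; with laterality
  unknown, the average of the unilateral and bilateral prices. A
  substituted price therefore always lies within the min–max range of the
  items it averages.
* Stay is billed per day at the *basic shared-ward* rate for general-ward
  days (the cheapest `general` admission item when several exist) and at
  the ICU rate for ICU days.
* In-hospital deaths add a death certificate, ward-to-morgue transport, and
  a body bag; all three items must be present in the schedule to cost a
  death.
* Surgery is billed as the procedural fee only; anesthesia and theatre
  consumables are not modeled separately, so totals are conservative.

The bundled fee schedule (`default_fee_schedule()`) is **synthetic**: its
prices have plausible relative magnitudes for a Tanzanian zonal referral
hospital but are placeholders. Real analyses must supply the institution's
price list via `load_fee_schedule()`; the file dialect is a six-column CSV
(`code,category,unit_cost_tzs,modality,variant,ward`).

USD figures use a fixed conversion of 2,339 TZS per USD, rounded to whole
dollars only for headline reporting; TZS amounts are never rounded during
computation.

## The CHE classifier

Let `OOP` be the costed expense, `TE` the household's annual total
expenditure, and `NSE = max(TE − SE, 0)` its non-subsistence expenditure,
where the subsistence expenditure `SE` is estimated **once per cohort** as
the mean annual food spending of households in the middle of the
consumption distribution (below). A patient is flagged at a threshold when

```
OOP ≥ x · Y,   with (x, Y) ∈ {(0.10, TE), (0.25, TE), (0.40, NSE)}
```

and `any_che` is the disjunction of the three flags. Design choices that
the measurement literature leaves open, resolved here:

* **Weak inequality.** A cost exactly at the threshold counts as
  catastrophic (`comparison = "ge"`, configurable to strict).
* **Exhausted capacity to pay.** When `NSE = 0` — the household spends at
  or below the subsistence floor — *any positive* OOP cost trips the
  40%-of-NSE rule, but a zero-cost encounter does not. Without this rule a
  zero-capacity household would be flagged for an expense of 0 TZS.
* **Annual basis.** Income and expenditure are annual household quantities;
  monthly poverty lines are multiplied by 12 and daily lines by 365.

### Subsistence expenditure

Households are ranked by annual total expenditure (ties keep input order,
so the estimate is deterministic); household at rank `r` of `n` receives
percentile `100·(r − 0.5)/n`; those inside the closed window [45, 55] are
averaged. For cohorts too small for the window to catch anyone (n = 2
yields percentiles 25 and 75), the household nearest the 50th percentile is
used, preferring the lower rank on ties. This midpoint-percentile rule was
chosen over interpolation because it is unambiguous, exactly reproducible,
and at n ≥ 10 selects the same households as any conventional definition
of a 45th–55th percentile band. Ranking uses household TE, not per-capita
TE; `SE` is a per-household amount and is *not* scaled by household size
(a per-adult-equivalent option exists but is off by default).

## The IMP classifier

Household size is converted to adult equivalents with the OECD-modified
scale — 1 for the first adult, 0.5 per additional adult, 0.3 per child
under 14 (`adult_equivalents()`). With annual household income `I` and
poverty line `Z` (annualized TZS per adult equivalent):

```
impoverished  ⇔  max(I − OOP, 0) / H_a < Z
```

for each of three lines: the Tanzanian national basic-needs line
(49,320 TZS per month), $1.90/day, and $3.20/day. The default mode flags a
patient whenever the post-OOP position is below the line, *regardless of
the pre-OOP position* — the literal reading of the indicator, appropriate
when many cohort households sit near the lines already. A `newly_poor`
mode (pre-OOP at or above the line, post-OOP below) is available but off
by default. Patients with missing income get `NA` flags rather than being
dropped: headline prevalence can then be reported against the full cohort
denominator while stratified tables exclude them, and both denominators
appear in the pipeline metrics.

## Synthetic cohorts

`generate_cohort()` exists so that every downstream stage is testable. Its
defaults are the study conditions: the marginal distributions listed in
`?cohort_params` (sex, mechanism, insurance, dependents brackets,
hospitalization, surgery, death, income-refusal rate) and lognormal
monthly adult-equivalent income with median 98,387 TZS and IQR 136,842.
The lognormal `sdlog` is solved in closed form from the median/IQR pair
(`asinh(IQR/2M)/Φ⁻¹(0.75)`); lognormality itself is an assumption —
standard for incomes — not an observed fact about the study households.
Other free choices, fixed once: adults beyond the respondent follow
1 + Poisson(0.8) plus adult dependents; 70% of dependents are children;
total expenditure is income times a lognormal factor centred near 0.85;
the food share of expenditure is Beta(9, 11) (mean 0.45, plausible for the
setting).

Service lists are assembled from the injury profile (imaging by mechanism,
a surgical procedure and surgical consult for operative patients, ward days
for admissions) and topped up with consumables so each costed total tracks
a lognormal draw with median 476,793 TZS and IQR 536,825 — consumables
absorbing the spend the itemized draw does not explain. Target draws are
rank-matched to the itemized base cost (costlier injury profiles receive
the larger totals), and the bundled schedule's big-ticket prices were
chosen once so that the itemized base typically sits below the target
median; together these keep the costed cohort median within a few percent
of the target. Surgery and hospitalization therefore raise costs
mechanically, inducing the CHE–surgery association in the generated data;
the association's magnitude is a property of the generator, not an
estimate.

With `target_any_che = p`, the generator constructs *exact* ground truth:
the CHE thresholds depend only on household expenditures, never on OOP, so
each patient's smallest triggering cost `m = min(0.10·TE, 0.40·NSE)` is a
fixed point of any cost adjustment. The `round(p·n)` patients with the
highest cost-to-threshold ratios are designated catastrophic (households
with `NSE = 0` are forced in, since their mandatory consult fee already
trips the rule); designated cases below `m` get consumable top-ups,
designated non-cases above `m` have discretionary services pared back (most
expensive first, then ward days). Infeasible targets — an all-zero fee
schedule, or more forced cases than requested — raise a generation error.
The construction assumes the default weak-inequality threshold
configuration. Emitted labels are verified against an independent
re-classification in the test suite.

What the generator does **not** emulate: joint dependence beyond the
mechanisms above (no copulas, no fitted registry model), seasonality,
within-household correlation of delays and finances, or real KCMC prices.
Passing tests demonstrate the *measurement chain* is correct, not that the
synthetic cohort is a statistical twin of the registry.

## Descriptive analysis

Stratified tables report categorical rows as `% (n)` with unknown
responses kept in the denominator, and continuous rows as median [IQR]
(linear-interpolation quantiles, `stats::quantile` type 7). Strata are
`overall`, `any`, `none`, plus one stratum per threshold or line; the
per-threshold strata overlap and are subsets of `any` by construction.
Group comparisons between the `any` and `none` strata use the Welch
two-sample t-test for continuous variables, one-way ANOVA for more than
two groups, and the chi-square test for categorical variables, with the
method recorded per row — a deliberately conventional assignment, since
applying mean-comparison tests to categorical rows is not statistically
defensible. No multiple-testing correction is applied, matching the
descriptive intent. Per-threshold strata are never tested against each
other: they are not independent groups.

The Three-Delays summary stratifies the prehospital markers the same way:
Delay 1 as the frequency of the decision-stage markers (cost concern,
perceived severity, agency), Delay 2 as facility transfers and surgery
after transfer, Delay 3 as the time-to-care ordinal {minutes, hours,
longer}, plus the ratio of median OOP between the toxic and non-toxic
strata. The delay-1 marker set is an extensible enumeration of the
registry fields available here and is documented as partial.

## Numerical and degenerate-input behaviour

* Money stays in exact double-precision TZS; component additivity is
  enforced to 1e-6 TZS in tests.
* Empty service lists are valid (the consult floor applies); an empty
  cohort is a validation error everywhere.
* Unknown variant/laterality is an explicit `"unknown"` token in the
  service dialect, distinct from a structurally absent field.
* Duplicate schedule codes, negative prices, negative stay, and negative
  transfer counts are rejected with typed conditions
  (`fintox_validation_error`, `fintox_schema_error`,
  `fintox_unresolvable_item_error`, ...), so callers can distinguish bad
  inputs from bugs.
* The pipeline is deterministic: identical inputs give byte-identical
  metrics and report files.

## Problem sizes

The test suite and acceptance script run the generator at n = 78 (the
study's sample size, with the exact-count construction), n = 100–600 for
the property suites, and n = 2,000 for marginal-fidelity and
target-recovery checks — large enough that a 3-binomial-SE band is a
meaningful test, small enough to keep the whole suite under a minute of
generator time.

## Limitations

Costing is conservative by construction (missed expense types, procedural
fees only); the bundled schedule is synthetic; the subsistence estimator is
the simple percentile-window average, not a food-share regression; CHE/IMP
flags are measured at a single encounter, so coping strategies (borrowing,
asset sales) and longer-run impoverishment dynamics are out of scope.
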