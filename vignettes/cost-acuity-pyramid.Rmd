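---
title: "Cost acuity pyramids, patient flow, and the dollars that move with them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost acuity pyramids, patient flow, and the dollars that move with them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costpyramid)
```

## The problem

Health care expenditure is extremely concentrated: in a typical insured
population the costliest 5% of patients account for roughly 40–50% of
total spending, the middle 45% for most of the rest, and the cheapest half
for only a few percent. Population health programs therefore tend to
target the current top tier. But annual cost is a noisy, heavy-tailed
quantity: a patient at the top this year — often there because of an
acute episode — will usually be cheaper next year whether or not anyone
intervenes (regression to the mean), while next year's top tier is largely
recruited from below. A defensible cost-management strategy needs the
*dynamics*: how many patients move between cost tiers each year, and how
many dollars move with them.

`costpyramid` operationalizes that analysis for longitudinal panels of
older, high-utilization patients (the setting it is calibrated to: ~2,600
home-care patients followed over five fiscal years), but nothing in the
machinery is specific to that cohort.

## The model and procedure

**Segmentation.** For each fiscal year, patients with any utilization
(a positive inpatient or outpatient cost) are ranked by annual total cost,
highest first. With `n` utilizers, the top `⌊0.05 n⌋` form the **T**
segment, patients up to rank `⌊0.50 n⌋` the **M** segment, and the rest
the **B** segment. The cumulative-floor arithmetic is deliberate: it is
the unique simple convention that yields tier sizes 110/993/1103 for
n = 2206, the benchmark case the package tests against. Ties in cost are
broken by ascending patient id — the choice is arbitrary but must be fixed,
or membership would depend on input row order. Tier thresholds are reported
as the minimum observed cost inside T and inside M (not interpolated
quantiles), matching how such cutoffs are quoted in practice. Segment SDs
use the sample (n−1) convention; at tier sizes in the hundreds the
distinction from the population convention is immaterial, but tests need
one fixed answer.

**Patient flow.** For consecutive years t, t+1 the package counts the nine
possible segment transitions over the *joint cohort* — patients who were
utilizers in both years. Patients entering or leaving the panel are
excluded from the matrix but counted in the result (`n_only_t`,
`n_only_t1`) and their dollars reported (`entering_cost_t1`,
`exiting_cost_t`), so per-year totals always reconcile. The joint-cohort
rule is an interpretation: published cohort denominators of this design
are consistent with it but do not spell it out, which is why the
reconciliation is surfaced rather than hidden. Row-normalizing the counts
gives a pair matrix; the study-level Markov chain is the **unweighted
element-wise mean** of the pair matrices (equal weight per year pair, not
pooled counts). A row with no observed leavers makes the pair degenerate
and is an error, not a silent imputation.

**Movement aggregation.** Given a transition matrix and segment shares
(nominally 0.05/0.45/0.50 by construction of the pyramid), each of the
nine probabilities is weighted by its from-segment share and summed by
direction under the ordering T > M > B: the upper-left triangle of the
(T, M, B) × (T, M, B) matrix is "down", the lower triangle "up", the
diagonal "stay". When shares are taken from the observed row totals this
aggregation is *exactly* equivalent to classifying patients one by one
(`movement_counts()`), a property the test suite checks; with nominal
shares it is the standard study-level summary. `stationary_distribution()`
adds the usual Markov diagnostic: the long-run tier occupancy implied by
the averaged chain (left unit eigenvector; the chain must be irreducible,
which is checked by boolean reachability).

**Cost flow.** The same joint cohort is partitioned two ways — by origin
segment at year t, and by movement direction — and each part's dollars are
summed at t and t+1 with percent changes `100·(after − before)/before`.
Both partitions must (and do, cent-exactly) sum to the same cohort totals.
Percent changes are computed on unrounded totals; rounding to integer
percent happens only at display time, using round-half-away-from-zero.

**Trends.** Annual totals (population and per segment, in US $M) are
regressed on the fiscal-year label by OLS with a two-sided t-test on the
slope (n − 2 df). Because the three segment totals sum to the population
total in every year and all four regressions share the regressor, the
population slope equals the sum of segment slopes exactly — a useful
internal consistency check. Year labels enter as-is; recoding 2011..2015
to 0..4 changes only the intercept. Degenerate inputs get defined answers:
an exactly flat series has slope 0 and p = 1, an exact nonzero-slope line
p = 0 (detected by residual variance below 1e-10 of the data scale, with
`t_stat = NA` since there is no sampling variability to test against).

**Group comparisons.** Movement groups (up/stay/down over a year pair) are
compared attribute by attribute: Pearson chi-square without continuity
correction for categorical attributes, one-way ANOVA for numeric ones.
The ANOVA is reconstructed from per-group (n, mean, SD) summaries — between
and within sums of squares need nothing else — and agrees with raw-data
`anova(lm(...))` to 1e-10 when the summaries come from the raw data. The
published table this mirrors does not name its tests; these are the
conventional choices, and the package validates the inference by
reproducing the table's live-alone p-value (.02) from its printed counts.
Missing attribute values are excluded per attribute, so each attribute
reports its own N. No multiple-testing adjustment is applied, matching the
unadjusted per-attribute presentation such tables use. For categorical
attributes with more than two levels, per-category (category vs rest)
tests are emitted alongside the overall test, labelled separately.

## The synthetic generator

`generate_panel()` simulates the generative structure the analysis
assumes, so the pipeline can be exercised and its estimators validated
against known truth:

- Each patient draws a latent segment from the initial occupancy
  (default: the nominal shares 0.05/0.45/0.50) and evolves it by the
  configured transition matrix — by default the study-calibrated chain
  (T: 0.24/0.54/0.22; M: 0.05/0.55/0.40; B: 0.02/0.29/0.69).
- Annual cost given the latent segment is lognormal, moment-matched by
  `lognormal_params_from_moments()` (σ² = ln(1 + (sd/mean)²),
  μ = ln mean − σ²/2) to the per-segment means/SDs of
  (117201, 75976), (19037, 14534), (1072, 985) dollars. The lognormal is
  the standard heavy-tailed cost model; no distribution family is implied
  by the rank-based segmentation itself, so this is a modelling choice.
  No hard cost cutoffs are imposed at generation — observed tiers are
  re-derived by ranking, which blurs boundaries exactly as rank-defined
  tiers do in real data.
- Each patient-year independently emits no record with probability
  `p_no_utilization` (default 0.17, a calibration chosen so ~2,200 of
  2,643 patients have any cost in a given year; it is not an empirical
  rate from any dataset).
- Totals split 2/3 inpatient / 1/3 outpatient (hospital admissions run at
  about two thirds of expenditure in this setting); optional beta noise
  around the fraction via `inpatient_beta_size`.
- Demographics are independent categorical draws from configured
  marginals, stored as exact count ratios so each map sums to 1. Numeric
  age is a normal(79, 11) truncated at 65 within the drawn age band and
  floored to completed years. Attributes are mutually independent — only
  marginals are modelled, no copula — so the generator cannot exhibit
  realistic attribute-attribute or attribute-cost correlation.

Randomness is controlled by one root seed: the panel stream uses
`set.seed(seed)`, the demographics stream `set.seed(seed + 1)`, so the two
can be generated independently and reproducibly. Latent labels for every
patient-year (including non-utilizing ones) ride along as a side table via
`latent_labels()`; the analysis pipeline never reads them.

**What passing tests do and do not show.** On synthetic panels the
estimators recover the generating chain (every entry within 0.03 at 5,000
patients × 5 years), conserve dollars exactly, and show the expected
regression-to-the-mean signature (T-origin cohorts' costs fall, B-origin
cohorts' rise, in ≥9/10 seeded replicates). That validates the *method
implementation*, not any claim about real populations: real panels have
cost autocorrelation beyond a first-order latent chain, informative
attrition (death, disenrollment), covariate-dependent transitions and
within-year correlation between utilization and cost level, none of which
the generator models.

## Numerical and design choices

- Costs are carried at cent precision (rounded on entry); "US $M" figures
  are display views only.
- An all-zero cost row is accepted on input but counts as *no utilization*
  for pyramid membership; a patient whose every year is zero is dropped by
  `filter_utilizers()`.
- Matrix averaging weights year pairs equally regardless of cohort size —
  the alternative (pooling counts) would weight later, larger pairs more.
- `aggregate_movement()` defaults to the nominal 5/45/50 shares rather
  than observed shares, because pyramid construction fixes tier sizes to
  those fractions up to floor rounding.
- p-values print in the compact style (".003", "<.001") but are stored
  unrounded.
- Problem sizes in the test suite are chosen for statistical resolution:
  moment matching is checked on 1e6 patient-years (~44,000 in the smallest
  tier, giving sub-percent Monte-Carlo error against a 2% band), parameter
  recovery at 5,000 patients × 5 years, null calibration at 1,000
  replicates.

## Limitations

- First-order Markov dynamics only; multi-year trajectory enumeration is
  out of scope (the flow space grows threefold per added year).
- The joint-cohort rule for pair denominators is an interpretation (see
  above); entering/exiting dollars are reported so users can judge its
  effect.
- Trend tests on five annual points have little power and assume
  independent errors; they are descriptive, not forecasting tools.
- The generator's demographics are marginal-only and independent of cost
  dynamics; group-comparison null behaviour on synthetic data is therefore
  exactly null by construction.
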