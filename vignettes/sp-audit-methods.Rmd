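---
title: "Methods: scoring SP audits and modelling the care cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring SP audits and modelling the care cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(spaudit.quiet = TRUE)
library(spaudit)
```

## The problem

Standardized-patient (SP) audits send trained incognito patients, presenting
a scripted clinical case, to real providers, and record what the provider
actually asks, examines, diagnoses, dispenses and refers. `spaudit`
implements the analysis pipeline for such an audit of type 2 diabetes (T2D)
care in a three-tier rural health system — village clinics (VC), township
health centers (THC) and county hospitals (CH): checklist-based quality
scoring, tier-stratified comparison tables, correlate regressions, and a
care-cascade model that aggregates provider-level quality and patient
sorting behavior into a system-level probability of correct treatment.

## Process scoring

Each visit is scored against a guideline checklist of 19 recommended
history questions and 13 recommended examinations. The process outcome is
NRQE, the count of recommended questions and examinations used; by
construction `nrqe = n_questions + n_examinations`. The adherence share
ANRQE divides NRQE by a denominator. Reports on this guideline quote two
totals — the 32 items of the component lists and an alternative total of
31 — and published ANRQE values are consistent with neither (a tier mean of
5.5 items is printed as 19.7%, but 5.5/32 = 17.2% and 5.5/31 = 17.7%). The
package therefore defaults to the reproducible definition `anrqe = nrqe/32`
(`component_sum` mode), offers `fixed_total` mode with a configurable total
(31 in the packaged file), and never treats ANRQE as a reproduction target.
The ANRQE row is likewise excluded from the fixture's cell-match tests.

## Treatment classification

What counts as "correct treatment" in an SP audit is a judgment the case
script leaves partly open, so `treatment_policy()` makes every choice an
explicit field. The pharmacological route requires at least one
correct-class drug (or all, under `drug_rule = "all_correct"`), and any
harmful drug vetoes the outcome. The packaged default additionally counts
joint lifestyle advice *and* blood-glucose-monitoring advice as correct
non-pharmacological treatment. That clause is clinically grounded —
lifestyle modification with glucose monitoring is first-line T2D management
for a newly presenting patient — and it is also the only reading under
which the published tier cells are jointly consistent: the reported
correct-treatment counts (13/18/10 by tier) exceed the reported
correct-drug counts (12/11/5) in every tier, so a purely drug-based rule
cannot generate them; crediting referral instead closes the gap at VC and
THC but not at CH (5 correct-drug visits + 1 referral < 10 treated).
Referral is kept out of the default treatment definition, matching tables
that report it as a separate row. Drug names are matched after case-folding
and whitespace stripping only; an unknown drug is an error, never a silent
default.

## The worked-example fixture

`build_table_fixture()` returns 126 providers (46/49/31 by tier) and one
interaction per provider, constructed deterministically so that scoring
plus `build_tier_table()` reproduces every count, one-decimal percentage
and one-decimal mean/SD cell of the published provider-characteristics and
care-quality tables, including the published denominator conventions:
correct drugs out of dispensing visits (29/14/6), harmful drugs out of the
full tier, and correct diagnosis out of visits with a stated diagnosis
(46/47/30 — three records carry no diagnosis). Only those marginals are the
contract; the joint structure (which record carries which attribute
combination) is unidentifiable from marginal tables and is an arbitrary
deterministic packing, so the fixture must not be used to study
cross-attribute associations. Continuous columns are frozen integer vectors
chosen so that means and SDs round (half-up) to the printed cells *and*
one-way ANOVA preserves each row's published significance classification.
One published cell is malformed at the source ("14.2.0%" for THC referral);
the fixture renders the arithmetically consistent 7/49 = 14.3%.

## Tier tables and significance tests

The published tables do not name their tests. The package uses Pearson's
chi-square test of independence without continuity correction for count
rows, switching to Fisher's exact test when any expected cell is below 5,
and the one-way ANOVA F-test for continuous rows. On the fixture these
choices reproduce the published p-values almost digit for digit (e.g.
0.0709 vs the printed 0.071 for gender; 0.0505 vs 0.051 for glucose
monitoring) and reproduce every published significance classification. The
one exception in magnitude is the referral row (computed 0.0006 vs printed
0.017 — evidently a different test at the source), where the classification
still agrees; this is asserted, not hidden. Degenerate rows with no
variation return p = 1 by convention with a log line. Cells are carried at
full precision and rounded half-up to one decimal only for display.

## Correlate models

NRQE is modelled by OLS with conventional homoskedastic Wald intervals;
binary outcomes by maximum-likelihood logistic regression reported as
average marginal effects (AMEs): the sample mean of the derivative of the
predicted probability for continuous covariates, and of the discrete 0-to-1
contrast for binary covariates, with delta-method intervals (analytic
gradient for the continuous case). Conventions, configurable and documented
as conventions rather than facts about the source study: income enters as a
z-score, patient volume as `log2(count + 1)` (per-doubling
interpretation), age as an at-or-above-median contrast. Tier indicators use
VC as the reference. Perfect separation, non-convergence and single-class
outcomes are errors with diagnostics. Because the original field records
are not public, the published regression estimates are treated as generator
defaults and recovery targets, not as reproduction targets.

## The synthetic cohort generator

`generate_cohort()` draws providers from tier-stratified distributions
moment-matched to the published provider table (log-normal income,
negative-binomial patient counts, truncated-normal integer ages, Bernoulli
binaries at the published tier shares), then one interaction per provider
under the data-generating model the correlate analysis assumes:
independent per-item Bernoulli use with tier-specific probabilities scaled
so the expected question/examination counts equal the published tier means;
diagnosis correct with probability
`plogis(a_tier + 0.15*NRQE + 0.8*certificate - 0.2*income_z)` and treatment
correct with probability `plogis(c_tier + 0.23*NRQE)`, intercepts
calibrated so the marginal rates sit at the published tier rates and the
NRQE slope chosen so its AME on treatment is about +0.05 per item;
referral as an independent per-tier categorical draw; and 750 households
sorting 0.39/0.32/0.29. Records are materialized so that re-scoring them
under the default policy recovers the drawn labels exactly (treated visits
carry a correct-class drug; untreated visits never carry both advice
flags). A single RNG stream is seeded once per call and global RNG state is
restored, so identical parameters give byte-identical output.

What the generator does not emulate — and hence what passing tests cannot
show about real data: spatial clustering of the sampling design, within-
provider correlation between item use and covariates beyond the modelled
coefficients, measurement error in the debriefing, or any dependence
between referral and treatment outcome.

## The care cascade

The cascade combines a sorting distribution `s`, per-tier correct-treatment
probabilities `q`, and referral rates `r` into the probability that a
patient entering the system is correctly treated,
`P = sum_t s_t * P(start = t)`. Field data record referral shares of whole
tier populations but not whether referral was conditioned on treatment
failure, so three readings are implemented:

* `additive_credit` (default): referral shares are unconditional masses
  added to the start tier's own success, e.g.
  `P(VC) = q_VC + r_VC>CH q_CH + r_VC>THC q_THC + r_VC>THC>CH q_CH`.
  On the packaged inputs this yields 38.81%, matching the source study's
  reported system-level figure of 38.9% to within rounding of its printed
  inputs, which is why it is the default.
* `conditional_on_failure`: referral applies to the untreated remainder
  and chains recursively, `P(t) = q_t + (1 - q_t) sum_u r_tu P(u)`
  (36.73% on the same inputs).
* `chain_thc_referral`: as additive, but VC-to-THC transfers inherit the
  THC onward-referral rate instead of the explicit second-hop mass
  (38.81%; the printed second hop 0.022 is numerically ~0.152 x 0.143).

The source study also prints an incompatible alternative system-level value
of 23.7% whose derivation is not public; no implemented policy reproduces
it from the printed inputs, and the package documents rather than guesses
it. The published second-hop figure ("2.2%") is read as a mass of VC
starters (its wording and the consistency 0.152 x 0.143 = 0.0217 both
support this); the alternative reading is available through the
`chain_thc_referral` policy. The CH outward-referral share (3.2%) exits the
modelled system without treatment credit under all policies, as there is no
higher tier in the model.

Feasibility: the additive policies require `q_t` plus the outgoing referral
mass of tier `t` not to exceed 1 (and the second hop not to exceed the
VC-to-THC mass); violations are errors naming the tier. Every analytic
result is cross-checked against `enumerate_paths_oracle()`, an independent
worklist walk over all patient paths, to 1e-12. Under
`conditional_on_failure` the path ledger is a proper probability
distribution per start tier (masses sum to 1); under the additive policies
the untreated remainder is reported as an explicit residual row.
`bootstrap_cascade_ci()` resamples each rate binomially from its audit
numerator/denominator and the sorting distribution multinomially (n = 750),
redrawing and logging infeasible resamples, and returns the percentile
2.5/97.5 interval. All inputs are carried as exact decimal-derived floats;
nothing is rounded before display.

## Numerical and testing choices

Display rounding is half-up to one decimal (matching how field reports
print), via `round_half_up()`; all internal arithmetic is full precision.
Logistic fits use IRLS with up to 100 iterations; separation is flagged
when fitted probabilities pin to 0/1 or a coefficient exceeds 15. Wald
intervals are used throughout because the symmetric intervals printed in
this literature are Wald intervals.

The test suite's simulation sizes are chosen to balance Monte-Carlo
resolution against runtime: the parameter-recovery study uses 200 replicate
cohorts of n = 5,000 interactions (per-coefficient 95% CI coverage is
required to be at least 93%, i.e. within ~1.3 binomial SDs of nominal), the
oracle-equivalence sweep uses 1,000 random feasible parameter draws per
policy, and the sorting-unbiasedness check uses 500 replicate household
samples of n = 750 against a 3-standard-error band.

## Known limitations

The fixture's joint structure is arbitrary; only marginals are meaningful.
The checklist item wording is a representative rendering of the guideline
standard, and the drug classification covers the common dispensations of
such audits, not a pharmacopoeia. The cascade is a single-episode model: no
repeat visits, time dynamics, costs or health outcomes, and it models
treatment quality only (not a diagnosis-stage cascade). Survey weighting
and clustered variance are deliberately out of scope, matching the source
analysis.
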