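---
title: "Developing a sciatica subgrouping algorithm: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing a sciatica subgrouping algorithm: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sciatriage)
```

## The clinical problem

Sciatica (lumbar radicular pain) is usually managed by stepped care: every
patient starts with advice, analgesia and perhaps physiotherapy, and
referral to spinal specialist services is considered only after conservative
care fails. A minority of patients — those with severe, persistent,
neurologically compromised presentations — would plausibly benefit from
being identified at the *first* primary-care consultation and fast-tracked
to imaging and specialist opinion. This package implements, as tested code,
the development pipeline for a rule that makes that decision: scoring a
short prognostic questionnaire, deriving four clinical characteristics,
selecting the factors statistically associated with eventual specialist
referral, internally validating the resulting model, and evaluating
candidate fast-track rules before fixing the final three-group allocation
algorithm.

Because the development cohort's patient-level data are not public, the
package ships a synthetic-cohort generator calibrated to the cohort's
published aggregate properties. Everything downstream of the generator is
pure method code that would run unchanged on real data in the documented
cohort schema (`cohort_schema()`).

## The subgrouping algorithm

Two inputs drive the allocation (`allocate()`):

* **Prognostic risk** from the 9-item STarT Back tool
  (`score_startback()`): items 1–8 are agree/disagree, item 9 (bothersome-
  ness) scores 1 for "very much" or "extremely". Total ≤ 3 ⇒ *low* risk;
  psychological subscore (items 5–9) ≥ 4 ⇒ *high* risk; otherwise *medium*.
  Since psych ≥ 4 forces total ≥ 4 the two clauses never conflict. The
  package refuses to score incomplete tools rather than impute.
* **Four clinical characteristics** (`derive_characteristics()`): impact on
  work/home activities (work-interference NRS > 6 for those in work,
  otherwise a "yes" on the RMDQ jobs-around-the-house item), current leg
  pain NRS > 6, sensory deficit on pin-prick (reduced *or* lost sensation —
  this coding reproduces the published sensory-deficit frequencies), and
  pain below the knee. Both NRS cut-offs are strict (> 6).

Allocation: low risk ⇒ group 1 (self-management support) irrespective of
characteristics; high risk with ≥ 3 characteristics or medium risk with all
4 ⇒ group 3 (fast-track referral); otherwise group 2 (physiotherapist-led
care). The rule is total and monotone over the 15 (risk, count) cells —
both properties are enumerated in the tests. A patient in work whose
work-interference NRS is missing falls back to the RMDQ item (this
maximizes usable records); any characteristic whose source is missing is
left indeterminate, and allocation is refused only when the indeterminate
flag could actually change the group (a low-risk patient allocates to
group 1 regardless; a high-risk patient with three confirmed flags
allocates to group 3 regardless of the fourth).

## Factor selection

`referral_model()` reproduces the development procedure as one fitting
function:

1. **Univariable stage.** Each candidate factor, organized into five
   clinical domains (`atlas_blocks()`), is regressed on referral alone.
2. **Collinearity screen + within-block stage.** Within each block,
   pairwise correlations use the type-appropriate coefficient (Pearson for
   numeric, Spearman for ordinal, point-biserial for binary); while any
   pair exceeds |r| > 0.7 one member is dropped — never a variable in the
   block's `force_keep` list, otherwise the member more correlated with the
   rest on average, ties resolved by dropping the later-listed variable.
   VIF > 5 on the survivors drops the rest. The surviving block members
   enter a within-block multivariable model; terms with joint Wald p < 0.05
   progress. A single-variable block progresses on its univariable result
   unchanged. The pain block is intentionally near-degenerate (all items
   reflect one severity construct), so the default `force_keep` carries
   current leg pain forward, mirroring the clinical override used in
   development; the screen's output records exactly which variable each
   drop was attributed to.
3. **Overall stage.** All block survivors enter one model; the term with
   the largest Wald p is removed (one per step) while any term has
   p ≥ 0.05. "Significant" is strict: p exactly 0.05 is eliminated.

Numerical choices: significance of multi-level factors uses the joint Wald
chi-square on the term's coefficients (so a 3-level examination finding is
kept or dropped as a unit, matching how it is entered); pin-prick sensation
enters as a 3-level factor with "normal" as reference; separated fits
(non-finite or extreme estimates) exclude the variable from multivariable
stages with the reason recorded. The selection trace gives every candidate
exactly one final disposition, and the procedure is deterministic given the
data.

For 2×2 tables, `odds_ratio_2x2()` uses the cross-product estimate with a
Wald CI; a single zero cell triggers the Haldane–Anscombe 0.5 correction
(flagged in the output), while a zero margin is an error because the odds
ratio is then genuinely undefined.

## Internal validation

`validate()` implements the enhanced bootstrap: patients are resampled with
replacement, the final model *specification* is refit in each resample, and
optimism is the mean difference between the resample AUC and the AUC of
that refit model on the original cohort; the optimism-corrected AUC is the
apparent AUC minus this optimism. Defaults: 500 replicates, seed recorded
in the report. AUC is tie-aware pairwise concordance; the apparent AUC's CI
uses DeLong's method (the standard choice for a single fitted model), and
the CI for the mean bootstrap AUC is a normal approximation over replicate
values. Replicates are discarded (and counted, with a warning above 10%)
only when the resample outcome is single-class or the refit yields aliased
or non-finite coefficients — a separated fit with finite estimates still
ranks patients correctly and is kept; this choice keeps the estimator
defined even for noise-free outcomes, where every resample separates and
optimism is legitimately zero. Negative optimism is possible and flagged
rather than truncated.

`calibration_slope()` refits the outcome on the model's linear predictor.
On the development data the maximum-likelihood score equations force the
slope to 1 — the package reports it with full precision and treats the
identity as a correctness check — while slopes below 1 in fresh data
measure overfitting (a shrinkage property verified by simulation in the
tests).

## Scenario evaluation

`scenario_rule()` defines a fast-track predicate over (risk class,
characteristic count); `evaluate_rule()` tabulates it against observed
referral and reports sensitivity, specificity, PPV, NPV and the fraction
fast-tracked. Proportion CIs use the Wilson score interval (well-behaved at
these sample sizes and event counts; the development report did not name a
method). Low-risk patients are never fast-tracked when the rule excludes
them but always remain in the denominators — the only reading consistent
with the published scenario arithmetic. Patients with indeterminate inputs
are excluded complete-case and counted. Internally all arithmetic is kept
at full precision; percentages are rounded only for display.

## The synthetic cohort generator

`generate_cohort()` emulates the development study's screening and
case-mix. Design:

* **Latent structure.** A standard-normal global severity drives most
  variables. The pain/bothersomeness block loads 0.9 on a *pain* latent
  that itself loads 0.55 on global severity: within-block correlations
  exceed 0.7 (so the collinearity screen has something real to find) while
  cross-domain confounding stays mild, which matches the small
  unadjusted-to-adjusted attenuation visible in the published odds ratios.
  STarT Back psychological items load 1.3 on a psychological latent
  (loading 0.6 on severity); physical items load 1.1 on severity directly.
* **Marginals.** Intercepts and thresholds are solved at run time by
  numerical integration so each binary/ordinal variable hits its target
  prevalence exactly in expectation (`default_marginals()` prints every
  target). NRS and questionnaire scores are integer-valued discretized
  truncated normals, as the instruments are. Published means, SDs and
  frequencies supply the targets; in-work prevalence (0.55) and the RMDQ
  item difficulty ladder are not published and were set once to values
  typical of primary-care sciatica cohorts.
* **Referral.** Drawn from a logistic model in the four characteristics
  plus medium/high risk indicators (`referral_coefficients()`) — the
  minimal generating structure consistent with the published associations.
  The coefficients were calibrated once, by iterative simulation, so large
  cohorts reproduce the published *unadjusted* magnitudes: impact OR
  ≈ 2.64, per-point current leg pain OR ≈ 1.20, sensory deficit ≈ 1.93,
  risk-class gradient ≈ 6.4/10.4 against low risk, and 13.3% referral
  prevalence among eligible patients.
* **Eligibility.** Screened patients are eligible with probability 429/609;
  eligible patients draw diagnostic confidence uniformly in 70–100,
  ineligible in 0–69, so the ≥ 70% confidence filter reproduces the
  published attrition.
* **Missingness.** Missing completely at random at 2% per
  neurological-examination field (the published tables report only "a small
  proportion" of missing data, with no mechanism); all other fields are
  complete by default. Work interference is structurally absent for
  patients not in work and is not counted as missing.

What the generator does *not* emulate: longitudinal follow-up, treatment
received, MRI findings, any informative missingness, item-level STarT Back
marginals (only the risk-class mix is calibrated), and the exact
per-variable denominators of the published tables (which reflect an
unrecoverable missingness pattern). Passing simulation tests therefore
demonstrates that the *procedures* behave correctly under a plausible
data-generating process with the published aggregate structure — not that
they would reproduce the original cohort's patient-level results.

## Problem sizes and what the tests show

The simulation tests run at the development study's scale (609 screened /
≈ 429 eligible / ≈ 13% events): 200 replicates for selection behaviour, 100
for coefficient recovery (all six generating log-odds covered by 95% CIs in
≥ 90% of replicates), 500 bootstrap replicates for one validation run, and
100,000-patient cohorts for marginal convergence. One power fact is worth
stating plainly: with ≈ 57 events, a sensory-deficit effect of the
published magnitude gives the 2-df factor test only ~30% power, so
sensation survives selection in a minority of simulated replicates even
though it is truly predictive — the procedure is working as designed at
that sample size; the tests therefore check that truly predictive factors
with adequate power (impact, leg pain) are retained in a majority of
replicates and that the conditionally redundant pain self-efficacy is
dropped in a majority, rather than asserting a retention rate the design
cannot support.

## Known limitations

* The allocation rule is reproduced as published; the package does not
  revisit the cut-offs (> 6 NRS, ≥ 3 / = 4 characteristic counts), which
  were fixed by clinical consensus, and offers no penalized or Bayesian
  alternatives to the selection procedure.
* Backward elimination by largest Wald p is the minimal procedure
  consistent with "dropped as not significant"; other orderings could
  retain different factor sets in borderline data.
* The generator's single-severity-latent geometry is a simplification; real
  questionnaire data have residual structure (method effects, item
  clustering) it does not model.
* Complete-case analysis throughout matches the development report but
  discards ~10% of records at the default missingness; no imputation is
  provided.
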