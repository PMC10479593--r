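---
title: "Methods: a literature-based naive-Bayes cardiovascular risk model for CKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a literature-based naive-Bayes cardiovascular risk model for CKD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calibra)
```

## The model

`calibra` predicts the probability that a patient with non-dialysis-dependent
chronic kidney disease (NDD-CKD) is hospitalized at least once for a
cardiovascular event within one year. The predictor is a naive-Bayes
classifier: a binary outcome node $Y$ (cardiovascular hospitalization within
1 year) with every risk factor $X_1, \dots, X_K$ a child of $Y$ and mutually
independent given $Y$. For a set $E$ of observed variables,

$$
\frac{P(Y=1 \mid E)}{P(Y=0 \mid E)}
  = \frac{P(Y=1)}{P(Y=0)} \prod_{i \in E}
    \frac{P(x_i \mid Y=1)}{P(x_i \mid Y=0)},
$$

computed in log space (`predict_risk()`). The defining practical property is
how missing data are handled: a variable that is not observed simply
contributes no factor, which under the naive-Bayes factorization is the
*exact* marginalization over its states — no imputation, no complete-case
restriction. `enumerate_joint_posterior()` materializes the full joint and
conditions on evidence by summation; the test suite holds the fast product
formula to the enumeration within 1e-12 across random models, including
arbitrary missing subsets.

Why naive Bayes rather than a fitted regression? The parameters do not come
from any single cohort: each conditional probability table (CPT) is compiled
from published effect sizes. That makes the model buildable where no
sufficiently large and complete derivation dataset exists, and extensible —
a new risk factor is one more CPT.

## From literature to conditional probability tables

Each published finding is an `effect_record`: variable, exposure state,
effect measure (odds, risk, or hazard ratio) with confidence interval, study
size, follow-up, and flags for populations outside scope. `filter_studies()`
keeps records with at least one year of follow-up and drops pediatric,
renal-replacement-therapy and other-disease populations.

Records for the same variable and state are pooled by fixed-effect
meta-analysis on the log scale with *normalized sample size* as the weight:

$$ \log \widehat{\theta} = \sum_i \frac{n_i}{\sum_j n_j} \log \theta_i . $$

The log scale is standard for ratio measures; mixing different measures in
one pool is a hard error rather than a silent conversion.

A pooled ratio is then inverted into the two conditionals the network needs.
Given the outcome prevalence $p = P(Y{=}1)$ and the exposure prevalence
$q = P(E{=}1)$, `or_to_conditionals()` solves the 2x2 table exactly:

$$ q = p\,a + (1-p)\,b, \qquad \frac{a/(1-a)}{b/(1-b)} = \mathrm{OR}, $$

a quadratic in $b = P(E{=}1 \mid Y{=}0)$ whose admissible root lies in
$(0,1)$; for a fixed-margin 2x2 table such a root exists for every positive
odds ratio. Risk ratios invert in closed form
($a = \mathrm{RR}\,q / (1 - q + \mathrm{RR}\,q)$), and combinations implying
a risk above 1 raise an infeasibility error naming the constraint. Hazard
ratios are treated as risk ratios over the one-year horizon — a deliberate
approximation that is accurate while the one-year event probability is a few
percent, and is recorded per record by its measure tag so a different rule
can be substituted.

Multi-state variables are handled state-wise: each non-reference state is
collapsed against the rest and inverted with its own marginal prevalence,
the reference state takes the residual mass, and both CPT columns are
renormalized. For binary variables this is exact; for multi-state variables
it is an approximation to the (under-determined) joint elicitation problem
that preserves each state's marginal prevalence and its effect direction.
Cells are kept away from the boundary by additive smoothing
($\varepsilon = 10^{-6}$, then renormalization), so every log likelihood
ratio is finite.

## Tunable parameters

* **Outcome prior** (`prior`, default 0.03). The assumed annual incidence of
  cardiovascular hospitalization. NDD-CKD cohorts typically run 2–4 per 100
  person-years; 0.03 sits in that band. It is a deployment parameter: a
  clinic with a known local incidence should set it.
* **Cut-points** (per variable, in the variable's units). KDIGO G-stages for
  eGFR (15/30/45/60/90 ml/min/1.73 m²), A-category-style bins for
  proteinuria (0.15/0.5 g/24 h, with ACR 3/30 mg/mmol as an alternative
  channel mapping to the same states), and conventional laboratory
  thresholds elsewhere (e.g. HDL 40/60 mg/dl, PTH 65/300 ng/l). Binning is
  half-open: a value equal to a cut-point goes to the upper bin. Age uses
  50/65/80 with reference 65–79, the modal band of elderly CKD cohorts, so
  younger age acts as the protective deviation from baseline.
* **Smoothing** $\varepsilon$ (default 1e-6): only relevant when residual
  reference-state mass hits 0; large enough to keep ratios finite, small
  enough to be invisible at reporting precision.

## Explanation metrics

Two per-patient surfaces accompany the risk number:

* **Impact (normalized likelihood).** For an observed item $e$,
  $\mathrm{NL}(e) = P(e \mid Y{=}1) / P(e)$, which equals the single-item
  posterior-to-prior ratio $P(Y{=}1 \mid e)/P(Y{=}1)$. NL > 1 is
  risk-increasing, NL < 1 protective. `impact_report()` ranks the observed
  evidence by NL. NL is marginal per item by construction; the product of
  per-item likelihood ratios — not of NLs — recovers the posterior odds, and
  the tests assert exactly that identity.
* **Value of information.** For an unmeasured candidate $X$,
  $\mathrm{VOI}(X) = H(Y \mid E) - \sum_s P(s \mid E) H(Y \mid E, s)$ in
  bits (base 2; rankings are base-invariant), the conditional mutual
  information $I(Y;X \mid E)$ under the model. It is myopic — one candidate
  at a time, matching the clinical question "which single test next?" —
  and non-negative, zero exactly under conditional independence.
  `indexed_voi()` reports two normalizations, because an "indexed" value can
  plausibly mean either of two things: `max` divides by the largest VOI (top
  entry = 1), `residual-entropy` divides by $H(Y \mid E)$ (fraction of the
  remaining outcome uncertainty removed). The ranking is identical under
  both; the mode is recorded in the report rather than left implicit.

## Comparator scores and evaluation

Equation-based cardiovascular scores are represented as data
(`equation_score`): Cox form $\;risk = 1 - S_0^{\exp(LP)}$ with per-input
transforms, centering constants, optional sex strata and an LP offset. The
shipped Framingham general-CVD file carries the published coefficients; the
ASCVD-form and INDANA-form files are *synthetic placeholders* (marked as
such in filename and content) that preserve those tools' input sets so that
computability under missingness can be studied without asserting anything
about the real instruments. Equation scores are deliberately evaluated
complete-case: one missing input makes them not-computable, which is
precisely the contrast with the naive-Bayes score that
`computability_report()` quantifies.

Evaluation follows standard discrimination methodology, implemented
in-package and cross-checked in the tests against independent
implementations (pROC) and brute-force oracles:

* `roc_auc()`: Mann–Whitney AUC, ties counted one half; DeLong
  structural-components variance for the confidence interval.
* `delong_paired()`: paired comparison of correlated AUCs, covariance via
  the shared structural components; identical scores return $p = 1$ by
  convention.
* `gatekeeping_test()`: fixed-order testing. Step 1, non-inferiority — the
  one-sided 95% lower confidence bound of $\Delta\mathrm{AUC}$ must clear
  the margin $-\sigma$ with $\sigma = 0.05$. Step 2, evaluated only if step
  1 passes (so the type-I error is not inflated): superiority requires
  *both* $\Delta\mathrm{AUC} \ge 0.05$ and DeLong $p < 0.05$. The
  conjunction matters: a small advantage can be highly significant in a
  large cohort yet fall short of the 0.05 threshold, and the procedure then
  reports "significant but not superior". The wording "a one-sided
  confidence interval of the AUC" is ambiguous between the paired
  difference and the new score's own AUC; the difference reading is the
  default and the alternative sits behind `ni_on_difference = FALSE`.
* `calibration_by_quantile()`: quantile bins with stable-rank tie-breaking
  (duplicated scores cannot create empty bins), per-bin mean prediction vs
  observed incidence, and adjacent-bin risk ratios (flagged `NA` on a zero
  denominator rather than returning infinities).
* `incidence_density()`: events per person-year with the exact
  chi-square-based Poisson interval; the lower limit is 0 at zero events.

## The synthetic-cohort generator

`simulate_cohort()` reads the network generatively: draw
$Y \sim \mathrm{Bernoulli}(prior)$, then each variable from its CPT column
given $Y$. This is the model's own data-generating process, so it supports
sharp self-consistency checks: re-estimated conditionals converge to the
CPTs (the suite requires ≥95% of entries within 3 binomial SEs at
n = 50,000, the 3-SE band itself admitting ~0.3% benign exceedances), and
true-model scores self-calibrate (per-quintile |predicted − observed| <
0.015 at n = 20,000).

Missingness is MCAR only, per-variable, never touching the outcome column.
Two presets encode qualitative registry patterns: `registry-heavy`
(purposefully prescribed labs — lipids, CRP, IL-6, hsTNT, PTH, proteinuria —
40–70% missing, demographics complete) and `protocol-light` (≤5%
everywhere), mimicking routine-care versus protocolized data collection.
These are caricatures by design: real registry missingness is informative
(sicker patients get more tests), so passing MCAR-based tests demonstrates
numerical robustness to incompleteness, not immunity to informative
missingness. Continuous variables are simulated at the state level, since
the model is defined on states.

Problem sizes in the tests (50,000 for parameter recovery, 20,000 for
calibration, 1,000 replicates for the type-I-error simulation at n = 500)
were chosen to make the Monte-Carlo error comfortably smaller than each
asserted band.

## The worked case

`case_study_fixture()` encodes a 45-year-old obese man (BMI 41) with stage
G4 CKD (eGFR 25) of likely diabetic origin, a past smoker with hypertension
and COPD, albumin 4.00 g/dl, calcium 8.9 mg/dl, hemoglobin 12.53 g/dl,
phosphate 4.19 mg/dl, PTH 289 ng/l, proteinuria 2.49 g/24 h. Hemoglobin
enters through the anemia node (12.53 g/dl in a man is below the 13 g/dl
threshold); serum calcium has no corresponding node and stays in the raw
record. CRP, hsTNT and uric acid are among the unmeasured variables, and
under the shipped model the VOI ranking puts the inflammatory and cardiac
markers at the top — the clinically sensible "measure these next" answer
for this patient.

## What the shipped parameters are — and are not

The evidence table and prevalences under `inst/extdata/` are **synthetic**:
clinically plausible effect magnitudes and state prevalences chosen once to
exercise every code path (multiple studies to pool, OR/RR/HR records,
excluded studies, multi-state variables). They are not a literature review,
and the numbers the package prints for the worked case (a risk of ~16%, the
specific NL and VOI values) are properties of this demonstration model, not
of any validated instrument. A real deployment replaces the two files — the
entire pipeline from CSV to scored patients is data-driven.

## Known limitations

* Conditional independence given the outcome is a strong assumption;
  correlated risk factors (eGFR and proteinuria, say) have their joint
  evidence double-counted to a degree the model cannot see.
* The state-wise inversion for multi-state variables is approximate (exact
  only for binary variables).
* HR-as-RR is a one-year-horizon approximation.
* MCAR-only missingness in the simulator, as discussed above.
* Calibration of the shipped model is self-calibration by construction;
  nothing here validates calibration against real cohort data.
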