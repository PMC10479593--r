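# calibra

Literature-based naive-Bayes prediction of one-year cardiovascular
hospitalization risk in non-dialysis-dependent chronic kidney disease
(NDD-CKD), with value-of-information and impact explanations, comparator
equation scores, and the full evaluation toolbox (AUC, paired DeLong,
fixed-order non-inferiority/superiority, quantile calibration, exact
Poisson incidence).

Cardiovascular disease is the leading cause of death in CKD, yet the
established risk calculators (Framingham, pooled-cohort ASCVD, INDANA) were
derived in general populations, ignore CKD-specific risk factors, and —
being closed-form equations — simply cannot be computed when any required
input is missing, which in routine-care registries is most patients. This
package is for biostatisticians and nephrology researchers who want a risk
model that (a) is compiled from published effect sizes instead of a single
derivation cohort, (b) scores **every** patient, whatever subset of the 31
risk factors happens to be measured, and (c) explains each score.

## The model

A naive-Bayes classifier: outcome node Y (≥1 cardiovascular hospitalization
within 1 year), every risk factor conditionally independent given Y.
Posterior odds are prior odds times the product of per-item likelihood
ratios over the *observed* variables:

    P(Y=1|E) / P(Y=0|E)  =  P(Y=1)/P(Y=0) · ∏_{i∈E} P(x_i|Y=1) / P(x_i|Y=0)

Unobserved variables drop out — this is the exact marginalization, so
missing data need no imputation. Parameters come from the literature: per
variable/state, published odds/risk/hazard ratios are pooled by
fixed-effect meta-analysis weighted by normalized study sample size,

    log θ̂ = Σᵢ (nᵢ / Σⱼ nⱼ) · log θᵢ ,

then inverted exactly into conditional probability tables given the outcome
prevalence p and exposure prevalence q (for an odds ratio, the quadratic
2×2-table solution of `q = p·a + (1−p)·b`, `odds(a)/odds(b) = OR`).

Each score comes with two explanation surfaces: **impact** — per observed
item the normalized likelihood `NL = P(e|Y=1)/P(e)` (>1 risk-increasing,
<1 protective) — and **value of information** — per unmeasured variable the
expected entropy reduction `I(Y;X|E)` in bits, ranking which test to order
next.

The evidence table and prevalences shipped under `inst/extdata/` are
**synthetic demonstration values** (plausible magnitudes, labelled as such);
swap in your own CSV/JSON to build a real model.

## Worked example

Score the package's worked case: a 45-year-old obese man (BMI 41), stage G4
CKD (eGFR 25), diabetic etiology, past smoker, hypertension, COPD, PTH
289 ng/l, proteinuria 2.49 g/24 h — 13 variables observed, 18 missing.

```r
library(calibra)

model   <- example_model(prior = 0.03)   # compiled from the shipped evidence
patient <- case_study_fixture()

predict_risk(model, patient$evidence)
#> <risk> P(Y=1 | evidence) = 0.1609 (prior 0.0300; 13 observed, 18 missing)

head(impact_report(model, patient$evidence), 4)
#>      variable state       nl       direction
#> 1        copd   yes 1.671001 risk-increasing
#> 2 proteinuria    A3 1.647056 risk-increasing
#> 3         bmi   35+ 1.472181 risk-increasing
#> 4    diabetes   yes 1.433557 risk-increasing

head(indexed_voi(model, patient$evidence), 3)
#>                   variable   voi_bits indexed_voi rank
#> 1                      crp 0.02537056   1.0000000    1
#> 2                    hstnt 0.02319152   0.9141114    2
#> 3 congestive_heart_failure 0.01847121   0.7280567    3
```

Reading: under the demonstration model this patient's one-year risk is
about 16% against a 3% prior; COPD, heavy proteinuria, obesity and diabetes
drive it up (his age, 45, is protective — not shown); and of everything not
yet measured, C-reactive protein and resting hsTNT would reduce outcome
uncertainty the most, so they are the tests to order next.

Cohort-level work goes through `simulate_cohort()` / `batch_score()` and
the evaluation functions (`roc_auc`, `delong_paired`, `gatekeeping_test`,
`calibration_by_quantile`, `incidence_density`), or the command line:

```sh
Rscript inst/cli/calibra simulate --model model.json --n 10000 --seed 7 \
    --preset registry-heavy --out cohort.csv
Rscript inst/cli/calibra score --model model.json --cohort cohort.csv \
    --out scored.csv
Rscript inst/cli/calibra explain --model model.json --case-study \
    --out report.json
```

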