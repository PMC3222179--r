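# rsmcat

Computerized adaptive testing (CAT) for polytomous questionnaires under the
Rasch rating scale model, with a simulation framework that quantifies how
much shorter an adaptive administration can be than the full instrument
without losing measurement precision.

The motivating instrument is an 18-item inpatient perception questionnaire
(IPQ-18) administered to patients at hospital discharge. Asking all 18
questions of every patient (nonadaptive testing, NAT) is burdensome; an
adaptive engine that picks each next question to be maximally informative
about the patient's current estimated perception level can stop early once
the measure is precise enough. rsmcat implements that engine against an
anchored item bank and reproduces the CAT-versus-NAT comparison study in
simulation. It is written for psychometricians and health-services
researchers working with Rasch-calibrated patient-reported instruments.

## The model and the engine

Responses are integer scores `0..4`. Under the rating scale model, the
probability of category *k* on item *i* at person measure θ (logits) is

    P(X_i = k | θ) ∝ exp( k(θ − δ_i) − Σ_{j≤k} τ_j )

where δ_i is the item's overall difficulty and τ_1 < … < τ_4 are category
thresholds shared by all items; the step difficulty δ_i + τ_j is where
adjacent categories are equally probable. The engine:

* estimates θ by maximum likelihood (Newton-Raphson on the concave Rasch
  likelihood; SE = 1/√(Σ W_i), with W_i the category-score variance, i.e.
  the item information);
* selects each next item to maximize W_i at the provisional θ;
* stops at SE ≤ 0.51 logits (the error SD implied by the calibration's
  person separation reliability: 2.09 × √(1 − 0.94)) after at least 10
  items;
* computes infit/outfit mean squares per respondent, flagging outfit ≥ 2
  as possibly aberrant;
* simulates whole cohorts and compares CAT against full-length NAT
  (paired t, Pearson r, efficiency gain = 1 − CAT responses/NAT
  responses).

The anchored IPQ-18 bank (18 difficulties, shared thresholds −3.76, −1.91,
1.57, 4.11, calibration metadata) ships with the package, both built in
(`builtin_ipq18()`) and as JSON/CSV fixtures under `inst/extdata/`.

## Worked example

```r
library(rsmcat)
bank <- builtin_ipq18()

# one simulated respondent at true measure 0.71 logits
set.seed(1)
run_cat_for_person(0.71, bank)
#> Adaptive test complete: 11 items, stop rule 'se_met'
#> Person measure 0.715 logits (SE 0.495), 11 items [newton_raphson]

# a 50-person CAT-versus-NAT study
run_study(study_config(n_persons = 50, seed = 2026), bank)
#> CAT-versus-NAT study: 50 persons x 18-item bank
#>   mean adaptive length 11.58 items; responses 579 vs 900
#>   efficiency gain 0.357 (mean length 11.58); r(CAT, NAT) 0.9669
#>   paired t (length): t(49) = -56.02, p <2e-16
#>   paired t (measure): t(49) = 0.60, p = 0.550
#>   adaptive measures: mean 0.66 (SD 1.66), median 0.76, skew -0.31, kurt 0.78
```

The respondent's adaptive test stopped after 11 items with a measure of
0.715 logits and SE just under the 0.51 target. In the cohort study, the
adaptive arm used 579 of the 900 responses the full instrument would have
required (a 36% saving), while the adaptive and full-length measures
correlate at r = 0.97 and do not differ systematically (paired t on
measures, p = 0.55) — shorter tests, same measurement.

A command-line front end is installed as `exec/rsmcat` with `validate`,
`run` (interactive administration), `simulate` and `report` subcommands.

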