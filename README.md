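# svycal

Design-based estimation and weight calibration for stratified two-stage
cluster school surveys, written for survey statisticians and epidemiologists
who need to turn a *regional* school sample into defensible regional — and,
with care, national — estimates of adolescent health and wellbeing
indicators.

The setting is a survey of secondary school students (years 9–13) in which
schools are the clusters: four design strata (kura kaupapa Māori schools
plus the mainstream schools of three education regions), 50% of schools
sampled within stratum, 30% of students within selected schools, heavy and
selective nonresponse. The package provides:

* **Design weights.** Inclusion probabilities multiply the stage fractions,
  `pi = f1[h] * f2[s]`, and weights are their reciprocals, `w = 1/pi` — the
  number of students each respondent represents.
* **Horvitz–Thompson estimation.** Totals `T̂_y = Σ w_i y_i` and ratio
  proportions `Σ w y / Σ w`, with the stratified with-replacement-PSU
  linearized variance
  `v = Σ_h n_h/(n_h−1) Σ_j (t_hj − t̄_h)²` and untruncated normal 95%
  intervals.
* **Calibration.** Minimal weight adjustment subject to exact reproduction
  of known demographic totals `Σ w̃ x = T_x` (school deciles, age bands,
  sex, prioritised ethnicity): the closed-form chi-square/GREG solution
  `w̃ = w (1 + x'λ)`, and raking `w̃ = w exp(x'λ)` as the
  positive-weights alternative. Calibrated variances use g-weighted GREG
  residuals, so calibration margins come back with exactly zero-width
  intervals.
* **A synthetic population generator** reproducing the study's frame
  dimensions, national demographic composition, logistic outcome models and
  selective nonresponse, plus a Monte-Carlo harness
  (`simulation_study()`) measuring bias, efficiency and coverage of the
  unweighted, design-weighted and calibrated estimators.

## A worked example

```r
library(svycal)
st <- run_study(run_config(seed = 42L))
st
```

```
Study run (seed 42): 7210 mainstream respondents

Participation:
                                      stage numerator denominator percent
      mainstream schools invited / eligible        81         161    50.3
 mainstream schools participating / invited        48          81    59.3
                    kura invited / eligible         6           8    75.0
               kura participating / invited         3           6    50.0
   mainstream students responding / sampled      7210       19025    37.9
         kura students responding / sampled       174         646    26.9

Outcome proportions (point estimates):
            variable unweighted    ht cal_regional cal_national    n
 depressive_symptoms      0.309 0.309       0.3023       0.2993 6940
      binge_drinking      0.220 0.220       0.2229       0.2312 6926
     regular_smoking      0.075 0.075       0.0763       0.0797 6922

Calibration g-weights (regional): [0.357, 8.611], 0 negative
```

The run generates a synthetic population, draws the two-stage sample,
applies school- and student-level nonresponse, and estimates each outcome
four ways. Unweighted and design-weighted proportions coincide here because
the mainstream design is self-weighting within strata; the calibrated
columns shift each estimate toward the demographic composition of the
regional (respectively national) student population. The
margin-reproduction table shows why the calibrated columns are trustworthy
for demographics:

```r
st$margin_table[st$margin_table$margin %in% c("female", "maori", "asian"),
                c("margin", "actual_regional", "ht_regional", "ht_lo",
                  "ht_hi", "cal_regional", "actual_national", "cal_national")]
```

```
 margin actual_regional ht_regional ht_lo ht_hi cal_regional actual_national cal_national
 female           66482       25947 22276 29618        66482          145477       145477
  maori           29140       10420  8193 12647        29140           64530        64530
  asian           21104        8947  7459 10435        21104           31675        31675
```

Design-weighted totals underestimate the population scale (weights are not
rescaled for nonresponse — calibration is the sole correction, and it
restores every constrained margin exactly). Estimated national quantities
are reported with calibrated weights only; a design-weighted national
column does not exist for a regional design.

The methods vignette (`vignettes/weight-calibration.Rmd`) documents the
estimators, the calibration distances, the generator's defaults, and the
known limitations of the margin convention.

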