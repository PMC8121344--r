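---
title: "Design weights and calibration for a regional school survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design weights and calibration for a regional school survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svycal)
```

## The estimation problem

`svycal` implements the design-based estimation workflow of a stratified
two-stage cluster survey of secondary school students, of the kind run in
New Zealand's three most ethnically diverse education regions (Auckland,
Tai Tokerau, Waikato): schools are the primary sampling units, students the
secondary units, and the four design strata are the kura kaupapa Māori
schools (one stratum across all three regions) plus the mainstream schools
of each region.  Eligible schools have strictly more than 50 students in
years 9–13; special and partnership schools are excluded.  Half the
mainstream schools of each stratum are sampled, then 30% of students within
each selected school; all kura students are invited, and individual schools
can be flagged as certainty (100% roll) units.

Because such surveys suffer substantial school- and student-level
nonresponse with a selective composition (more female and more Asian
respondents than the student population), and because a regional sample is
also used to make national statements, design weighting alone is not
enough.  The package therefore provides the three estimation layers a
survey statistician needs:

1. **Design weights.** Every student in school $s$ of stratum $h$ has
   inclusion probability $\pi_i = f_{1h} f_{2s}$ and design weight
   $w_i = 1/\pi_i$, "the number of students individual $i$ represents".
2. **Horvitz–Thompson (HT) estimation.** A total $T_y$ is estimated by
   $\hat T_y = \sum_{i \in \text{sample}} w_i y_i$, a proportion by the
   ratio $\sum w_i y_i / \sum w_i$, with variance from the standard
   stratified with-replacement-PSU linearization
   $v = \sum_h \frac{n_h}{n_h - 1} \sum_j (t_{hj} - \bar t_h)^2$,
   where $t_{hj}$ is the weighted school total of the score variable.
3. **Calibration.** Weights are minimally adjusted so that weighted totals
   of known demographic margins $T_x$ (school decile, age band, sex,
   prioritised ethnicity) are reproduced exactly:
   $\tilde w = \arg\min_w d(w, \tilde w)$ subject to
   $\sum \tilde w_i x_i = T_x$.  Under the chi-square distance
   $\sum (\tilde w_i - w_i)^2 / 2 w_i$ the solution is the closed-form GREG
   estimator $\tilde w_i = w_i (1 + x_i'\lambda)$; under the multiplicative
   distance ($\tilde w_i = w_i e^{x_i'\lambda}$, solved by damped Newton
   iteration) it is raking, identical to iterative proportional fitting on
   saturated categorical margins.

Calibrated-estimator variances use the GREG residual technique: the
residuals $e_i = y_i - x_i'\hat B$ of the design-weighted regression of $y$
on the margin columns, scaled by the $g$-weights $g_i = \tilde w_i / w_i$,
are pushed through the same stratified linearization.  A variable in the
span of the margins has zero residuals, hence an exactly degenerate
confidence interval — known totals are reproduced with no uncertainty,
which is the visible signature of calibration in a margin-reproduction
table.

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(seed = 42L)
st <- run_study(cfg)
st                      # participation, proportions, g-weight diagnostics
head(st$margin_table)   # actual vs HT vs calibrated, with 95% CIs
```

The margin-reproduction table shows the design-weighted estimates
scattering widely around the known totals (school deciles especially: a
decile is a school-level attribute, so its estimated total inherits the
full between-school sampling variability) while both calibrated columns
equal the known totals with zero-width intervals.  National quantities are
only ever reported with nationally calibrated weights; a design-weighted
"national" estimate does not exist for a regional design, and the package
deliberately produces no such column.

## Conventions and defaults

* **Margin sets.** The packaged margin fixtures
  (`inst/extdata/margins_*.json`) carry the published actual totals for the
  2019 three-region student population and the 2018 national population:
  deciles 1–9, age bands ≤13/14/15/16, female, and Māori / European /
  Pacific / Asian.  One category per partition (decile 10, age ≥17, male,
  Other ethnicity) is deliberately unconstrained, and no grand-total row is
  included, matching the published convention.  Consequences of that
  convention are discussed under *Limitations*.
* **Rounding.** Sample sizes use half-up rounding
  (`round_half_up`), so a stratum of 23 schools at $f_1 = 0.5$ invites 12;
  participation percentages are printed half-up to one decimal.
* **Nonresponse.** Refusing schools and absent students are dropped with
  design weights left untouched; calibration is the sole nonresponse
  correction.  No response-propensity reweighting stage exists.
* **Variance.** With-replacement PSU approximation, no finite-population
  correction by default (an optional stage-1 $(1 - f_{1h})$ multiplier is
  available).  At $f_1 = 0.5$ this is deliberately conservative: estimated
  SEs of totals exceed the empirical sampling SD by roughly $\sqrt 2$, and
  interval coverage of totals runs above nominal.  Confidence intervals
  are symmetric normal-approximation at $\pm 1.96$ SE and are never
  truncated at zero.
* **Missing outcomes** are dropped per variable (complete case), weights
  not reallocated.
* **Negative weights** can arise under the linear distance and are
  reported in the calibration diagnostics, never silently altered; raking
  guarantees positivity if that matters more than closed-form exactness.
* **Degenerate inputs.** A margin without sample representation, a
  collinear margin matrix, and a stratum reduced to a single responding
  school all raise informative errors (the last names the stratum, since
  the variance formula needs $n_h \ge 2$).

## The synthetic population generator

Real microdata for such surveys are not publicly deposited, so the
package carries a generator whose defaults emulate the study dimensions:
161 eligible mainstream schools in the study regions (100/23/38) plus 8
kura, 238 eligible mainstream schools elsewhere (407 nationally), with
log-normal rolls whose expectations match the published student counts
(~129.8k mainstream study-region students, ~927 kura, ~280k national).
Demographics follow the national 2018 composition (female 0.503, Māori
0.207, Pacific 0.096, Asian 0.117, European 0.519, five age bands between
0.17 and 0.22), with region-specific ethnic mixes (the Auckland analogue
carries the Asian concentration) and a school-decile tilt placing more
Māori and Pacific students in low-decile schools.  Rolls truncate below at
51 so the eligible counts are exact by construction.

Outcomes are Bernoulli draws from logistic models additive in sex,
ethnicity, age band and decile tercile.  The three default outcomes are
labelled after familiar adolescent-health indicators (depressive symptoms,
binge drinking, regular smoking) purely as labels; their coefficients are
configuration, chosen once at plausible magnitudes (e.g. a +0.6 log-odds
female effect on depressive symptoms, a strong positive age gradient and a
−0.9 Asian effect on binge drinking).  The response model refuses schools
at rate $1 - 0.563$ and students by a logistic model (intercept 0.16,
female +0.35, Asian +0.55, small decile effects) so that overall student
response lands near 0.6 and respondents over-represent female and Asian
students — the published selectivity pattern.  Margin sets emitted with a
population are exact tabulations of the generated mainstream students
(kura excluded, as in the published margin tables), so calibration targets
are internally consistent by construction; margins with a zero population
count are dropped rather than emitted as degenerate constraints.

What the generator does **not** emulate: inter-outcome correlation beyond
shared demographics, joint demographic structure beyond the marginal
shares and the decile tilt, school-size–decile dependence, or any
questionnaire content.  Passing tests therefore demonstrate the estimation
machinery under a known, well-behaved data-generating process — not that
any particular real-world estimate is correct.

## What the Monte-Carlo suite verifies

The test suite redraws 500 two-stage samples from one fixed synthetic
population (the design-based frame of reference), with and without the
nonresponse mechanism, and checks:

* **Unbiasedness of HT estimation** — exactly, by enumerating all samples
  of toy designs, and to within 1% for proportions at the study scale.
* **Efficiency** — the mean estimated SE of the calibrated estimators
  never exceeds the mean HT SE for any outcome, total or proportion (the
  classical guarantee that calibration cannot hurt precision, in
  expectation).
* **Nonresponse correction** — under the selective response model the
  design-weighted proportions are biased with the signs the coefficients
  imply, and calibration shrinks the bias for every outcome.
* **Oracle equivalences** — the weight-based calibrated total equals the
  independently computed regression (GREG) estimator to machine precision;
  raking equals iterative proportional fitting on a 2×2 margin table; the
  linearized variance equals the delete-one-PSU jackknife exactly for
  totals and within 1% for ratios.
* **Coverage** — 95% intervals for HT proportions cover at nominal rate
  (within [92%, 98%]) under full response.

Replicates where a margin loses sample representation or a stratum drops
to a single responding school are counted and skipped (about 8% of
replicates under the default nonresponse model); this is reported, not
hidden.

## Known limitations

Two genuine, quantifiable biases survive at the study conditions, and are
worth understanding rather than papering over:

* **Nominal-fraction weights vs realized sample sizes.**  Weights use the
  nominal fractions ($w = 1/(f_1 f_2)$) while sample sizes are rounded,
  so a 23-school stratum samples 12 schools at a claimed $\pi = 0.5$
  (realized 0.522).  HT *totals* inherit a structural bias of roughly
  +1% (concentrated in outcomes that load on the odd-sized stratum);
  proportions are essentially unaffected because the distortion cancels
  in the ratio.
* **Unconstrained categories under whole-sample nonresponse.**  A
  respondent whose every category is omitted from the margin list (male,
  Other ethnicity, age ≥17, unknown/10th-decile school) has an all-zero
  margin row, keeps $g = 1$, and never recovers the ~0.6 response scale
  loss; with no grand-total constraint the calibrated weight sum
  undershoots the population size by 2–3%, and outcomes loading on those
  cells (the binge-drinking analogue, with its strong age-≥17 gradient)
  retain a 1–2% downward bias in calibrated proportions and 2–5% in
  totals.  Constraining the grand total removes most of this; the package
  keeps it off by default because the published margin tables carry no
  total row, but `margin_set(..., grand_total = N)` enables it in one
  argument.  National extrapolation adds a further joint-composition
  mismatch of the same order for strongly nonlinear outcomes.

Problem sizes were chosen once for the validation suite: one synthetic
population (~270k students), 500 replicates per Monte-Carlo condition, and
enumeration or small multi-PSU toys wherever an exact oracle exists.
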