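---
title: "Methods: model, metrics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, metrics and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quizpk)
```

# Structural model

Quizartinib disposition is described by a mamillary three-compartment model
with first-order oral absorption: a depot compartment feeding a central
compartment (volume $V_2$) at rate $K_A$, elimination by clearance $CL$ from
the central compartment, and two peripheral compartments ($V_3$, $V_4$)
exchanging with the central one at intercompartmental clearances $Q_3$ and
$Q_4$. In amounts $A_1,\dots,A_4$ (µg):

$$
\begin{aligned}
\dot A_1 &= -K_A A_1 \\
\dot A_2 &= K_A A_1 - (k_e + k_{23} + k_{24})A_2 + k_{32}A_3 + k_{42}A_4 \\
\dot A_3 &= k_{23}A_2 - k_{32}A_3 \\
\dot A_4 &= k_{24}A_2 - k_{42}A_4
\end{aligned}
$$

with $k_e = CL/V_2$, $k_{23} = Q_3/V_2$, $k_{32} = Q_3/V_3$,
$k_{24} = Q_4/V_2$, $k_{42} = Q_4/V_4$. Plasma concentration is
$C(t) = A_2(t)/V_2$; each dose enters the depot as
$F_1 \times \text{dose (mg)} \times 1000$, so that mg doses and litre volumes
yield ng/mL concentrations with the unit conversion applied exactly once.

## Closed-form solution

The system is linear, so a single dose contributes a sum of four exponential
modes. `quizpk` computes their rates and residues analytically: the three
disposition rates are the roots of the characteristic cubic (quadratic or
linear when peripheral compartments are disconnected), obtained by the
trigonometric closed form, and the fourth pole is $-K_A$; residues follow from
the partial-fraction expansion of the Laplace transform. Multiple doses are
superposed, and for uniform once-daily schedules the superposition collapses
into a per-mode geometric partial sum evaluated backwards from the most recent
dose, which is numerically stable because every rate is negative.

Three layers back each other up:

1. analytic poles/residues (used almost always);
2. an eigen-decomposition of the compartment matrix, reduced to the active
   compartments, when pole expressions collide;
3. a `deSolve` ODE integration (`rtol = atol = 1e-10`) for genuinely
   degenerate parameter sets (e.g. $K_A = k_e$, a repeated pole).

The test suite pins layer 1 against the Bateman closed form, layer 3 against
the $t e^{-kt}$ repeated-pole solution, and all layers against mass balance
(total amounts, including eliminated drug computed as $k_e \int A_2$, equal
cumulative absorbed dose to $10^{-6}$ relative).

Steady state uses the closed geometric limit
$\sum_i c_i e^{\lambda_i t} / (1 - e^{\lambda_i \tau})$; the `"auto"` dose
count lays down enough doses for the slowest mode to decay below $10^{-9}$.

# Parameters, units and provenance

The packaged config `inst/extdata/quizartinib_model.yaml` carries the
published typical values ($CL$ 1.76 L/h, $V_2$ 227.32 L, $V_3$ 176.03 L,
$V_4$ 39.30 L, $Q_3$ 26.56 L/h, $Q_4$ 0.56 L/h, $K_A$ 1.68 h⁻¹, $F_1$ 0.75)
and refuses to load without explicit units (mg, L, L/h, h⁻¹, ng/mL, h). Two
provenance notes:

- The source tabulates $V_2 = 227.32$ L while its text quotes 212.9 L; the
  config uses the tabulated value.
- These parameters imply a terminal half-life of about 182 h
  (`pk_terminal_halflife(default_pk_parameters())`), i.e. pronounced
  accumulation under once-daily dosing.

# Synthetic cohort and its calibration

`generate_cohort()` emulates the validation study's *design*: 14 subjects on
30 mg once daily with food, one CYP3A4-inhibitor-free subject on 60 mg,
steady-state samples at predose/+2/+4/+6 h jittered within a ±15 min window
(predose drawn only before the dose), 64 % female, 79 % on a strong CYP3A4
inhibitor, and one subject contributing a single sample (53 observations).

The published typical parameters overpredict the study's reported timepoint
mean concentrations (82/129/141/120 ng/mL at 0/2/4/6 h) by roughly 4.5-fold —
an apparent exposure mismatch between the model's source population and this
cohort. The generator therefore keeps the published distribution parameters
but uses an effective $CL = 6.72$ L/h and $F_1 = 0.568$
(`default_cohort_parameters()`), fitted once by log-least-squares of the
typical steady-state profile to those four means (achieved profile
83.5/140.4/128.5/118.8 ng/mL). Between-subject variability
(`random_effects()`: CV² 0.09 on $CL$ and $V_2$, 0.04 on $F_1$) and residual
error (proportional SD 0.2, additive SD 1 ng/mL) are repository defaults
chosen to give realistic spread at this design — none of these are published
estimates, and the synthetic data must not be mistaken for the clinical
dataset.

Bioanalytical batches (`generate_bio_batch()`, `generate_matrix_batch()`)
mirror the method-validation layout: a 6–200 ng/mL calibration ladder, QC
levels 20/80/140 ng/mL in six replicates over three days, an area-ratio
response line $y = 0.0116x + 0.1429$, multiplicative intra-day noise, a
log-scale day effect, and configurable proportional bias; matrix batches
encode ion suppression (0.70) and extraction recovery (0.50) equally on
analyte and internal standard, so IS-normalized values are 1 by construction.

# Prediction and MAP estimation

PRED evaluates the model at typical values over each subject's actual dose
history and sampling times. IPRED comes from per-subject MAP estimation:
minimize

$$
\sum_j \left[ \frac{(DV_j - C_j(\eta))^2}{v_j} + \log v_j \right]
  + \eta^\top \Omega^{-1} \eta,
\qquad v_j = (\sigma_{prop} C_j)^2 + \sigma_{add}^2,
$$

by BFGS from $\eta = 0$ (with deterministic jittered restarts on
non-convergence and a Nelder–Mead polish). One property of this extended
least-squares objective matters for testing: the $\log v_j$ term pulls the
optimum away from the data by an amount proportional to $\sigma^2$, so
"exact recovery from noiseless data" is only meaningful in the small-$\sigma$
regime. The recovery tests use $\sigma_{prop} = 0.002$, where the recovered
$\eta$ is within $10^{-4}$ of truth; at $\sigma_{prop} = 0.2$ the same
optimizer is correct but the *objective's* optimum sits visibly off the
generating value.

# Validation metrics

With $PE = (C_{pred} - C_{obs})/C_{obs} \times 100$ (%), the suite reports
MPE (mean of $C_{pred} - C_{obs}$, ng/mL, with SD and a t or Wilcoxon test),
MdPE (median $PE$, bias), MdAPE (median $|PE|$, imprecision), F20/F30
(percent of observations with $|PE| \le 20$ or $30$), MdPE stratified by
concentration band ($<100$, $100$–$150$, $>150$ ng/mL, edges inclusive in the
middle band), and the squared Pearson correlation. Note that $|PE|$ is taken
of the percentage directly — a formulation that writes "$|PE| \times 100$"
with $PE$ already in percent would double-apply the factor. Acceptability
gates: MdPE within $[-20, 20]$ %, MdAPE $\le 30$ %, F20 $\ge 35$ %,
F30 $\ge 50$ %, all inclusive.

# Simulation diagnostics

**NPDE.** Each subject's observation vector is decorrelated with the mean and
Cholesky factor of the covariance of its `simulate_replicates()` draws; the
rank of each decorrelated observation among its decorrelated simulations
(uniform tie-jitter, clipped to $[0.5/K, (K-0.5)/K]$) is inverse-normal
transformed. Under a correct model the result is standard normal;
`npde_tests()` reports mean, variance, a t-test and a KS test. Numerically
rank-deficient simulated covariances (relative Cholesky pivot below $10^{-6}$)
fall back to variance-only decorrelation with a warning. At least $K = 100$
replicates are required for rank resolution; the acceptance suite uses
$K = 300$ over 1000 subjects.

**pcVPC.** Observations and simulations are prediction-corrected within time
bins, $pcY_{ij} = Y_{ij} \cdot \mathrm{median}(PRED_{bin}) / PRED_{ij}$; per
bin the observed 5th/50th/95th percentiles are compared with nonparametric
95 % intervals of the same percentiles across replicates. Default binning is
by nominal sampling time; undersized bins merge into a neighbor. $K = 200$
replicates is a deliberate desk-scale reduction of the conventional 1000 used
for the acceptance coverage check (the acceptance script and tests average
coverage across replicate cohorts because a single 14-subject cohort gives a
noisy coverage estimate).

# Problem sizes and limitations

Cohort sizes (14 for design emulation, hundreds-to-1000 for calibration
checks), $K$ (200–300), and Monte-Carlo tolerances (3 standard errors) are
package choices balancing statistical resolution against a minutes-scale test
budget — not properties of the methodology. Known limitations: the model is
strictly linear (no saturable elimination), covariates are generated but not
modelled (no covariate effects on parameters), BLQ observations are flagged
but not censored-likelihood handled, and the generator's effective
clearance/bioavailability are a calibration device, not an estimate of any
population's parameters.
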