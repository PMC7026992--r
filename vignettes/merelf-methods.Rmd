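---
title: "Methods: model, estimation and simulation choices in merelf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, estimation and simulation choices in merelf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(merelf)
```

`merelf` implements the population PK/PD analysis chain for meropenem
given by continuous or extended infusion in nosocomial pneumonia, with the
epithelial lining fluid (ELF) of the lung as the effect site. This
vignette explains the model, the assumptions behind every major numerical
and design choice, and what the packaged tests do — and do not — establish
about real data.

## Structural model

Amounts in three compartments (central `A1`, peripheral `A2`, ELF `A3`)
follow a linear mammillary system with zero-order infusion input into the
central compartment and first-order elimination from it:

$$\begin{aligned}
\dot A_1 &= R(t) - (CL/V + K_{12} + K_{13})A_1 + K_{21}A_2 + K_{31}A_3\\
\dot A_2 &= K_{12}A_1 - K_{21}A_2\\
\dot A_3 &= K_{13}A_1 - K_{31}A_3
\end{aligned}$$

with `c_plasma = A1/V` (total drug) and `c_elf = A3/V_ELF`. Parameters and
units: clearance `CL` (L/h), central volume `V` (L), rate constants (1/h),
ELF volume `V_ELF` (L). The packaged population reference
(`reference_parameters()`) gives medians of CL 11.219 L/h, V 10.143 L and
V_ELF 19.424 L with substantial dispersion, reflecting a critically ill
population with conserved renal function.

Two structural choices deserve emphasis:

* **ELF is compartment 3.** The published parameterization lists
  `K12/K21/K13/K31` and a single ELF volume without stating which
  peripheral compartment is the lung; assigning ELF to the compartment
  that carries `V_ELF` is the only assignment under which the single
  extra volume is meaningful. Compartment 2 is then a non-observed
  distribution space.
* **ELF exchanges only with the central compartment** (mammillary
  topology). Nothing in a mammillary fit of plasma + one ELF sample can
  distinguish peripheral-to-ELF pathways; the assumption is flagged here
  rather than buried.

Under constant-rate infusion `R0` the steady states are
`Css_plasma = R0/CL` and `Css_elf = Css_plasma (V K13)/(K31 V_ELF)`;
the latter ratio (~37.8% at the reference medians) is also the
steady-state ELF/plasma AUC penetration ratio, and the package asserts
this identity against its own simulator in the test suite. The observed
patient-level penetration medians (~30-36%) sit slightly below the
median-parameter identity, as expected for ratios of skewed quantities.

## Solver

Because the input is piecewise constant, the system is solved exactly per
rate segment using the eigendecomposition of the (constant) rate matrix:
within a segment with rate `r`,
`A(t0 + tau) = A_p + P e^{Lambda tau} P^{-1}(A(t0) - A_p)` with
`A_p = -r M^{-1} e_1`. The analytic path is refused — and an adaptive ODE
integrator (deSolve, rtol 1e-10, integrated segment by segment so
discontinuities are exact) takes over — when eigenvalues are nearly
degenerate (relative gap < 1e-7), the eigenvector matrix is
ill-conditioned, or an eigenvalue is near zero relative to the spectrum
(< 1e-8), where the particular-solution term cancels catastrophically
(negligible clearance is the practical case). The two paths agree to
relative 1e-6 on random parameter draws in the test suite; mass balance
at negligible clearance and superposition/linearity are asserted as
properties.

Default simulation grid: 0.1 h. This resolves the 15-min loading dose,
and halving or refining the step changes PTA summaries by well under the
Monte Carlo noise at n = 1000 (the window metrics interpolate linearly at
MIC crossings and window edges, so grid sensitivity is second order).

## BAL correction and limits of quantification

BAL recovers ELF diluted ten- to a hundred-fold. Urea equilibrates freely
between plasma and ELF, so
`MER_ELF = MER_BAL x Urea_serum / Urea_BAL`. `correct_elf()` is exact for
noise-free inputs (a property test round-trips it through the trial
generator) and degree-1 homogeneous in the numerator quantities.
Quantification limits: meropenem 0.5 mg/L (plasma) and 0.03 mg/L (BAL);
urea 3 mg/dL (serum) and 0.078 mg/dL (BAL). A value exactly at the LOQ
counts as quantifiable (inclusive boundary, the usual assay-validation
convention). Below-LOQ observations are excluded from the likelihood by
default — how (or whether) censored points entered the original fit is
not documented, and an LOQ/2 substitution is available but not silently
applied; corrected ELF values derived from any below-LOQ analyte carry an
explicit `censored` flag rather than being dropped at the correction
stage.

## Residual error model and likelihood

Each analyte has a linear assay-SD polynomial `sd(c) = c0 + c1 c`
evaluated at the model prediction; observations are weighted by the
inverse of this estimated assay variance, and process noise is a
multiplicative inflation `gamma >= 1` of the assay SD. The published
assay polynomials are unavailable; the defaults `LOQ/2 + 0.15 c` anchor
the proportional term to the assays' validated <= 15% precision and are
config-overridable. `gamma` starts at 1 and is profiled over `[1, 10]`
during fitting; the profile search is free because per-point
residual/SD caches make the likelihood an explicit function of `gamma`.

## Population estimation

`npag_fit()` estimates the population distribution as a discrete mixture
of support points — the nonparametric view: no distributional shape is
imposed. The implementation is a deliberately simplified adaptive-grid
scheme rather than a primal-dual interior-point NPAG:

1. Latin-hypercube candidates within the search box;
2. EM updates of the mixture weights for fixed points (each run is
   monotone in the total log-likelihood and the per-run traces are kept
   so the property is testable);
3. adaptive refinement: each subject's posterior-mode point is polished
   against that subject's own likelihood (Nelder-Mead on log-parameters
   with one restart; an extra data-informed start with the steady-state
   clearance guess `rate/mean(c_plasma)` is used when the posterior mode
   disagrees with it grossly);
4. pruning of points with weight < 1e-6 and interleaved gamma profiling,
   until the cycle-to-cycle gain drops below 1e-4.

Acceptance of this scheme is parameter *recovery* on trials generated at
the study's own design, not bit-compatibility with any particular NPAG
implementation.

**Search bounds.** Defaults are mean +/- 4 SD of the packaged reference,
floored at one tenth of each parameter's mean. The floor is a modelling
decision worth spelling out: for the most dispersed rate constants,
mean - 4 SD is negative, and an epsilon floor would admit
quasi-irreversible deep-compartment modes (equilibration half-times of
hundreds of hours). With all samples drawn near steady state on day 3 —
flat concentration-time data — such modes mimic genuine elimination
almost perfectly and demonstrably corrupt the recovered clearance
distribution. One tenth of the mean excludes those time scales while
clipping under 0.3% of plausible subjects for every parameter.

**Identifiability under the study design.** The sampling layout (five
plasma samples across one 8-h interval at steady state, one ELF sample)
identifies clearance well (plasma level ~ rate/CL) and the composite ELF
ratio `(V K13)/(K31 V_ELF)` through the single ELF point, but leaves `V`
and the individual rate constants weakly informed — at steady state the
plasma profile carries almost no volume information. The recovery tests
therefore assert the clearance median (within 15% of the reference on
31-subject synthetic trials, in at least 8 of 10 seeded replicates) and
treat volumes as reported, not asserted. This is a property of the
design, not of the estimator.

## Diagnostics

Bias is the mean prediction error, imprecision the bias-adjusted mean
squared prediction error; observed-vs-predicted regression uses ordinary
least squares. The VPC simulates the fitted model under the study
regimen and reports 5th/50th/95th percentile bands; with well-estimated
random effects about 90% of observations should fall inside the 5-95
band, which `vpc_coverage()` quantifies and the suite checks on
self-simulated data. NPDE uses the rank-based construction
(`(rank + 0.5)/(n_sim + 1)` mapped through the normal quantile) without
the decorrelation step of the reference method: with a single ELF point
per subject the within-subject correlation is weakly identifiable, and
the rank variant keeps the null distribution testable (the suite checks
mean ~ 0 and variance ~ 1 under self-simulation).

## Monte Carlo dosing simulation

`population_sampler()` draws virtual subjects either nonparametrically
(resampling fitted support points by weight) or parametrically:
independent log-normals per parameter truncated at mean +/- 4 SD on the
natural scale. Two details matter:

* **Truncation-aware moment matching.** Truncating a skewed log-normal
  shifts its moments (for the most dispersed rate constant the SD would
  come out ~16% low). The sampler therefore calibrates `(mu, sigma)` so
  the *truncated* distribution reproduces the published mean and SD,
  using closed-form truncated-lognormal moments; the match is verified
  to within 1% at n = 1e5 in the suite.
* **Stratified draws.** Parametric draws are Latin-hypercube stratified
  per parameter (independent permutations, inverse-CDF on the truncated
  law), which preserves the joint distribution while trimming Monte
  Carlo error; plain independent draws are a switch away.

Parameters are sampled independently — the joint correlation structure
is unpublished. This is a documented limitation: correlations between
clearance and volumes would mostly affect the spread of exposure ratios,
and the borderline-MIC PTA values are sensitive to it.

PD targets: 50% fT>MIC in ELF over 48-72 h (day 3), free fractions 0.98
in plasma and 1.0 in ELF, ties at the MIC counting as attainment (the
target is quoted both as fT>MIC and fT>=MIC in the field; equality is
measure-zero on continuous profiles, so the choice is cosmetic but
documented). PTA uses one set of draws per call, shared across the MIC
grid and — when a common seed is passed — across regimens, making the
curves monotone by construction and dose comparisons variance-reduced.
The MIC grid is the standard susceptibility dilution series 0.002-16
mg/L (14 points). The neurotoxicity summary takes the maximum over 8-h
interval-end troughs in 0-72 h and compares it to 64.2 mg/L, so a
subject "reaches" the threshold if any interval trough does; under
continuous infusion troughs equal the running concentration, so this is
conservative in the intended direction.

The packaged simulations use n = 1000 virtual subjects (the headline
quantities in `scripts/acceptance.R` as well). At that size the binomial
SE of a PTA near 0.9 is ~0.009, which matters when a dose sits exactly
at the 90% optimality threshold: the CI regimens' coverage boundaries
(loss of optimality at 2 mg/L for 3 g/day, 4 mg/L for 6 g/day) are
reproduced stably across seeds, but the attainment value at the critical
MIC itself hovers a percentage point or two above the threshold.

## Synthetic trials

`generate_trial()` emulates the study: 16 + 15 subjects, 2 g/15-min
loading dose followed by contiguous 1 g or 2 g 8-h infusions, plasma
samples at 48 (pre-infusion trough), 49.5, 51, 54 and 56 h, one
BAL-derived ELF sample at 54 h. BAL dilution is log-uniform on [10, 100]
(BAL conventionally dilutes ELF by one to two orders of magnitude; the
study reports no distribution), serum urea log-normal with median
40 mg/dL and CV 40% (typical ICU values; unpublished, overridable).
Meropenem analytes carry multiplicative log-normal noise with SD 0.15
(the assays' <= 15% precision bound); urea analytes default to noise-free
because an enzymatic urea assay is far more precise than HPLC and any
urea noise would otherwise dominate the corrected-ELF error budget —
the urea CV is a design field for sensitivity analyses. With noise off
the generator/correction round trip is exact.

What the passing tests show — and what they do not: recovery and
diagnostic properties are established under the generator's assumptions
(independent log-normal parameters, multiplicative noise, the exact
sampling schedule). Real data add model misspecification, occasion
effects, censoring mechanisms and correlated parameters; the synthetic
results bound what the estimator can do when the model is right, nothing
more.

## Known limitations

* Volumes and individual rate constants are weakly identified by the
  steady-state design (above); credibility intervals for them should not
  be over-read.
* No covariate modelling: the original analysis screened covariates and
  retained none; the package deliberately omits that machinery.
* Independent-parameter sampling in the simulator (no published
  correlation matrix); a rank-correlation copula could be added if one
  became available.
* Nonlinear elimination and renal-function dose adjustment are out of
  scope (the study population had conserved renal function).
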