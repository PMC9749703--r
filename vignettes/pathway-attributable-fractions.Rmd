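---
title: "Methods: pathway-specific attributable fractions in pspaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-specific attributable fractions in pspaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspaf)
```

## The estimands and their assumptions

`pspaf` works with a binary exposure $A$, binary outcome $Y$, baseline
covariates $C$ not affected by the exposure, and mediators $M^1,\dots,M^K$
assumed to lie on separate causal pathways (d-separated given $A$ and $C$).
The total attributable fraction compares observed prevalence with prevalence
under exposure elimination; the pathway-specific PAF (PS-PAF) for mediator
$k$ compares observed prevalence with prevalence after mediator $k$'s
distribution is shifted to the conditional distribution it would have under
exposure elimination, the exposure itself remaining as observed:

$$\mathrm{PSPAF}_k \;=\;
  \frac{P(Y=1)-\mathbb{E}_{A,C}\,\mathbb{E}_{M^k\mid A=0,C}\,
        P(Y=1\mid A,C,M^k)}{P(Y=1)}.$$

Identification of that display requires (i) no unmeasured
exposure–mediator confounding given $C$, and (ii) no unmeasured
mediator–outcome confounding given $A$ and $C$. The direct PAF additionally
needs (iii) no unmeasured exposure–outcome confounding given $C$ and the
mediators. Under the further cross-world condition that holds in structural
equation models with independent errors and no post-treatment confounding,
the same formula also identifies the *mechanistic* reading (disable the
$A \to M^k \to Y$ pathway at the individual level) and the *separable*
reading (set the mediator-directed component of the exposure to zero). The
package treats the identification formula as the estimand and leaves the
reading to the analyst; the simulator's oracle verifies the three readings
coincide on d-separated models (`verify_identification_equivalence()`).

Indirect PAFs are defined by subtraction, `total − direct_single`, and are
computed exactly that way — the additivity `indirect + direct_single =
total` is a floating-point identity in every fit, not an approximation.

## Estimation

All estimators are weighted plug-ins
$\widehat{\mathrm{PAF}} = (\sum_i w_iY_i - \sum_i w_i\hat q_i)/\sum_i w_iY_i$
with $\hat q_i$ the fitted outcome probability under the relevant
counterfactual substitution:

* **PS-PAF, continuous mediator**: replace $M^k_i$ by
  $\hat M^k_i = M^k_i - A_i(\hat E[M^k\mid 1,C_i] - \hat E[M^k\mid 0,C_i])$,
  keep $A_i$ and other mediators observed.
* **PS-PAF, discrete mediator**: average the outcome model over the fitted
  level probabilities $\hat P(M^k = m \mid A=0, C_i)$.
* **Direct (all mediators / single mediator)**: evaluate at $A=0$ with
  mediators at observed values, using the joint or the single-mediator
  outcome model respectively.
* **Total**: evaluate at $A=0$ with every continuous mediator shifted and
  every discrete mediator integrated over its $A=0$ law (g-formula under
  d-separation). A reduced-model route (`Y ~ A + C` standardised at $A=0$)
  is available via `total_method = "reduced"` for comparison; the mediated
  route is the default so total, direct and indirect are internally
  coherent.
* **Impact fractions**: same plug-in with a user-supplied post-intervention
  mediator distribution replacing the $A=0$ law; supplying the fitted $A=0$
  law recovers the PS-PAF, supplying the observed values gives zero.

With several mediators, a single joint outcome model
$P(Y=1\mid A,C,M^1,\dots,M^K)$ is used for all PS-PAFs, holding the other
mediators at observed values; this shortcut is valid exactly under the
d-separation assumption, and the package refuses joint estimation when any
mediator is declared (or detected, in simulated data) to sit on a shared
pathway — estimation under post-treatment confounding among mediators is an
explicit non-goal, as is double-robust estimation of the direct PAF.

### Design weights

Cohort and cross-sectional records carry weight 1. For a 1:r case-control
design with known prevalence $\pi$, cases get weight 1 and controls
$(1/\pi-1)/r$, so weighted sample averages estimate population quantities;
with exactly $r$ controls per case the weighted case fraction equals $\pi$
identically. The prevalence and ratio are taken from the design declaration
as supplied by the analyst (the realized control:case ratio of the analysed
sample is the natural choice for `matching_ratio` when the design ratio was
not met, and is what the simulator's case-control sampler records). By
default the weights are used both in model fitting and in the estimator
averages (`weight_fitting = FALSE` restricts them to the averages).
Model-fitting weights are internally rescaled to mean 1 — the weighted
maximum-likelihood solution is invariant to that rescaling, and raw control
weights in the hundreds destabilise the IRLS iterations on realistic
samples. No standard errors are ever taken from these weighted fits; the
bootstrap is the sole inference route.

### Nuisance models and numerical choices

The outcome model is a weighted logistic regression (identity and log links
are accepted but experimental: out-of-range predictions are clipped into
$[10^{-12}, 1-10^{-12}]$ with a warning). Continuous terms may enter as
natural cubic splines; `spline_df = c(whr = 5)` gives the 5-degree-of-freedom
basis commonly used for anthropometric mediators, with internal knots at
weighted quantiles of the fitting data and boundary knots at the observed
range, so the basis is a deterministic function of the data. Mediator models
are weighted least squares (continuous), weighted logistic (binary) or
weighted multinomial via `nnet::multinom` (3+ levels). Converged fits
satisfy the intercept score identity $\sum_i w_i(Y_i-\hat p_i)=0$ to
$10^{-6}$, which is what forces a PS-PAF of exactly zero whenever the fitted
mediator model shows no exposure effect. Rank deficiency is reported with
the offending terms; coefficients beyond $\pm 30$ on the logit scale are
treated as separation. Categorical covariates are coded with the first
sorted level as reference, making results reproducible across record
orders.

For binary mediators the level-sum estimator is the default (exact under
the model). The mean-shift route is kept as a diagnostic; it evaluates the
outcome model *linearly* between the two levels, treating the fractional
shifted value as a mixture weight rather than a covariate value — plugging
it into the logistic curve instead would interpolate on the logit scale and
bias the diagnostic. With saturated models and no covariates the two routes
agree exactly.

Degenerate inputs fail loudly: no cases, single-arm exposure, empty
declared mediator levels, and mediator values outside declared levels are
errors, not silent drops; incomplete records are removed with a reported
count (complete-case analysis only).

### Bootstrap

`paf_boot()` resamples records — stratified by case status for case-control
designs, preserving the case and control counts exactly — recomputes design
weights from the declared design, refits every model and reruns the
pipeline, for `n_boot` (default 200) replicates. The SE is the sample
standard deviation of replicate estimates and the default 95% interval is
`estimate ± 1.96·SE`; percentile intervals are available. Per-replicate
seeds are drawn once from the master seed (`sample.int` stream, replicate
*b* uses the *b*-th seed), so results are bit-reproducible. Replicates
whose models fail are dropped and counted, with a warning above 10%
failures and an error when all fail. Intervals may be asymmetric around a
re-estimated point only by construction; only `ci_low ≤ ci_high` is
guaranteed.

## The simulator and what the tests do (and do not) show

`structural_model()` encodes structural equations with independent errors:
each node is a deterministic function of its parents and one uniform noise
term (inverse-cdf construction for discrete nodes). Counterfactual worlds
share the noise, so `enumerate_oracle()` computes $P(Y_0=1)$,
$P(Y_{0,M}=1)$, $P(Y_{A,M_0^k}=1)$ and the separable analogue exactly for
finite-support models, by summing over a partition of the joint noise space
(within each partition cell every node's value is constant for every parent
configuration). The interventional functional is deliberately computed by a
*different* route — its identification formula applied to the observational
joint distribution — so the oracle-level agreement between the two is a
genuine cross-check, asserted to $10^{-12}$ on d-separated models and
reported without assertion on sequential ones. Models with continuous nodes
use `mc_oracle()` (shared-noise Monte Carlo, default $10^6$ draws, with
delta-method MC standard errors).

The canonical fixture `sem_toy1()` ($A\sim\mathrm{Bern}(0.5)$,
$M\mid A\sim\mathrm{Bern}(0.2+0.6A)$,
$Y\mid A,M\sim\mathrm{Bern}(0.1+0.3A+0.4M)$) enumerates to observed risk
0.45, total PAF 0.6, direct PAF 1/3 and PS-PAF = indirect PAF = 4/15; the
equality of PS-PAF and indirect here is forced by the additive-risk outcome
assignment and does not hold generally. `random_discrete_sem()` draws
additive-risk Bernoulli models (probabilities kept inside (0.02, 0.98) so
positivity holds by construction) for property checks: the
interventional/mechanistic equivalence, and on monotone-deleterious draws
the orderings PS-PAF ≥ indirect PAF and total ≥ PS-PAF. On such monotone
models the PS-PAFs plus the direct PAF typically *exceed* the total PAF —
pathway burdens overlap and are not an additive decomposition.

`interstroke_model()` emulates the structure of a large international
stroke case-control study: eight baseline covariates, a binary
physical-inactivity exposure, a binary hypertension mediator, Gaussian
waist-hip-ratio and ApoB/ApoA mediators, and a rare outcome whose intercept
is calibrated (deterministically, against a fixed quasi-sample of the
linear predictor) so the marginal incidence is 0.0035 — which makes the 1:1
control weight $(1/0.0035-1)/1 \approx 284.7$. Arrow set and coefficients
are plausible fabrications chosen once; the generator emulates the *shape*
of such data (rare outcome, mixed mediator types, case-control sampling),
not any real study's joint distribution. Passing tests therefore
demonstrate correctness of the estimators under correctly specified models
on data of realistic structure; they say nothing about robustness to model
misspecification, measurement error or selection beyond the case-control
scheme, all of which real applications face.

Test and acceptance problem sizes were chosen as the smallest at which the
sampling yardsticks are sharp: oracle-recovery checks use cohorts of
$n = 200{,}000$ with saturated models (agreement within 3 bootstrap SEs),
case-control fidelity uses 2000 cases with 200 bootstrap replicates, and
bootstrap coverage uses 100 outer replications of $n = 5000$ cohorts with
$B = 200$, requiring at least 90 of 100 intervals to cover the oracle
PS-PAF.

## Known limitations

* Mediators on a shared causal pathway (post-treatment confounding) are
  detected and refused, not handled.
* Longitudinal mediator trajectories and time-varying confounding are out
  of scope; a point-in-time mediator is a proxy at best.
* Analytic (influence-function) standard errors are not provided; the
  bootstrap is the only inference route, and with very rare outcomes small
  case counts make both the point estimates and their bootstrap SEs noisy.
* The case-control weighting assumes cases and controls are random samples
  of their source populations and that $\pi$ is known; matched-pair
  conditional designs are not supported.
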