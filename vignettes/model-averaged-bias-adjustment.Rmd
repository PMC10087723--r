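---
title: "Model-averaged adjustment for publication bias: models, priors, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-averaged adjustment for publication bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmapb)
```

## The problem and the modelling stance

A meta-analysis pools K study estimates $y_k$ with standard errors
$se_k$.  When publication depends on the studies' results, the published
record is a biased sample and the pooled estimate inherits that bias.
Two families of corrections encode rival views of the selection process:

* **Selection models** assume publication probability is a step function
  $\omega(p)$ of the study's p-value.  The published estimate then has the
  weighted density
  $$f(y_k \mid \mu, \tau, \omega) =
    \frac{\omega_{j(k)}\, N(y_k;\, \mu,\, se_k^2 + \tau^2)}
         {\sum_j \omega_j\, P_j(\mu, \tau, se_k)},$$
  where $j(k)$ is the p-value interval of the observed estimate and
  $P_j$ the probability of landing in interval $j$ under the model — the
  classic weighted-likelihood construction of the selection-model
  literature.  We use the marginal (study-level) form: interval
  probabilities are computed from $y_k \sim N(\mu, se_k^2+\tau^2)$ with
  the p-value referred to the observed $se_k$.  Ties at a cutoff go to
  the more significant interval.
* **Small-study-effect regressions** assume bias expresses itself as a
  relationship between estimates and their precision: PET regresses
  $y_k$ on $se_k$, PEESE on $se_k^2$, and in both the intercept $\mu$ is
  the bias-corrected effect at infinite precision.

Neither family is correct in general.  The package therefore builds an
ensemble crossing effect (spike at 0 / slab), heterogeneity
($\tau = 0$ / slab) and bias component (none, six weight functions, PET,
PEESE), computes each model's marginal likelihood, and reports
inclusion Bayes factors (posterior-to-prior odds updates for model
subsets) plus model-averaged spike-and-slab posteriors.

## Default priors and their scale

Defaults, declared on the Cohen's d scale:

| parameter | prior | role |
|---|---|---|
| $\mu$ | Normal(0, 1) | mean effect slab; unit information on d |
| $\tau$ | InvGamma(1, 0.15) | heterogeneity SD; mode at 0.075, heavy right tail |
| $\omega$ | CumDirichlet(1, …, 1) | flat over monotone step weight functions, $\omega_1 = 1$ |
| PET $b$ | Cauchy(0, 1) on $[0,\infty)$ | slope on $se$; unit-scale ratio |
| PEESE $b$ | Cauchy(0, 5) on $[0,\infty)$ | slope on $se^2$; larger because $se^2$ is small |

The six default weight functions are two-sided with cutoffs {.05} and
{.05, .10}, and one-sided (expected direction) with {.05}, {.025, .05},
{.05, .50} and {.025, .05, .50}.  One-sided variants distinguish
significant, marginal, and wrong-direction results; 0.025 is the
one-sided significance of a two-sided test, 0.50 the boundary of the
expected direction.

Prior model mass is 0.5 on the bias-free class and 0.25 each on the
selection and PET/PEESE classes, uniform within a class: 0.125 per
bias-free model, $0.25/24 \approx 0.010$ per selection model, $0.03125$
per PET/PEESE model.  If only one bias class is requested it receives
the full 0.5 (matching how selection-only and regression-only ensembles
are reported in the literature this package follows).

### The d-to-z transformation

Cohen's d input is fitted on the Fisher z scale, where the normal
sampling model is a better approximation.  Point estimates map exactly
through $z = \operatorname{asinh}(d/2)$; variances through the implied
sample size $N = (d^2+8)/(2\,se_d^2)$ (equal-group back-calculation) and
$se_z = 1/\sqrt{N-3}$.  A user-supplied per-study $n$ overrides the
implied N — but note this is only coherent for two-group designs; for
one-sample studies the implied-N route preserves each study's
z-statistic and is the right default (this is why the bundled example
table carries d and se only).

Priors declared on d are mapped to the z scale as follows: the normal
$\mu$ prior by exact change of variables through $d = 2\sinh(z)$; the
$\tau$ scale by the Jacobian at zero, $dz/dd|_0 = 1/2$; the PET slope
unchanged (a ratio of like-scaled quantities); the PEESE slope scale
doubled.  The exact recipe used by other implementations is not public
in detail; this package's choice is documented here and validated by
reproducing published results (below).  Estimates are transformed back
to d for reporting ($\mu$ exactly, $\tau$ by the factor-2
linearisation).

## Computation

Each model has at most five free parameters.  Sampling works on an
unconstrained scale ($\log \tau$, stick-breaking logits of the Dirichlet
coordinates, $\log b$) with a jointly adapted random-walk Metropolis
kernel: the proposal covariance starts from a Laplace approximation at
the posterior mode, is adapted (Haario covariance + Robbins–Monro global
scale, target acceptance 0.3) during burn-in only, and is frozen for the
kept draws, so the kept chain is a valid fixed-kernel Metropolis
sampler.  A spec that works through per-component scans would also be
correct; the joint kernel was chosen because these posteriors are
low-dimensional but correlated ($\mu$ with $\tau$, $\mu$ with $b$), and
a full-covariance proposal mixes better at equal cost.  Convergence is
monitored by split R-hat (threshold 1.05) and effective sample size;
non-converging models are refitted with doubled iterations and, if still
failing, excluded with prior mass renormalised and a loud warning.

Marginal likelihoods use iterative optimal-bridge sampling with a
moment-matched multivariate normal proposal on the unconstrained scale
(relative tolerance $10^{-10}$, cap 1000 iterations), with a standard
error from the bridge variance formula, autocorrelation-corrected on the
posterior side.  Parameter-free models return the exact log-likelihood.

Two independent code paths guard the arithmetic: the sampler and bridge
evaluate the model densities in compiled C++, while the **quadrature
oracle** — tensor-grid trapezoid quadrature in Laplace-standardised
unconstrained coordinates, adaptively widened (ranges 10 to 24 standard
deviations) until the estimate moves by less than $2 \times 10^{-4}$ —
integrates a separate vectorised R implementation.  Their agreement
(asserted to 0.02 log units for every model with up to three free
parameters, and to the exact closed form for conjugate cases) therefore
cross-validates both the integrator and the likelihood code.  Wide
ranges matter: on the log scale, half-Cauchy and inverse-gamma tails
decay only exponentially, and an 8-standard-deviation grid visibly
truncates them.

Determinism: one master seed; per-model seeds derived from (master,
model id), so any model's fit is reproducible in isolation.

## What the generator emulates — and what it does not

`simulate_meta_analysis()` draws per-study true effects
$\theta_k \sim N(\mu, \tau^2)$ on the d scale, total sample sizes
uniformly from a range, $se_k$ from the equal-group formula
$se^2 = (8+\theta_k^2)/(2n)$, optionally shifts the observed estimate by
a PET-type slope, and accept/rejects each candidate study with the
publication probability of its observed p-value interval.  This is
exactly the process the selection models assume — so green recovery
tests establish internal consistency, not robustness.  Real literatures
deviate in ways the generator does not emulate: publication probability
varying within intervals or depending on effect sizes, p-hacking that
skews estimates without suppressing them (known from the method's own
evaluation literature to cause overcorrection), correlated estimates
from shared samples, and non-normal small-sample sampling
distributions.

Generator defaults (K = 20, n between 30 and 150, no selection) mirror a
typical psychology meta-analysis.  The recovery suite instantiates the
stated "large n" condition as n between 500 and 2000 — per-study power
near 1 at d = 0.3 — because with n around 100–250 a d = 0.3 effect has
study-level power well under 0.5 and any bias-adjusting ensemble
legitimately shrinks the pooled estimate; that shrinkage is a property
of the problem, not an estimation failure.

## Numerical and design choices worth knowing

* **Intervals are central quantile intervals** of the spike-and-slab
  mixture, including the spike — an endpoint can be exactly 0.  Highest
  density intervals were rejected because the mixture of a point mass
  and continuous densities makes HDIs discontinuous in the spike weight.
* **Zero weights**: $\omega_j = 0$ with an observed study in interval
  $j$ gives likelihood zero (log-likelihood $-\infty$), a legal state the
  sampler simply rejects, not an error.
* **The PET decision test** in the frequentist baseline is two-sided at
  $\alpha = 0.10$ (this reproduces the published switch on the bundled
  example); a one-tailed variant is available via `one_sided = TRUE`.
* **Collinear PET designs** (all $se$ equal) are flagged with a warning;
  the intercept degrades gracefully to the weighted mean.
* **Degenerate inputs**: $se \le 0$, implied $N \le 3$, empty tables and
  malformed CSVs raise typed, row-numbered errors at the boundary.
* **Config files** for `run_analysis()` are JSON (the environment's
  standard serialisation; YAML would add a dependency for no expressive
  gain).

## Validation against published results

The reconstruction of the nine-experiment precognition table (see
`inst/extdata/README.md`; d and published N, se back-computed) yields,
with the default ensemble: selection-only $BF_{10} = 1.85$ and
$\mu = 0.095$; PET/PEESE-only $BF_{10} = 0.228$; full 36-model ensemble
$BF_{10} = 0.48$, $BF_{rf} = 0.145$, $\mu = 0.038$ with 95% CI
$[-0.03, 0.22]$; frequentist PET $\mu = -0.182$, $t(7) = -3.65$ and
PEESE $\mu = 0.024$, $t(7) = 0.86$.  These match the published analyses
of the same nine studies to within MCMC noise and the documented
transformation approximations; the test suite asserts them at ±15%
(Bayes factors) and ±0.02 (posterior means).

## Known limitations

* Selection acts on the study's own p-value only; no model of
  effect-size-dependent selection, time trends, or within-study multiple
  estimates (clustered/multilevel likelihoods are out of scope).
* The d↔z machinery assumes two-group standardised mean differences;
  odds ratios, correlations (other than through d) and Cohen's q are not
  converted.
* Under strong p-hacking the ensemble is expected to overcorrect — a
  property documented for this class of methods, and outside what the
  bundled generator simulates.
* Bridge sampling error grows for weakly identified selection models
  (flat $\omega$ posteriors); the per-model standard error is reported
  in `ensemble_table()` and should be checked before interpreting
  per-model Bayes factors below about 0.05 log units of separation.
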