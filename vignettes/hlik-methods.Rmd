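---
title: "Direct hierarchical-likelihood estimation for GLMMs: models, algorithms and design choices"
author: "hlik package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct hierarchical-likelihood estimation for GLMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlik)
```

## The model

`hlik` fits generalized linear mixed models for repeated-measures data of
the kind produced by electronic health records: encounters nested within
patients, patients mostly nested within healthcare facilities but with a
fraction crossing between facilities.  With outcomes $y_{ij}$ (encounter
$j$ of patient $i$), fixed-effect design $X$, and sparse random-intercept
design $Z$ partitioned into one indicator block per grouping factor,

$$ g(\mu) = X\beta + Zu + \text{offset}, \qquad
   u \sim \mathcal N(0,\, G(\gamma)), $$

where $G(\gamma)$ is block diagonal with $\sigma_k^2 I$ within grouping
factor $k$ and $g$ is the canonical link (log for Poisson counts, logit
for binary outcomes, identity for Gaussian).  The dispersion $\phi$ is
fixed at 1 for Poisson and Bernoulli responses and is the residual
variance for Gaussian ones.  Death during a sequence of clinical
encounters is encoded as a Poisson outcome through the standard
piecewise-exponential device: a string of zeros possibly terminated by a
one, with the log encounter duration as offset, so the Poisson rate is a
death hazard per unit exposure time.

## Hierarchical likelihood and adjusted profiles

All inference is built on the hierarchical (joint) log-likelihood

$$ h(\beta, u, \gamma, \phi) = \log f(Y \mid \beta, u, \phi)
   + \log f(u \mid \gamma), $$

and on adjusted profile log-likelihoods of the form

$$ p_w(h) = \left[ h - \tfrac12 \log\left| -H(h, w)/2\pi \right|
   \right]_{w = \hat w}, $$

where $w$ is the set of arguments eliminated by profiling ($u$, or
$(\beta, u)$ jointly), $\hat w$ solves $\partial h/\partial w = 0$ at
fixed remaining parameters, and $H$ is the Hessian of $h$ in $w$.
$p_w(h)$ is exactly the Laplace approximation to the log of
$\int \exp(h)\,dw$: eliminating $u$ approximates the marginal likelihood
of $(\beta, \gamma, \phi)$; eliminating $(\beta, u)$ approximates the
restricted (REML) likelihood of $(\gamma, \phi)$, i.e. the marginal
likelihood additionally integrated over $\beta$ with a flat prior.  For
Gaussian responses both approximations are exact.

Three estimators expose the standard trade-offs:

* **`fit_hl11()` — HL(1,1), the default.**  Stage 1 maximizes
  $p_{\beta,u}(h)$ over $\log\sigma_k$ (and $\log\phi$), giving REML-type
  variance components with standard errors from the numerical Hessian of
  the stage-1 objective.  Stage 2 fixes $(\hat\gamma, \hat\phi)$ and
  maximizes $p_u(h)$ over $\beta$.  Random effects are read from the
  stage-2 inner mode; the third conditional optimization of $h$ over $u$
  alone is available as `refit_random_effects()` but is not run by
  default, because the stage-2 mode is typically indistinguishable from
  it (the Gaussian case is exactly equal; tests quantify the Poisson
  case).
* **`fit_hl01()` — the joint shortcut.**  Only stage 1 is run; $\beta$
  and $u$ are read off the final joint inner mode.  This halves the cost
  and gives identical variance components (same code path, same optimizer
  trace), but the fixed effects inherit the known joint-mode bias for
  sparse binary data with few observations per cluster — approximately
  $+\sigma^2/2$ on the intercept of a log-link model.  The package's
  simulation harness makes this visible (see below).
* **`fit_ml_laplace()` — ML.**  Maximizes $p_u(h)$ jointly over
  $(\beta, \log\gamma[, \log\phi])$; equivalent to adaptive Gauss–Hermite
  quadrature with a single node, and the referent for the classical
  ML-vs-REML comparison.

## Numerical design

**Inner problem.**  For canonical links, $-H(h, w) = A^\top W A +
\mathrm{diag}(\text{prec})$ with $A = [X \mid Z]$ restricted to the
elimination set, $W$ the family variance weights, and prec the prior
precisions ($0$ for $\beta$ coordinates, $1/\sigma_k^2$ for $u$).  The
sparsity pattern is derived from the grouping structure — exact for
random-intercept models, no numerical detection needed — and the prior
precisions are folded into a single sparse cross-product via augmented
identity rows, so each Newton iteration is one `crossprod` and one
CHOLMOD factorization with a fill-reducing permutation whose symbolic
analysis is computed once and reused (`Matrix::update`).  The inner
solver is Newton with step-halving (at most 30 halvings, at most 100
iterations, gradient sup-norm tolerance $10^{-8}$); accepted steps never
decrease $h$ beyond floating-point resolution.  Derivatives are analytic
per family; their correctness is enforced by finite-difference oracle
tests rather than algorithmic differentiation, which keeps the same
accuracy contract as an AD implementation without the machinery.

**Outer problem.**  Variance parameters are optimized unconstrained on
the log scale by BFGS with warm-started central finite-difference
gradients (step $10^{-4}$); if any $\log\sigma$ drifts below
$\log(10^{-4})$ the fit switches to bound-constrained L-BFGS-B with
$\sigma \ge 10^{-4}$ and flags the boundary.  Because BFGS's
objective-change stopping rule can leave a residual gradient, outer
optima are polished with up to two finite-difference Newton steps in the
default (standard-error-producing) mode; this is what makes the Gaussian
fits agree with the closed-form REML/ML oracles to $10^{-6}$ relative.
Benchmark loops (`se = FALSE`) skip both the polish and the SE Hessians,
since replicate summary statistics are insensitive to the last
$10^{-4}$ of the outer parameters.  Standard errors come from
central-difference numerical Hessians of the relevant adjusted profile at
the optimum (step $10^{-3}$), with the delta-method transform
$\mathrm{se}(\hat\sigma) = \hat\sigma\,\mathrm{se}(\log\hat\sigma)$ back
to the SD scale.  The $|{-H}|/2\pi$ term is computed as
$\log|-H| - \dim \cdot \log 2\pi$ to avoid scaling the matrix.

**Warm starts.**  The previous inner mode and Cholesky factor are carried
between outer evaluations, so a finite-difference gradient costs a
handful of one-to-two-iteration inner solves rather than cold Newton
runs.

## Verification oracles

The `quadrature_oracle` layer provides independent routes to the same
quantities, deliberately sharing no code with the estimators:

* `agh_loglik()` — adaptive Gauss–Hermite quadrature for single-factor
  models, fully adaptive (per-group centers and scales recomputed at
  every parameter value).  Order 1 reproduces the Laplace approximation
  identically; order 25 is treated as ground truth in tests.
  `fit_agh()` maximizes it, giving an ML oracle.
* `lmm_closed_form()` — dense exact Gaussian marginal (GLS-profiled),
  with the flat-prior $\beta$ integration for REML; capped at $N = 2000$
  since it is a test oracle.
* `bruteforce_marginal_loglik()` — tensor-product Gauss–Hermite over all
  random effects jointly for $q \le 4$ crossed toys, centered and scaled
  by the joint mode and its Cholesky factor.

Gauss–Hermite nodes use the physicists' $e^{-x^2}$ convention (cached per
order), with the $\sqrt2$ rescaling absorbed into the adaptive transform.

## The synthetic-data generator

`simulate_grouping()` draws visits per patient as $2 + \text{Poisson}(3)$
(median 5, matching the structural summaries the generator emulates) and
makes exactly $\lceil \text{fraction} \times n_{\text{IP}} \rceil$
patients "crossed" (assigned 2–4 facilities, with the first two visits
guaranteed to hit two distinct ones), so the crossing share is structural
rather than stochastic.  `simulate_poisson_scenario()` adds a
patient-level binary covariate ("gender", effect 0.3), a patient-level
count covariate ("comorbidity score", effect 0.15), and one smooth
encounter-level covariate on a potassium-like scale $[2.5, 6.5]$.  The
smooth effect is expressed in a *fixed* natural-spline basis (interior
knots at thirds of the range) so that every generated coefficient has a
declared true value and per-coefficient bias is well defined; the fitted
model uses the same fixed knots.  The intercept $-3.5$ keeps the realized
event rate near 0.06 per observation (below the 0.10 design bound);
random-intercept SDs default to 0.3 (patient) and 0.4 (facility).
`simulate_binomial_scenario()` is intercept-only with a "less variable"
($\sigma_{IP} = 0.3$, intercept $-5$) and a "more variable"
($\sigma_{IP} = 2$, intercept $-6.5$) variant, keeping event rates below
0.015 per observation.  `simulate_crwd_like()` generates a full clinical
table (potassium, kidney function, age, comorbidities, race, gender,
inpatient flag, durations) with death drawn from the Poisson-survival
model under a configurable U-shaped log-relative-risk curve in potassium
(minimum risk at 4.0 meq/l by default); death terminates a patient's
encounter sequence, mirroring the encoding contract.

What the generator does *not* emulate: real marginal distributions of
labs and demographics, informative visit processes, measurement error, or
missingness.  Passing recovery tests therefore demonstrates correctness
of the estimation machinery under the declared data-generating process,
not robustness to real-EHR pathologies.

## Evaluation harness

`standardized_bias()` is $100\,|\bar{\hat\theta} - \theta| /
\mathrm{sd}(\hat\theta)$ over replicates — the normalization by the
empirical replicate SD is a documented choice (normalizing by the true
value or the SE are defensible alternatives and can change conclusions
materially; see the limitations below).  `mse()` is the plain mean
squared error.  `compare_methods()` tabulates both per parameter per
method and summarizes between-method agreement as the maximum pairwise
difference in standardized bias; `ranef_agreement()` gives the
Bland–Altman-style numerical summary (correlation, mean difference,
limits of agreement) for random-effect predictions.  `rr_curve()` turns a
fitted spline block into a relative-risk curve
$\exp\{[B(v) - B(v_{\text{ref}})]\hat\beta\}$ with delta-method 95%
pointwise bands; the reference (default 4.0) has RR exactly 1 with a
zero-width band.

## Problem sizes used by the test suite

The acceptance-level tests run, on one CPU: Gaussian exactness at
$N \le 500$; quadrature equivalence on 50 groups × 5 observations;
crossed-structure oracles at $q = 4$ with a 40-node-per-dimension tensor
grid; the nested Poisson study at 1000 patients / 50 facilities with 200
replicates (HL(1,1)) of which the first 50 are also fitted with HL(0,1)
and ML; and the sparse-binomial comparison with 200 replicates at 100
patients and 100 replicates at 1000 patients.  These sizes were chosen as
the smallest at which the phenomena of interest (REML/ML splits,
joint-mode bias, method agreement) are clearly resolved.

## Known limitations

* At the default Poisson study conditions (≈0.3 expected events per
  patient), *any* Laplace-based fit — ours, or the equivalent
  single-node-quadrature fits in other mixed-model software — estimates
  the patient-level SD with substantial bias; high-order adaptive
  quadrature recovers it.  The package's quadrature oracles make this
  measurable rather than hiding it: treat LA variance components with
  caution when events per cluster are far below 1.
* The joint-mode (HL(0,1)) fixed effects carry an intercept bias of
  roughly $+\sigma^2_{\text{total}}/2$ for log-link models; whether this
  is "minimal" depends entirely on the standardized-bias normalization
  (it is large relative to the replicate SD, small relative to the
  intercept itself).
* Only random intercepts are supported (no random slopes, no
  interactions, no general formula language), matching the intended
  model class.
* The AGH oracle requires a single grouping factor; the tensor-grid
  oracle is limited to $q \le 4$.  Neither scales — that is by design.

## A minimal session

```{r example, eval = FALSE}
scenario <- poisson_scenario(n_ip = 200, n_hcf = 10)
sim <- simulate_poisson_scenario(scenario, replicate = 1)
d <- build_design(sim$table, sim$config)
fit <- fit_hl11(d)
print(fit)
rr_curve(fit, "k", grid = seq(2.6, 6.4, 0.1), reference = 4.0)
```
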