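---
title: "Bayesian one-parameter IRT with generalized logistic links"
author: "glogitIRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian one-parameter IRT with generalized logistic links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glogitIRT)
```

## The model

One-parameter item response models describe the probability that person
$i$ (ability $\theta_i$) answers item $j$ (difficulty $\beta_j$)
correctly as a monotone function of $\eta = \theta_i - \beta_j$.  The
classical choices — logit (Rasch), probit (normal ogive), complementary
log-log — force every item characteristic curve (ICC) in a test to be
either symmetric or asymmetric in the same way.  This package implements
a family that removes that restriction: the generalized logistic
(Stukel) link, indexed by two per-item shape parameters
$\lambda_j = (\lambda_{1j}, \lambda_{2j})$,

$$P(x_{ij} = 1) = \frac{\exp\{h_{\lambda_j}(\theta_i - \beta_j)\}}
                       {1 + \exp\{h_{\lambda_j}(\theta_i - \beta_j)\}},$$

where $h_\lambda$ is a strictly increasing piecewise transform: for
$\eta > 0$ it is $(e^{\lambda_1\eta} - 1)/\lambda_1$,
$\eta$, or $-\log(1 - \lambda_1\eta)/\lambda_1$ as $\lambda_1$ is
positive, zero, or negative, and for $\eta \le 0$ the mirrored form in
$\lambda_2$ and $|\eta|$.  $\lambda_1$ controls how fast the curve
approaches its upper asymptote, $\lambda_2$ the lower one; larger values
mean faster approach.  At $(0, 0)$ the model is exactly the Rasch model;
at roughly $(0.165, 0.165)$ the link behaves like a probit, and at
roughly $(0.62, -0.037)$ like a complementary log-log
(`fixed_shape_constants()`).  Every curve passes through $1/2$ at
$\theta = \beta$, and when $\lambda_1 = \lambda_2$ the curve is exactly
symmetric about that point.

Two caveats shape the package interface:

* The probit/cloglog reductions hold only up to an affine rescaling of
  $\eta$ (e.g. the fixed-shape variant gives $0.748$ at $\eta = 1$ where
  the exact probit gives $\Phi(1) = 0.841$, and any generalized-logit
  curve passes through $0.5$ at $\eta = 0$ where the exact cloglog gives
  $1 - e^{-1} = 0.632$).  In the simulation studies "1PNO" and "CLLM"
  mean the *fixed-shape generalized-logit variants* (`pno_glogit`,
  `cllm_glogit`); the exact links are available separately as
  `pno_exact` and `cllm_exact`, and no pointwise equality between the
  two forms is asserted anywhere.
* Shapes at or below $-1$ make the posterior improper, so the priors are
  truncated there.  The deterministic link itself is defined for any
  finite shapes on its domain (the illustrative heavy-tail curves use
  $\lambda = -1$), so `icc()`/`h_lambda()` do not enforce the bound;
  `log_prior()` and the sampler do.

For comparison with guessing/slipping formulations the 3PL and 4PL
logistic models are included:
$P = c_j + (d_j - c_j)\,\mathrm{logistic}(\alpha_j(\theta_i - \beta_j))$
with discrimination $\alpha_j > 0$, guessing floor $c_j$ and ceiling
$d_j$ ($d_j = 1$ for the 3PL, implemented as a 4PL with $d$ fixed to
avoid a duplicate code path).

## Priors and estimation

The hierarchical prior is

$$\beta_j \sim N(0, \sigma_\beta^2), \quad
  \lambda_{1j}, \lambda_{2j} \sim N(0, \sigma_\lambda^2)\,I(-1, \infty),
  \quad \theta_i \sim N(0, 1),$$
$$\sigma_\beta, \sigma_\lambda \sim \text{half-Cauchy}(0, 5),$$

with the truncated-normal density carrying its correct normalizer
$1 - \Phi(-1/\sigma_\lambda)$ (this matters when $\sigma_\lambda$ itself
is updated).  The unit-variance prior on $\theta$ anchors the location
and scale of the latent metric; no further identification constraints
are imposed.  For the 3PL/4PL, $\log\alpha_j \sim N(0,1)$ and
$c_j \sim U(0, 0.5)$; the ceiling gets $d_j \sim U(0.5, 1)$.  A uniform
prior on $(0, 0.5)$ for $d$ itself would contradict data-generating
ceilings centred near $0.77$, so the package reads the $(0, 0.5)$ range
as applying to the slipping probability $1 - d_j$ — a deliberate design
choice, stated here once.

`girt()` samples the joint posterior with an adaptive
Metropolis-within-Gibbs scheme written in C++:

* every scalar gets a Gaussian random-walk proposal on an unconstrained
  scale — $\lambda$ moves on $u = \log(1 + \lambda)$ with the Jacobian
  $e^u$, scales on $\log\sigma$, discrimination on $\log\alpha$; the
  uniform-supported $c, d$ move on their natural scale with
  out-of-support proposals rejected;
* step sizes adapt toward a 0.44 acceptance rate in batches of 50
  iterations with a decaying gain, *during burn-in only*, so the
  retained draws come from a fixed Markov kernel;
* difficulties and shapes are the slowest-mixing directions but cost
  only one data-column scan per proposal, so item blocks are refreshed
  `item_sweeps` times per iteration (default 3 when shapes are sampled,
  2 otherwise);
* a $\lambda_1$ proposal touches only cells with $\eta > 0$ (and
  $\lambda_2$ only $\eta \le 0$), which the updater exploits;
* because only $\theta_i - \beta_j$ enters the likelihood, the common
  location of $(\theta, \beta)$ is identified by the priors alone and is
  the slowest direction of the posterior; a dedicated joint translation
  move shifts both blocks by one $\delta$ per iteration, leaves the
  likelihood exactly invariant, and is accepted on the prior ratio only;
* chains run sequentially from a single seeded RNG stream: a fit is a
  pure function of `(data, config, seed)`.

A gradient-based sampler (HMC/NUTS) would reach a given effective sample
size in fewer iterations; the contract here is only that the chain is an
asymptotically correct sample of the joint posterior, which the
quadrature cross-checks in the test suite verify directly on
low-dimensional toys (posterior means and SDs of a one-person/one-item
model against dense-grid integration).

Convergence is monitored with the classic split-chain potential scale
reduction factor (each chain halved, Brooks–Gelman between/within
ratio), computed for *every* sampled scalar including all abilities.
The non-rank-normalized variant is used deliberately, as the closest
match to the PSRF convention the simulation studies quote; the usual
1.05 working cutoff applies.  Summaries report posterior mean, SD, the
shortest interval containing 95% of the pooled draws (HPDI, computed by
the sorted-window method), and R-hat.

## Model-comparison criteria

All four criteria are computed from the pointwise log-likelihood matrix
(retained draws × observed response cells; one cell, one observation —
person-level pooling is intentionally not offered):

* **DIC** with the plug-in effective-parameter count:
  $p_D = \bar D - D(\bar\vartheta)$, where the plug-in $\bar\vartheta$
  is the posterior mean taken on the *unconstrained sampling scale* and
  back-transformed — this keeps the plug-in $\lambda$ inside its
  truncated support.  The variance-based $p_D$ variant would shift
  values by a few units.
* **LPML**: sum of log conditional predictive ordinates, each the
  harmonic mean of the cell likelihood over draws, evaluated in log
  space.  Reported as a log score (larger better); the other three are
  on the deviance scale (smaller better).
* **WAIC**: $-2(\text{lppd} - p_\text{waic})$ with the
  sample-variance penalty.
* **PSIS-LOO**: importance ratios $e^{-\ell}$, the largest 20% per cell
  smoothed by a generalized-Pareto fit (empirical-Bayes estimator of
  Zhang & Stephens, weakly regularized toward $k = 0.5$), truncated at
  the raw maximum; per-cell Pareto-$k$ diagnostics are returned, with
  $k > 0.7$ the usual warning level.  Below 100 draws the tail is too
  short to fit and plain importance sampling is used with a warning.

All three pointwise criteria decompose exactly over cells, which the
tests exploit (splitting the matrix by columns and summing reproduces
the totals).

## Recovery metrics and the simulation studies

`run_recovery_study()` draws one set of true parameters per condition —
$\theta \sim N(0,1)$, $\beta \sim N(0,1)$, free shapes from
$N(0, 0.5^2)$ truncated at $-1$ (rejection sampling; acceptance
$\approx 0.977$), 3PL/4PL truths $\alpha \sim U(0.5, 2)$,
$c \sim \mathrm{Beta}(5, 17)$, $d \sim \mathrm{Beta}(17, 5)$ — holds
it fixed, and lets each replication ($r$ uses seed `base_seed + r`)
redraw the responses.  Bias, MSE, SE and SD are then defined per
parameter across replications around the single true value and satisfy
the exact identity
$\mathrm{MSE} = \mathrm{SE}^2 + \mathrm{Bias}^2$, which the tests
verify on every run.

One subtlety deserves its own paragraph.  Only $\theta - \beta$ enters
the likelihood, so the origin of the latent metric is identified by the
$\theta \sim N(0,1)$ prior alone, and the fitted difficulties inherit
a common offset of about $-\bar\theta_{\text{true}}$ — for raw
$N(0,1)$ draws a fixed $N(0, 1/N)$ quantity per condition that lands
entirely in the bias column and adds a mean-$1/N$ lottery to the
averaged MSE.  (Its mirror image is visible in any such design:
per-replication estimate spread excludes the fixed offset while the
posterior SD includes $\sim 1/N$ of origin variance, so
$\mathrm{SD}^2 - \mathrm{SE}^2 \approx 1/N$.)  The recovery driver
therefore standardizes the drawn ability vector (sample mean 0, SD 1)
before generating responses: the condition's latent metric is pinned to
the scale the prior assumes, the expectation of the averaged MSE equals
the across-replication variance $\mathrm{SE}^2$ (inflated only by the
$1/R$ bias-estimation noise), and a short study stops depending on the
luck of one origin draw.  The tabulated criterion is the *mean squared* error — the
identity only holds without the square root, and published recovery
tables for this design satisfy it (e.g. $0.0498^2 + 0.0033^2 \approx
0.0027$) — while `rmse()` exposes the root form separately.  Ability
recovery uses the same formulas averaged over persons instead of items.

`run_comparison_study()` generates each replication's data once from the
true family, fits every candidate family to the *same* matrix, and
tallies best/second-best selections per criterion (DIC/WAIC/LOO
minimized, LPML maximized; ties broken by the supplied family order;
replications with any failed fit are dropped jointly so comparisons stay
paired).  `run_real_data()` chains the cleaning, multi-family fitting,
criteria table, winner's item summary, ability estimates and ICC export
into the reporting workflow, choosing the winner by WAIC.

### Problem sizes

The full published designs use 50 replications per condition with four
chains of 3000 iterations.  The package defaults and the bundled
acceptance checks run the same designs at reduced replication counts —
10 replications (5 for the $J = 40$ condition) with 2 chains × 1500
iterations for recovery; 2–3 replications for comparison sweeps — which
keeps a complete study on one desktop core in minutes while leaving the
Monte-Carlo error on averaged MSEs within roughly ±30%.  The full-scale
settings are plain arguments (`n_reps`, `chains`, `iter`), not separate
code paths.

### What the generator emulates — and what it does not

The synthetic generator reproduces the distributional assumptions of the
study design exactly: independent Bernoulli cells, normal abilities and
difficulties, truncated-normal or fixed shapes, no missingness (the
`pisa_like` fixture adds missing codes 6/9 to 76 of 685 synthetic
persons purely to exercise the cleaning rules; it is a synthetic
stand-in, not a redistribution of any assessment data).  Real response
matrices violate several of these assumptions — local dependence within
testlets, speededness, differential item functioning, nonnormal ability
distributions — so passing recovery tests demonstrate correctness of the
estimator under the model, not robustness to misspecification.  The
model-comparison studies probe one specific misspecification axis (wrong
link shape) only.

## Numerical choices

* $|\lambda| < 10^{-8}$ switches $h_\lambda$ to its linear limit
  ($\lambda \to 0$ row of the definition), avoiding 0/0; continuity at
  the switch is tested ($|h - \eta| \approx |\lambda|\eta^2/2$ nearby).
* $\eta = 0$ is assigned to the $\lambda_2$ branch; both branches vanish
  there, so this is convention only.
* $h$ is clamped to $\pm 700$ before the logistic — $h$ overflows for
  large $\lambda_1\eta$ — and the Bernoulli log-likelihood uses
  `log1p(exp(h))` with a large-$h$ asymptote, so probabilities never
  produce `NaN`.  In double precision the ICC saturates to exactly 0/1
  once $|h| \gtrsim 37$.
* Degenerate likelihoods ($p \in \{0,1\}$ contradicting the response)
  yield $-\infty$, which propagates as a flag rather than an error;
  criteria exclude non-finite draws with a warning.
* One-person or one-item matrices are legal; the posterior is then
  prior-dominated and wide, which the tests assert rather than forbid.

## Known limitations

Dichotomous responses only; unidimensional ability; no testlet/local
dependence structure; marginal maximum likelihood and variational
estimation are out of scope.  The random-walk sampler needs the full
3000-iteration default for clean R-hats on free-shape fits at
$N = 1000$; halving chains and iterations is fine for fixed-shape
models but borderline for `glogit_free`.  Very heavy-tailed items
($\lambda$ near $-1$) mix slowest because the likelihood is nearly flat
in the tail shape.
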