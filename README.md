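# glogitIRT

Bayesian estimation of one-parameter item response theory (IRT) models
built on the **generalized logistic (Stukel) link**, for psychometricians
and applied researchers who need item characteristic curves (ICCs) that
are not forced to share one symmetric — or one asymmetric — shape across
a whole test.

## The model

For person $i$ with ability $\theta_i$ and item $j$ with difficulty
$\beta_j$, the probability of a correct response is

$$P(x_{ij}=1 \mid \theta_i, \beta_j, \lambda_j) =
  \frac{\exp\{h_{\lambda_j}(\theta_i-\beta_j)\}}
       {1+\exp\{h_{\lambda_j}(\theta_i-\beta_j)\}},$$

where $h_\lambda$ is the two-shape-parameter Stukel transform: for
$\eta > 0$,

$$h(\eta) = \begin{cases}
  (e^{\lambda_1\eta}-1)/\lambda_1 & \lambda_1 > 0\\
  \eta & \lambda_1 = 0\\
  -\log(1-\lambda_1\eta)/\lambda_1 & \lambda_1 < 0,
\end{cases}$$

and the mirrored form in $\lambda_2$ for $\eta \le 0$.  $\lambda_{1j}$
sets how fast item $j$'s ICC approaches its upper asymptote, and
$\lambda_{2j}$ the lower one.  Special cases: $(0,0)$ is exactly the
Rasch model; $(0.165, 0.165)$ behaves like the one-parameter normal
ogive and $(0.62, -0.037)$ like the complementary log-log model (both up
to an affine rescaling of $\eta$; the exact probit/cloglog forms are
available as separate families).  3PL/4PL logistic models (guessing
$c$, slipping $1-d$) are included for comparison studies.

Estimation is fully Bayesian — priors $\beta_j \sim N(0,\sigma_\beta^2)$,
$\lambda_{1j},\lambda_{2j} \sim N(0,\sigma_\lambda^2)$ truncated below at
$-1$, $\theta_i \sim N(0,1)$, half-Cauchy(0, 5) scales — via an adaptive
Metropolis-within-Gibbs sampler written in C++ (seeded, exactly
reproducible).  The package also provides split-chain R-hat diagnostics,
HPDI summaries, the model-comparison criteria DIC, LPML, WAIC and
PSIS-LOO computed from the pointwise log-likelihood, Bias/MSE/SE/SD
parameter-recovery metrics, and drivers for complete recovery and
model-selection simulation studies.

## Worked example

Simulate a free-shape dataset, fit two competing families, and compare:

```r
library(glogitIRT)

design <- sim_design(n_persons = 1000, n_items = 20,
                     family = "glogit_free", base_seed = 404)
truth  <- draw_true_parameters(design, seed = 404)
X      <- simulate_responses(truth, seed = 405)

fit <- girt(X, "glogit_free", chains = 4, iter = 3000, burnin = 2000,
            seed = 406)
fit
#> Bayesian one-parameter IRT fit (family: glogit_free)
#>   1000 persons x 20 items, 20000 observed responses
#>   4 chains x 3000 iterations (2000 burn-in), 4000 retained draws
#>   max split R-hat: 1.017
#>   sampling time: 108.8 s

head(posterior_summary(fit), 3)
#>   parameter   Estimate         SD HPDI_lower HPDI_upper     Rhat
#> 1   beta[1] -0.4609406 0.09438348 -0.6623196 -0.2849331 1.007419
#> 2   beta[2] -1.8411829 0.13778515 -2.1125578 -1.5770983 1.004254
#> 3   beta[3] -0.7058926 0.11073050 -0.9312543 -0.4975543 1.005005

rasch <- girt(X, "rasch", chains = 4, iter = 3000, burnin = 2000, seed = 406)
rbind(glogit = criteria_report(fit)[, c("dic", "lpml", "waic", "loo")],
      rasch  = criteria_report(rasch)[, c("dic", "lpml", "waic", "loo")])
#>             dic      lpml     waic      loo
#> glogit 22713.62 -11390.74 22762.82 22770.53
#> rasch  22878.68 -11447.61 22891.95 22889.90
```

Every R-hat is below the 1.05 convergence cutoff, and all four criteria
prefer the generating free-shape family over the misspecified symmetric
Rasch fit
(DIC/WAIC/LOO: smaller is better; LPML: larger is better).  `coef()`,
`predict()`, `plot()` (ICC curves), `simulate()` (posterior-predictive
matrices) and `residuals()` work on the fitted object; `export_icc_curves()`
and `draws_long()` produce long-format tables for external plotting.

Response matrices are read from CSV with configurable missing-data codes
(`read_response_matrix()`, default codes 6/9, person-drop or
likelihood-skip policies), and a thin command-line wrapper with
`simulate` / `fit` / `recover` / `compare` / `icc` / `fixtures`
subcommands ships in `inst/cli/girt.R`.

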