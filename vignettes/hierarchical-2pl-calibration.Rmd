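---
title: "Hierarchical Bayesian 2PL calibration in small samples: models, generator, and simulation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian 2PL calibration in small samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the design decisions taken where the design was genuinely open.

## The model

For dichotomous responses `y[j, i]` of person `j` to item `i`, the
two-parameter logistic model is

$$\Pr(y_{ij} = 1 \mid \theta_j, \alpha_i, \beta_i)
  = \mathrm{logit}^{-1}\!\big[\alpha_i(\theta_j - \beta_i)\big],$$

with ability $\theta_j$, discrimination $\alpha_i > 0$ and difficulty
$\beta_i$, all on the logit scale. The hierarchical formulation treats the
item pairs $\xi_i = (\log\alpha_i, \beta_i)$ as exchangeable draws from a
bivariate normal with grand means $\mu = (\mu_\alpha, \mu_\beta)$, scales
$\tau = (\tau_\alpha, \tau_\beta)$ and correlation matrix $\Omega$. The
person scale is identified solely through $\theta_j \sim N(0, 1)$; no
sum-to-zero constraints are imposed.

Three ingredients distinguish the optimized formulation implemented by
`fit_bayes(model = "hier2pl")` from a naive hierarchical 2PL:

1. **Non-centered parameterization.** The actively sampled quantities are
   uncorrelated z-scores $\tilde\xi_i \sim N(0, 1)$; the item parameters are
   reconstructed deterministically as
   $\xi_i = \Lambda L_\Omega \tilde\xi_i$, with
   $\Lambda = \mathrm{diag}(\tau_\alpha, \tau_\beta)$ and $L_\Omega$ the
   lower Cholesky factor of $\Omega$, followed by
   $\alpha_i = \exp(\mu_\alpha + \xi_{\alpha i})$ and
   $\beta_i = \mu_\beta + \xi_{\beta i}$. This removes the cross-level
   posterior dependency between individual parameters and their grand means
   (the "funnel") that cripples samplers in small samples, and it guarantees
   $\alpha_i > 0$ by construction. The map is bijective given positive
   scales; `classical_to_noncentered()` inverts it exactly.

2. **Separation strategy.** Instead of one inverse-Wishart prior on the full
   covariance matrix — which ties variances and correlation together a
   priori — the scales and the correlation receive independent priors:
   $L_\Omega \sim \mathrm{LKJ}(\eta)$ with $\eta = 2$ by default (a weak
   preference for small correlations; for a $2 \times 2$ matrix this is
   equivalent to $(\rho + 1)/2 \sim \mathrm{Beta}(\eta, \eta)$), and a
   configurable hyperprior on each scale.

3. **Bounded auxiliary transforms.** Heavy-tailed scale priors are sampled
   through bounded uniform auxiliaries:
   $u \sim U(0, \pi/2)$, $\tau = s\tan u$ gives a half-Cauchy$(0, s)$ scale;
   $u \sim U(0, 1)$, $\tau = s(-\log u)$ gives an Exponential scale with
   mean $s$. Both transforms are strictly monotone, so the bounded uniform
   is an exact reparameterization, with no Jacobian surprises and no chain
   excursions into the Cauchy tail.

The remaining priors are $\mu_\alpha \sim N(0, 1)$ and
$\mu_\beta \sim N(0, 2)$.

### Hyperprior catalogue

`hyperprior_table()` lists the twelve variance-component specifications,
four per family, labelled weakly informative I/II and noninformative I/II:

| family        | parameter(s)      | WI1    | WI2        | NI1    | NI2             |
|---------------|-------------------|--------|------------|--------|-----------------|
| half-Cauchy   | scale             | 1      | 2.5        | 5      | 25              |
| Exponential   | inverse scale (rate) | 1   | 0.4        | 0.2    | 0.04            |
| inverse-Gamma | shape, scale      | 3, 2   | 1, 0.5     | 1, 2   | 0.001, 0.001    |

The Exponential rate `b` implies mean `1/b`, so WI2 is the
Exponential(mean 2.5) prior. For the inverse-Gamma family the bounded
auxiliary trick does not apply; $\tau$ is sampled directly on the log scale.

Two readings were genuinely open and are resolved as follows, each behind a
switch:

* **inverse-Gamma placement**: the prior is placed on $\tau$ itself
  (default); `hyperprior_config(..., ig_on = "tau_sq")` places it on
  $\tau^2$ with the appropriate Jacobian.
* **N(0, 2) priors**: the second argument is read as a standard deviation
  (the convention of most modern probabilistic languages);
  `scale_reading = "variance"` in the fitting and log-joint functions
  switches to the variance reading.

Throughout, $\tau_\alpha, \tau_\beta$ are standard deviations entering
$\Sigma = \tau\,\Omega\,\tau^{\mathsf T}$; the traditional label "variance
components" is kept in the documentation but never changes the math.

### Comparator models

* `model = "iw2pl"`: the centered hierarchical 2PL with
  $\xi_i \sim \mathrm{MVN}(\mu, \Sigma)$ and $\Sigma \sim IW(3, I)$ — the
  specification the separation strategy is meant to replace. The grand means
  and $\Sigma$ have conjugate full conditionals and are Gibbs-updated.
* `model = "simple2pl"`: the nonhierarchical Bayesian 2PL with independent
  $\alpha_i \sim \mathrm{logN}(0,1)$, $\beta_i \sim N(0,2)$.
* `fit_mml()`: Bock–Aitkin marginal maximum likelihood (below).

All three Bayesian log joints also exist as documented, pure-R reference
builders (`log_joint_hier2pl()`, `log_joint_iw2pl()`,
`log_joint_simple2pl()`); the test suite checks them term by term against
independent summation oracles, and the compiled likelihood against the R
reference.

## Sampling

The engine is an adaptive random-walk Metropolis-within-Gibbs sampler
written in C++ (a classic and well-understood choice for IRT posteriors),
operating directly on the non-centered parameterization. Each sweep updates
every ability, every item z-score pair, the grand means, the scale
auxiliaries and the correlation; conjugate blocks in the centered comparator
(grand means, covariance) are Gibbs draws. Because the non-centered
parameterization couples the grand means tightly to the z-scores once the
data dominate, every sweep also performs interweaving
(ancillarity–sufficiency) moves: a hyperparameter is shifted or rescaled
while the z-scores are compensated deterministically so the item parameters
— and hence the likelihood — are unchanged, leaving a prior-only acceptance
ratio. These moves cost no likelihood evaluations and keep the grand means
and scales mixing well across the whole sample-size range. Scalar proposal standard
deviations adapt towards a 0.44 acceptance rate by Robbins–Monro updates
during burn-in only and are frozen afterwards, so the post-burn-in chain is
a valid fixed-kernel Markov chain. All randomness flows through R's RNG:
identical `chain_spec()` seeds give bit-identical results.

The default chain protocol is three chains of 4000 iterations with 1000
burn-in cycles and dispersed random starting values per chain (draws around
the priors, different by chain seed); initialization failures are retried up
to three times before the fit is returned flagged rather than raising.

Summaries are computed on the classical parameterization — discriminations
are averaged *after* exponentiation, per draw — because that is the scale on
which calibration results are used. The point estimate is the posterior
mean (`point_estimate = "median"` switches). Convergence is assessed with
the classic Gelman–Rubin between/within statistic (no rank normalization; a
split-chain variant sits behind `gelman_rubin(split = TRUE)`), computed for
every item parameter, the grand means and the variance components — not the
individual abilities, since item calibration is the target. A fit counts as
converged only if every monitored $\hat R < 1.05$, strictly. Interval
summaries are sample-based highest density intervals: the shortest
contiguous window of the sorted draws containing $\lceil 0.95\,n\rceil$
points, ties broken towards the smaller lower bound (never wider than the
equal-tailed interval by construction). Effective sample sizes use coda's
spectral estimator; they are reported, not used for any decision, and can be
switched off (`compute_ess = FALSE`) where summary cost matters.

```{r}
library(hier2pl)
ds <- generate_dataset(generating_condition(100, 25, c(0.25, 0.90), 0.3, seed = 1))
fit <- fit_bayes(ds$responses, "hier2pl", hyperprior_config("exponential", "WI2"),
                 chains = chain_spec(3, 4000, 1000, seed = 1))
fit$converged
```

## The MML comparator

`fit_mml()` re-implements Bock–Aitkin EM so the comparator is self-contained
and screenable: the E-step computes person posteriors on a 41-point
equally spaced quadrature grid over [−6, 6] carrying normalized
standard-normal weights (Gauss–Hermite available via
`em_settings(quadrature = "gauss_hermite")`); the M-step runs per-item
Newton–Raphson on the slope/intercept logistic
$\mathrm{logit}^{-1}(a\theta + c)$ with the expected counts. The marginal
log-likelihood is non-decreasing across iterations — asserted in the tests —
and estimates are mapped back by $\alpha = a$, $\beta = -c/a$.

MML has no prior to keep boundary patterns finite, so the harness screens
solutions: a fit is *inadmissible* when the EM did not converge, any item
was answered all-correct/all-wrong, any $\alpha \le 0$, or any estimate
exceeds the caps $\alpha > 10$, $|\beta| > 10$. These caps are this
package's operationalization (exposed as arguments); published studies
report inadmissibility rates without printing their rule. An optional
per-item lognormal penalty on the slope (`slope_penalty`) is available as
the usual rescue for a boundary item one wants to keep. EAP ability scores
are computed by quadrature under the N(0, 1) population prior in all cases.

## The data generator

`generate_dataset()` emulates a calibration study's generating process:

1. draw item pairs from a bivariate normal with grand mean (1, 0) truncated
   to the box [0.65, 4.0] × [−4.5, 4.5] (rejection sampling; the initial
   covariance equals the target $\Sigma$ — immaterial, see step 2);
2. **exact-moment rescaling**: center, whiten with the inverse Cholesky
   factor of the *sample* covariance, color with the Cholesky factor of
   $\Sigma = \tau\,\Omega\,\tau^{\mathsf T}$ — after which the sample SDs
   and correlation of the generated set equal the targets to numerical
   precision (about 1e-10), for every seed, not merely in expectation. The
   sample covariance uses the n−1 denominator (n variant switchable);
3. shift each column to the true marginal means of the truncated bivariate
   normal — computed by reducing the 2-D moment integrals to 1-D integrals
   of closed-form conditional-normal expressions, integrated adaptively to
   1e-10 — so the generated grand means are correct;
4. redraw the whole set (at most 100 times) if any parameter leaves the
   admissible ranges $0.5 < \alpha < 3.5$, $-4 < \beta < 4$; since each
   draw's moments are exact, redrawing does not disturb them;
5. draw $\theta_j \sim N(0, 1)$ and Bernoulli responses from the 2PL.

Generation happens on the natural $(\alpha, \beta)$ scale — that is what the
truncation limits and the grand mean of 1 refer to — even though the model
pools $(\log\alpha, \beta)$. With a grand mean of 1 the two scales differ
only at second order ($\mathrm{sd}(\log\alpha) \approx
\mathrm{sd}(\alpha)/\overline{\alpha}$), which is why comparing estimated
$\tau_\alpha$ to the generating value remains meaningful; a log-scale
generator is available via `generate_item_parameters(scale = "log")`. The
minimum item count is 3 (the sample covariance of two points is singular, so
the exact rescaling is undefined).

What the generator does **not** emulate: guessing (no 3PL lower asymptote),
multidimensional abilities, polytomous items, nonignorable missingness,
misfit between the fitted and generating model, or difficulty distributions
shifted against the ability distribution. Passing recovery tests therefore
demonstrates internal consistency of estimator and generating process — not
robustness of the 2PL to real-data violations.

## The simulation harness

`build_design_grid()` crosses 6 sample sizes {50, 75, 100, 150, 200, 500},
2 test lengths {25, 50}, 3 variance-component pairs {(0.10, 0.40),
(0.25, 0.90), (0.75, 1.50)} (small / typical / extreme), 2 correlations
{0, 0.3}, and the 12 hyperprior cells: 864 conditions, 100 replications
each by default. `run_study()` generates, fits, discards and aggregates:

* **discard rules**: Bayesian replications with any monitored
  $\hat R \ge 1.05$ and inadmissible MML replications are excluded from
  bias/RMSE but counted in the per-cell rates;
* **bias**: averaged across items within a replication, then across
  replications (mirrored for persons — the published rule covers items
  only, so the person rule is this package's symmetric choice);
* **RMSE**: per item across replications, then averaged across items;
  variance components aggregate directly across replications;
* **conditional means**: per family and cell, the mean across the four
  specifications plus each specification's deviation
  (`conditional_mean_table()`), the quantity robustness statements are made
  about.

Seeds split deterministically: master seed → cell seed → replication seed,
so any (cell, replication) is independently reproducible and results merge
identically regardless of completion order; one flat record per
(cell, replication, model) is appended to a checkpoint file, and a resumed
run recomputes nothing. The full 864 × 100 grid is a cluster-scale
experiment; the test suite exercises the harness at the scale a single
machine handles comfortably — 10 replications per condition at N = 100,
k = 25 for the bias bands, N = 50 for the hierarchical-vs-nonhierarchical
RMSE comparison, and a 3 × 2000-iteration (500 burn-in) chain protocol —
sizes chosen to keep Monte-Carlo error well inside the asserted bands.

```{r}
grid <- build_design_grid(sample_sizes = 100L, test_lengths = 25L,
                          tau_pairs = list(c(0.25, 0.90)), rhos = 0.3,
                          families = "exponential", specs = "WI2",
                          replications = 10L)
res <- run_study(grid, list(list(model = "hier2pl"), list(model = "mml")),
                 chains = chain_spec(3, 2000, 500, seed = 1), master_seed = 1)
res[, c("model", "replications_used", "bias_tau_alpha", "bias_beta", "rmse_alpha")]
```

## Numerical choices and degenerate inputs

* Bernoulli log-likelihoods use `log1p(exp(·))` forms; no probability is
  ever materialized at 0 or 1.
* The tangent transform clips its argument a relative machine epsilon away
  from $\pi/2$; proposals outside a bounded support are rejected (a valid
  Metropolis move), not reflected.
* Ties in the HDI window go to the smallest lower bound; constant samples
  return a zero-width interval; constant chains return $\hat R = 1$ exactly.
* An item answered correctly by everyone is handled without adjustment by
  the Bayesian models (shrinkage keeps it finite) and flagged inadmissible
  by the MML screen; EM Newton steps are clamped so boundary items cannot
  produce non-finite intermediate values.
* Missing responses are treated as missing at random and contribute zero
  likelihood; readers reject anything other than 0, 1 or the missing marker,
  with the offending cell's coordinates.

## Known limitations

* Unidimensional, dichotomous 2PL only — no 3PL guessing parameter, no
  polytomous models, no multidimensional extension.
* The random-walk engine mixes more slowly per iteration than a
  gradient-based sampler; the grand-mean/correlation blocks have the lowest
  effective sample sizes, and very diffuse specifications (notably the
  half-Cauchy NI2, scale 25) are expected to show elevated non-convergence
  rates — as reflected in the discard-rate bookkeeping rather than hidden.
* MML standard errors are not computed (the screen needs only the point
  estimates); no WAIC/LOO model comparison; no plotting.
* The exactness guarantee of the generator applies to the sample moments of
  the item parameters; response matrices remain Bernoulli-noisy, so
  estimator comparisons at 10 replications carry visible Monte-Carlo error.
* Truth–estimate *correlations* for the discriminations are attenuated
  whenever the true spread is small relative to the estimation error: under
  the typical-variance condition (sd(α) = 0.25) no estimator — Bayesian or
  MML — exceeds r ≈ 0.9 at N = 500, although the item-averaged bias is tiny.
  Recovery correlations are only a sharp diagnostic under wide-spread
  (extreme-variance) conditions.
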