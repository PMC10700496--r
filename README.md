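# hier2pl

Small-sample item calibration with a hierarchical Bayesian two-parameter
logistic (2PL) IRT model.

## The problem

Calibrating dichotomous test items with the 2PL model,

P(y_ij = 1 | θ_j, α_i, β_i) = logit⁻¹[ α_i (θ_j − β_i) ],

usually requires several hundred respondents: item discriminations α_i and
difficulties β_i are poorly identified in small samples, and marginal maximum
likelihood (MML) routinely returns inadmissible solutions (negative or
runaway discriminations, items nobody gets wrong). Hierarchical Bayesian
estimation pools information across items — the pairs ξ_i = (log α_i, β_i)
share a bivariate prior with grand means μ = (μ_α, μ_β), scales
τ = (τ_α, τ_β) and correlation matrix Ω — which stabilizes calibration down
to N ≈ 50. The catch is that naive hierarchical 2PL samplers suffer funnel
degeneracies, and the usual inverse-Gamma / inverse-Wishart hyperpriors bias
the variance components, and with them every shrunken item parameter.

`hier2pl` implements the optimized formulation of that hierarchical model:

* **non-centered parameterization** — the sampler moves uncorrelated
  z-scores ξ̃_i ~ N(0, 1) and reconstructs ξ_i = Λ L_Ω ξ̃_i deterministically,
  with Λ = diag(τ_α, τ_β) and L_Ω the Cholesky factor of Ω;
* **separation strategy** — scales and correlation get independent priors:
  L_Ω ~ LKJ(2), and τ_α, τ_β get a configurable hyperprior;
* **bounded auxiliary transforms** — heavy-tailed scale priors are sampled
  through bounded uniforms: τ = s·tan(u) with u ~ U(0, π/2) is
  half-Cauchy(0, s); τ = s·(−log u) with u ~ U(0, 1) is Exponential(mean s);
* the twelve catalogued hyperprior specifications (half-Cauchy scales 1,
  2.5, 5, 25; Exponential rates 1, 0.4, 0.2, 0.04; inverse-Gamma (3,2),
  (1,0.5), (1,2), (0.001,0.001)), labelled WI1/WI2/NI1/NI2.

It also ships the three standard comparators — the centered hierarchical 2PL
with Σ ~ IW(3, I), the nonhierarchical Bayesian 2PL (α ~ logN(0,1),
β ~ N(0,2)), and Bock–Aitkin MML with an inadmissibility screen — plus the
data generator and bias/RMSE harness of a parameter-recovery simulation
study: item parameters drawn from a box-truncated bivariate normal and
rescaled so every generated item set has *exactly* the target standard
deviations and correlation.

## Worked example

```r
library(hier2pl)

# a small calibration sample: 100 persons, 25 items, typical variances
cond <- generating_condition(n_persons = 100, n_items = 25,
                             tau_pair = c(0.25, 0.90), rho = 0.3, seed = 42)
dataset <- generate_dataset(cond)

fit <- fit_bayes(dataset$responses, model = "hier2pl",
                 config = hyperprior_config("exponential", "WI2"),
                 chains = chain_spec(n_chains = 3, n_iterations = 2000,
                                     n_burnin = 500, seed = 7))
fit
#> <fit_result> model=hier2pl (exponential/WI2), converged
#>  parameter     mean    sd rhat   ess
#>   mu_alpha -0.00732 0.101 1.01 202.0
#>    mu_beta  0.02867 0.218 1.01 370.2
#>  tau_alpha  0.19589 0.104 1.02 130.2
#>   tau_beta  0.94156 0.184 1.00 327.7
#>        rho  0.33507 0.310 1.01  89.9
```

The fit converged (every monitored Gelman–Rubin R̂ < 1.05). The posterior
means of the variance components sit near the generating values
τ = (0.25, 0.90) — τ_β at 0.94, τ_α mildly shrunken to 0.20, the behavior
expected at N = 100 — and the correlation's posterior mean 0.34 sits next to
the generating 0.3 well inside its posterior spread. Item recovery against
the known truth:

```r
items <- estimated_items(fit)
round(cor(items$beta, dataset$items$beta), 3)   # 0.965
round(mean(items$beta - dataset$items$beta), 3) # -0.022 (item-averaged bias)
```

The MML comparator on the same data:

```r
fit_mml(dataset$responses)
#> <mml_result> 25 items, converged, admissible (logLik -1437.78 after 31 EM iterations)
```

A command-line front end covering generate / fit / study / evaluate ships in
`inst/cli/hier2pl`:

```sh
Rscript inst/cli/hier2pl generate --n 100 --k 25 --tau 0.25,0.90 --rho 0.3 --seed 1 --out data/
Rscript inst/cli/hier2pl fit --data data/responses.csv --model hier2pl \
    --family exponential --spec WI2 --out fit.csv
```

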