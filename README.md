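# cmpd3

Exact Bayesian inference for lifetimes modelled by a **3-component mixture
of power distributions** under **type-I right censoring**.

## The problem

Reliability data are often heterogeneous: units fail through several
distinct mechanisms, each with its own lifetime law. When lifetimes live on
the unit interval (or arrive as exponential-type lifetimes mapped there by
`y = exp(-x)`), a natural model is the mixture

```
f(y; Θ) = p₁ λ₁ y^{λ₁-1} + p₂ λ₂ y^{λ₂-1} + (1 − p₁ − p₂) λ₃ y^{λ₃-1},   0 < y < 1,
```

with shape parameters `λₘ > 0` and mixing weights `p₁, p₂`
(`Θ = (λ₁, λ₂, λ₃, p₁, p₂)`). A life test is terminated at a fixed time
`t`, so the `n − u` surviving units contribute only `{S(t)}^{n-u}` to the
likelihood, where `S` is the mixture survival function.

Expanding `{S(t)}^{n-u}` by nested binomial series turns the posterior of
`Θ` into a **finite signed mixture of Gamma × Gamma × Gamma × Dirichlet
components** — one per index triple `0 ≤ k ≤ j ≤ i ≤ n−u` — so posterior
moments, marginal densities, Bayes estimators, and posterior risks all have
closed forms. No MCMC is involved anywhere.

The package is aimed at reliability analysts and biostatisticians who want
exact small-sample Bayes answers for mixture lifetime data, and at anyone
studying how the choice of prior (uniform, Jeffreys', or an elicited
informative gamma × bivariate-beta prior) and loss function (squared-error
SELF, quadratic QLF, precautionary PLF, DeGroot DLF) affects the estimates
and their posterior risks.

## What's inside

| Area | Functions |
| --- | --- |
| Data reduction | `summarize_censored()`, `censored_summary()`, `read_censored_summary()` |
| Exact posterior | `build_posterior()`, `posterior_moment()`, `marginal_pdf()`, `log_likelihood()` |
| Decision theory | `bayes_estimate()`, `posterior_risk()`, `estimate_all()`, `information_criteria()` |
| Prior elicitation | `ppd_density()`, `ppd_interval_probability()`, `elicit_hyperparameters()` |
| Monte Carlo harness | `simulation_config()`, `run_replicate()`, `run_mc_study()` |
| Command line | `cmd_estimate()`, `cmd_simulate()`, `cmd_elicit()`, `cmd_ppd()` |

A classic benchmark — the Kevlar 373/epoxy fatigue-fracture lifetimes,
76 units in three subpopulations censored at 3.4 on the negative-log scale
— ships as a plain-text sufficient-statistic fixture
(`inst/extdata/kevlar_summary.txt`).

## Worked example

```r
library(cmpd3)

tab <- estimate_all(kevlar_summary(), priors = c("UP", "JP"),
                    losses = c("SELF", "QLF"))
print(tab)
#> Bayes estimates
#>          lambda1  lambda2  lambda3       p1       p2
#> SELF UP 0.761517 0.737372 0.755910 0.338405 0.338013
#> QLF UP  0.700854 0.678693 0.692959 0.318327 0.317936
#> SELF JP 0.731365 0.708214 0.724613 0.338424 0.338007
#> QLF JP  0.670828 0.649641 0.661789 0.318343 0.317925
#>
#> Posterior risks
#>          lambda1  lambda2  lambda3       p1       p2
#> SELF UP 0.023162 0.021687 0.023857 0.003249 0.003246
#> QLF UP  0.041448 0.041408 0.043413 0.031014 0.031051
#> SELF JP 0.022194 0.020786 0.022818 0.003250 0.003247
#> QLF JP  0.043141 0.043109 0.045282 0.031020 0.031059
```

Reading this: under the uniform prior and squared-error loss, the posterior
mean of the first component's shape is `λ̂₁ = 0.7615` with posterior
variance (its SELF risk) `0.0232`; about a third of the population is
attributed to each subpopulation (`p̂₁ ≈ p̂₂ ≈ 0.338`). Quadratic loss
shrinks every estimate (it weights small parameter values more) and Jeffreys'
prior gives slightly smaller shape estimates than the flat prior, with
slightly smaller risks — the pattern used to compare priors and losses.

The posterior object itself:

```r
post <- build_posterior(kevlar_summary(), "uniform")
print(post)
#> Exact signed-mixture posterior (uniform prior)
#>   364 components (n - u = 11), ln(Omega) = -168.243
#>   posterior means:
#>  lambda1  lambda2  lambda3       p1       p2
#> 0.761517 0.737372 0.755910 0.338405 0.338013
```

Model fit at a plug-in estimate:

```r
theta <- mixture_params(0.761517, 0.737372, 0.755910, 0.338405, 0.338013)
ll <- log_likelihood(theta, kevlar_summary())
information_criteria(ll, k = 5, n = 76)
#>      aic      bic
#> 145.0845 156.7382
```

From the shell, the same analysis:

```sh
Rscript -e 'cmpd3::cmd_estimate()' --summary inst/extdata/kevlar_summary.txt --out kevlar
```

## Further reading

The methods vignette (`vignettes/cmpd3-methods.Rmd`) documents the model
and its assumptions, the signed-expansion numerics (including the
cancellation guard and the double-precision conditioning limit), the
elicitation design choices, what the synthetic-data generator does and does
not emulate, and known limitations.
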