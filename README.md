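# phylomiss

Missing-taxa sensitivity analysis for phylogenetic comparative methods.

Model-based studies of continuous trait evolution fit stochastic models
— Brownian motion (BM), multi-rate Brownian motion (BMS),
Ornstein–Uhlenbeck (OU) and multi-optimum OU (OUM) — to a phylogeny and
a vector of tip trait values. Real datasets almost always lack taxa, and
the lacking taxa are rarely missing at random: sampling probability
tracks ecological traits with phylogenetic signal, so missing taxa tend
to be phylogenetically *clumped* or directly *correlated* with the trait
under study. `phylomiss` implements a complete simulation framework for
measuring what such missingness does to AICc model selection and to the
bias and precision of parameter estimates.

The package provides, as plain R functions over `ape` trees:

* simulation of unit-height pure-birth trees, binary selective regimes
  under an equal-rates Mk model, and traits under the exact Gaussian
  transitions of BM/BMS/OU/OUM
  (σ² per regime, optima θ per regime, attraction strength α);
* three missingness generators — per-tip Bernoulli (random),
  thresholded Brownian liability (clumped), and trait-proportional
  weighted sampling without replacement (correlated);
* the Fritz–Purvis **D** statistic of a binary character, scaled between
  a permutation null (D = 1) and a prevalence-matched Brownian-threshold
  null (D = 0);
* maximum-likelihood fitting of all four models by profiled GLS (Hansen
  weight matrices for OUM, fixed-root OU covariance), AICc selection
  with `AICc = −2logL + 2k + 2k(k+1)/(n−k−1)`, and a BM-vs-OU
  likelihood-ratio test;
* an experiment orchestrator that runs replicated factorial designs and
  tabulates selection error rates, delta-AICc, normalized bias
  ((mean estimate − truth)/truth) and MAD-based precision.

The fitting entry point `fit_trait_model()` returns a classed object
with `print`, `summary`, `coef`, `logLik`, `predict`, `residuals`,
`simulate` and `plot` methods. See the vignette
(`vignettes/missing-taxa-methods.Rmd`) for the models, the study design
and every numerical choice.

## Worked example

Simulate one study replicate — a 300-tip tree, regimes, an OUM trait,
10% trait-correlated missingness — then quantify the signal of the
missingness pattern and refit the models to the pruned data:

```r
library(phylomiss)

tree    <- simulate_yule_tree(300, seed = 42)
regimes <- simulate_mk_regimes(tree, q = 0.5, seed = 43)
trait   <- simulate_trait(tree, regimes, model_spec("OUM"), seed = 44)
status  <- sample_missing_correlated(trait, p = 0.1, seed = 45)

d_statistic(tree, status, seed = 46)
#> Fritz-Purvis D = 0.9992  (d_obs = 50.697, d_r = 50.716, d_b = 26.723, 1000 nulls)

pruned <- apply_missingness(tree, trait, status)
pp     <- prune_painting(tree, regimes, pruned$tree)
summary(fit_trait_model(pruned$tree, pruned$trait, "OUM", pp))
#> Trait-evolution model fit: OUM (n = 270 tips)
#>   estimates:  sigma2_0 =  0.4868, theta_0 = 10.2100, theta_1 = 10.8000, alpha =  1.7200
#>   logLik = -13.4207   k = 4   AICc = 34.9923
#>   phylogenetic half-life ln(2)/alpha = 0.4029 tree heights
#>   stationary variance sigma2/(2 alpha) = 0.1415

all4 <- fit_all_models(pruned$tree, pruned$trait, pp)
all4$best
#> [1] "OUM"
round(all4$delta, 2)
#>    BM   BMS    OU   OUM
#> 17.87 18.83  0.76  0.00
```

The generating parameters (σ² = 0.5, θ₀ = 10, θ₁ = 11, α = 1.5) are
recovered closely, the trait-correlated status carries essentially no
phylogenetic signal (D ≈ 1, as this scheme draws tips
non-phylogenetically), and OUM is correctly selected with the nested OU
model 0.76 AICc units behind.

Full factorial designs run through `run_experiment()` (or the wrapper
script `inst/scripts/run-experiment.R`), which writes per-replicate and
per-cell summary CSVs plus a run manifest.

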