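---
title: "Models and simulation design for missing-taxa sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation design for missing-taxa sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomiss)
```

## The problem

Comparative studies of continuous trait evolution fit stochastic models
to a phylogeny and a vector of tip trait values, and almost never have
every member of the clade in hand. Taxa go unsampled because they are
rare, remote, or hard to collect — ecological properties that themselves
have phylogenetic signal and can correlate with the very trait under
study. Missing taxa are therefore unlikely to be missing at random: they
should be expected to be phylogenetically clumped, or correlated with
the modelled trait. `phylomiss` provides a complete, testable pipeline
for asking what such non-random missingness does to model selection and
parameter estimation, by simulating studies end to end and fitting the
standard single- and multi-regime Gaussian models back to the degraded
data.

## Trait models

All four models are Gaussian processes along the tree, so tip data are
multivariate normal with mean and covariance determined by the tree, the
regime painting and the parameters.

* **BM** — Brownian motion with rate $\sigma^2$: over a branch of
  length $t$, the change is $\mathcal N(0, \sigma^2 t)$. Tip covariance
  is $\sigma^2 t_a(i,j)$, where $t_a(i,j)$ is the depth of the most
  recent common ancestor of tips $i$ and $j$.
* **BMS** — Brownian motion whose rate depends on a binary regime
  painted on the branches: the covariance accumulates
  $\sum_r \sigma_r^2 \cdot (\text{path length in regime } r)$ along the
  shared root-to-MRCA path.
* **OU** — Ornstein–Uhlenbeck: $dX = \alpha(\theta - X)\,dt +
  \sigma\,dW$. With the root pinned at a known value, the exact
  transition over a branch of length $t$ is
  $X_{child} \sim \mathcal N\!\big(\theta + (x_{parent}-\theta)e^{-\alpha t},\,
  \tfrac{\sigma^2}{2\alpha}(1 - e^{-2\alpha t})\big)$, and the tip
  covariance is
  $\tfrac{\sigma^2}{2\alpha} e^{-\alpha(d_i + d_j - 2t_a)}
  (1 - e^{-2\alpha t_a})$ with $d_i$ the tip depths.
* **OUM** — OU with a regime-dependent optimum. The expected tip value
  is a convex combination of the optima given by the Hansen weight
  matrix: each regime segment $[t_0, t_1]$ of the root-to-tip path
  contributes weight $e^{-\alpha(d_i - t_1)} - e^{-\alpha(d_i - t_0)}$
  to its regime's optimum, and the root contributes $e^{-\alpha d_i}$ to
  the root regime's optimum. Rows sum to one by telescoping.

Because every model is linear-Gaussian, maximum likelihood reduces to
profiled generalised least squares (`gls_profile()`): for fixed shape
parameter (none for BM, the rate ratio $\sigma_1^2/\sigma_0^2$ for BMS,
$\alpha$ for OU/OUM) the regression coefficients and the overall scale
$\hat\sigma^2$ have closed forms, leaving a 1-dimensional profile
likelihood. Parameter counts are $k = 2$ (BM: rate, root mean), 3 (BMS:
two rates, root mean), 3 (OU: rate, optimum, $\alpha$) and 4 (OUM: rate,
two optima, $\alpha$). Models are compared by
$\mathrm{AICc} = -2\log L + 2k + 2k(k+1)/(n-k-1)$, and BM vs OU can also
be compared by a likelihood-ratio test ($2\Delta\log L$ against
$\chi^2_1$; no boundary-mixture correction is applied — see below).

## The simulated study

A replicate of one design cell proceeds as:

1. **Tree** — a pure-birth (Yule) tree rescaled to unit height. The tip
   count before pruning is `round(300 / (1 - p))` so that 300 tips always
   remain afterwards, isolating the effect of missingness from the
   effect of tree size (333 tips at 10% missing, 600 at 50%, 3000 at
   90%).
2. **Regimes (R)** — a binary character under the equal-rates Mk model
   with transition rate $q = 0.5$, simulated by the exact two-state
   transition probability $(1 - e^{-2qt})/2$ node to node. A replicate
   is accepted only if the minority regime covers 25–45% of the tips
   retained after pruning; otherwise the regime/trait/status triple is
   redrawn (the trait must be redrawn too, because under correlated
   missingness the retained set depends on it).
3. **Trait (T)** — simulated under one of the four models with the study
   parameters $\sigma_0^2 = 0.5$, $\sigma_1^2 = 1$, $\theta_0 = 10$,
   $\theta_1 = 11$, $\alpha = 1.5$ (a phylogenetic half-life of
   $\ln 2 / 1.5 \approx 0.46$ tree heights — a process of moderate
   strength).
4. **Sampling status (S)** — one of three schemes. *Random* (rMT): each
   tip missing independently with probability $p$, so the realised count
   is binomial (at $p = 0.5$ on 600 tips the realised fraction ranges
   roughly 0.43–0.57). *Clumped* (cluMT): a Brownian liability
   ($\sigma^2 = 1$) is simulated on the tree and the lowest
   $\mathrm{round}(pn)$ tips are missing — a threshold model, giving
   missingness with strong phylogenetic signal. *Correlated* (corMT):
   exactly $\mathrm{round}(pn)$ tips are drawn missing sequentially
   without replacement with probability proportional to
   $w_i = t_i/\mathrm{sum}(T) - \min(T)/\mathrm{sum}(T)$, so missingness
   is linearly proportional to the trait and the minimum-trait tip is
   never missing.
5. **D statistic** — the Fritz–Purvis D of S on the full tree: the sum
   of sister-clade differences (nodal values estimated by unweighted
   child averaging) scaled between a permutation null (D = 1) and a
   Brownian-threshold null matched to the observed prevalence (D = 0),
   1000 replicates each by default.
6. **Prune and fit** — missing tips are dropped (degree-2 nodes
   suppressed, depths preserved), the regime painting is transferred to
   the pruned tree through preserved MRCAs, all four models are fitted,
   and the AICc-best model recorded.

Across replicates, `run_experiment()` tabulates model-selection error
rates, the median AICc shortfall of the generating model when it loses,
and the normalized bias ((mean estimate − truth)/truth) and precision
(median absolute deviation from the median, divided by truth) of each
generating parameter, using only the generating model's own converged
fits.

## Design choices

Several points are genuinely open in this kind of design; the package
fixes them as follows.

* **Edge-regime convention.** An edge carries the state of its parent
  (rootward) node, constant along the edge; within-edge transitions are
  not simulated. The same convention drives the trait simulator, the
  BMS covariance and the OUM weight matrix, so simulation and fitting
  are mutually consistent by construction.
* **Mk root state** is uniform on $\{0, 1\}$ — the stationary
  distribution of the equal-rates chain.
* **Root handling for OU/OUM.** The root value is pinned to the root
  regime's optimum (non-random root), giving $k = 3$ and $k = 4$. The
  trait simulator starts every model at the trait value 10 (equal to
  $\theta_0$), so the fitted mean family matches the generating process
  exactly whenever the root is in regime 0; when the Mk draw puts the
  root in regime 1 the pinned-root family is mildly misspecified, which
  is one plausible source of the small systematic biases in the optima.
* **BM/BMS root value.** Set to 10 so trait scales match across models;
  BM-family inference is invariant to any constant shift, so the choice
  is inconsequential.
* **rMT is per-tip Bernoulli**, not exact-count sampling: only the
  Bernoulli reading is compatible with a realised missing fraction that
  varies across replicates at fixed $p$.
* **corMT sampling** renormalises weights after each draw (the
  semantics of weighted integer sampling without replacement, as
  implemented by R's `sample.int`).
* **LRT without boundary correction.** BM sits on the $\alpha = 0$
  boundary of OU, so a 50:50 mixture reference is arguable; the plain
  $\chi^2_1$ test is used, which is conservative in the direction that
  matters for the BM-vs-OU comparison reported here.
* **Bias sign convention** is (mean estimate − truth)/truth, so a
  positive value means overestimation (e.g. $\alpha$ is overestimated,
  $\theta_1$ underestimated).
* **Replicates are fully independent across cells**; nothing (trees,
  regimes) is shared between cells.

## Numerical choices

* $\alpha$ and the BMS rate ratio are profiled on a log scale —
  $\alpha \in [10^{-6}, 10^3]$, ratio in $[10^{-4}, 10^4]$ — by a
  12-point grid scan followed by Brent refinement in the bracketing
  interval (tolerance $10^{-5}$ on the log scale, i.e. far below the
  Monte-Carlo spread of the estimates). Estimates at the search
  boundary are flagged.
* Covariance factorisations use Cholesky with a $10^{-10}$ diagonal
  ridge retried on failure; near-singularity arises only at extreme
  $\alpha$.
* Zero-variance traits are flagged as non-converged rather than fitted;
  flagged fits are excluded from bias/precision summaries but counted.
* `round()` (half-to-even) fixes the missing-tip counts; liability ties
  (measure zero) break by tip-label order.
* Trees are validated as rooted, bifurcating and branch-length-complete;
  ultrametricity is checked to $10^{-9}$ absolute but violations only
  warn, because every fitting formula remains valid on non-ultrametric
  trees.
* Tip order for all matrices is sorted tip-label order, and internal
  node identity follows a deterministic traversal, so repeated runs
  produce identical matrices.

## What the generator does and does not emulate

The generator reproduces the study conditions exactly: pure-birth
topologies, unit height, the parameter values above, and the three
missingness mechanisms. It does **not** emulate extinction (on internal
branches or otherwise), measurement error, diversification-dependent
traits, multifurcations, or a mechanistic joint model of trait and
sampling liability (corMT is non-phylogenetic by construction). Passing
tests therefore show that the *pipeline* behaves as designed under these
idealised conditions; they do not certify robustness of real-data
analyses whose generating process differs.

## Problem sizes used by the test suite

The full design (4 models × 10 scenario/percentage combinations × 1000
replicates) is the full-scale study; the package's own quantitative
checks run reduced versions chosen to keep a complete run on one core
comfortable: 50 D-statistic replicates per percentage and
scheme, 200 replicates for the no-missing-taxa model-selection cells,
400 pooled fits for the $\alpha$ bias, and 200 replicates for the 90%
correlated-missingness bias, with all comparisons made at 3 Monte-Carlo
standard errors (both our estimate's and the reference mean's). A full-
scale run is a single `run_experiment()` call away.

## Known limitations

* Only two regimes are supported, matching the binary regime character.
* The D statistic is defined for binary characters on bifurcating
  trees; no p-values are attached (only means are used here).
* The OUM optimum weights assume the painted (known) regime history;
  regime uncertainty (e.g. stochastic mapping) is out of scope.
* Multivariate traits and trait-dependent diversification are out of
  scope.
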