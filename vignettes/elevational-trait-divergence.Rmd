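---
title: "Models and methods for elevational trait divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for elevational trait divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevtraits)
```

# The scientific question

Plant species of temperate mountain ranges segregate along elevation, and
with it along temperature regimes. Do species from low and high elevations
differ heritably in growth and stress-tolerance traits, and if so, did those
differences arise through drift-like divergence or through adaptation toward
distinct trait optima? `elevtraits` implements the comparative machinery to
answer this on a time-calibrated phylogeny: discrete regime reconstruction,
competing trait-evolution models, information-criterion consensus, and
supporting mixed-model and multivariate analyses — together with a synthetic
data generator so that every stage can be validated by simulation without
any external data.

# Elevational regimes and their history

Species are assigned to a binary regime from their median elevational
occurrence with a threshold of 1500 m a.s.l., separating foothill/hill
species from sub-alpine/alpine ones. A species exactly at the threshold is
classed "low": the closed-low convention is arbitrary but deterministic and
affects a measure-zero set of inputs.

Regime switching along the tree follows a 2-state continuous-time Markov
model with rates $q_{LH}$ and $q_{HL}$ (events per million years, mya),
either constrained equal (ER, 1 parameter) or free (ARD, 2 parameters).
The likelihood is computed by Felsenstein pruning with per-branch
$2\times 2$ matrix exponentials and a flat $(1/2, 1/2)$ root prior — flat
rather than stationary so that ER and ARD remain directly comparable and
the prior carries no information the data do not. Rates are estimated by
bounded maximum likelihood on the log scale over $[10^{-6}, 100]$ per mya
with an 8-point multi-start grid, which brackets any plausible rate for
trees measured in mya.

Because the tip states determine the interior history only probabilistically,
regime-dependent trait models are fitted over *stochastic character maps*:
full histories sampled from the joint posterior of the switching process
given the tips. Node states are drawn exactly from the pruning partials
root-to-tip; within-branch paths conditional on endpoint states are drawn by
rejection sampling (with the first jump forced when the endpoints differ),
falling back after 1000 attempts to exact uniformization sampling, which
guarantees termination on long branches with incompatible endpoints. The
sampler is validated against the analytically computed marginal node
posteriors (total variation < 0.02 at 10,000 maps) and, per branch, against
conditioned forward simulation.

# Five models of trait evolution

Species mean trait values $\mathbf{y}$ are modelled as multivariate normal
with mean and covariance determined by one of five processes, always plus a
*known* measurement-error diagonal $\mathrm{diag}(SE^2)$, where $SE$ is the
standard error of each species mean across sowing rounds (never estimated;
species observed in a single round receive the trait's median SE, flagged):

* **WN** (white noise): $y_i \sim N(\mu, \sigma^2)$, independent of the
  phylogeny; $k = 2$.
* **BM1**: Brownian motion, covariance $\sigma^2 C$ with $C$ the shared
  root-to-MRCA time matrix; $k = 2$.
* **BMM**: Brownian motion whose rate depends on the mapped regime: each
  branch contributes $\sigma^2_{state} \times$ (time in state); $k = 3$.
* **OU1**: single-optimum Ornstein–Uhlenbeck with pull $\alpha$ toward
  $\theta$; $k = 3$.
* **OUM**: OU with regime-specific optima $\theta_{LOW}, \theta_{HIGH}$ and
  shared $\alpha, \sigma^2$ — regimes move the optimum, not the dynamics;
  $k = 4$.

For the OU models on an ultrametric tree the covariance is
$V_{ij} = \frac{\sigma^2}{2\alpha} e^{-2\alpha (T - s_{ij})}
(1 - e^{-2\alpha s_{ij}})$ with $s_{ij}$ the shared time, and the OUM
expectation integrates the mapped optima along each lineage:
segment $[t_0, t_1]$ in state $s$ contributes
$\theta_s (e^{-\alpha(T-t_1)} - e^{-\alpha(T-t_0)})$.

Two conventions close degrees of freedom the data cannot resolve:

* The **root state is pinned to the optimum of the root's regime** rather
  than estimated. On ultrametric trees with moderate $\alpha T$ the root
  term $x_0 e^{-\alpha T}$ is weak, and pinning keeps the parameter counts
  at $k = 3$ (OU1) and $k = 4$ (OUM), matching the "two optima" reading of
  the multi-optimum model.
* **OUM shares one $\alpha$ and one $\sigma^2$ across regimes**; only the
  optimum shifts. Regime-specific dynamics are a different model family and
  are out of scope.

Fitting profiles all location parameters ($\mu$, $x_0$, $\theta$s) by
generalized least squares, leaving a 1–2 dimensional bounded quasi-Newton
search over $\log \alpha$ and/or $\log \sigma^2$, multi-started on a
10-point log grid of $\alpha \in [10^{-4}, 100]$. Degenerate inputs
(constant traits, maps in which one regime never occurs along any lineage)
return fits flagged non-converged, which downstream consensus excludes per
map. Numerical notes: the OU covariance uses `expm1` so the $\alpha \to 0$
Brownian limit is accurate to $10^{-4}$ already at $\alpha = 10^{-8}$, and
the likelihood is validated against an independent dense multivariate-normal
computation to $10^{-8}$.

# Model comparison, half-life, and significance

Models are compared by AICc, $-2\ell + 2k + 2k(k+1)/(n-k-1)$. Across the
(default 100) stochastic maps the per-map AICc winner is recorded — ties
resolve toward fewer parameters — and the **consensus is the modal winner**;
the vote counts are retained so a 60/40 split is visible. The reported
$\Delta$AICc is the median across maps of (winner − runner-up); a magnitude
$\le 2$ classes the winner "among-best" (model equivalence), otherwise
"clear". Modal voting is the simplest faithful reading of consensus over
maps; mean-AICc aggregation is also computed by callers that want it.

Phylogenetic half-life is $t_{1/2} = \ln(2)/\alpha$, in mya because branch
lengths are in mya. Its uncertainty is assessed by bootstrap: each replicate
removes a random third of the species, refits the OU model (OU1, or OUM
where that is the best/among-best model, with a fresh stochastic map on the
pruned tree), and records $t_{1/2}$; significance uses the
$(\text{mean} - 1.64\,SD) > 0$ rule. Treatment effects on evolutionary
lability are estimated by an ML linear mixed model on $\log t_{1/2}$ with
treatment fixed (baseline Mild) and trait as a random intercept;
90% intervals come from bootstrapping over traits, so a contrast of
$\log(0.5) \approx -0.693$ reads as a 50% half-life reduction.

# Growth traits

Leaf-length series are summarized by a three-parameter logistic
$y(t) = ASYM / (1 + e^{(XMID - t)/scal})$ per plant, fitted by
`stats::SSlogis` self-starting least squares with a Levenberg–Marquardt
fallback from heuristic starts. $MGR = 1/scal$; $XMID$ is negated
($-XMID$) so larger values mean faster progression. Fits whose asymptote
exceeds three times the observed maximum are flagged non-converged
(monotone, non-saturating series carry no information about $ASYM$) and are
excluded from species means rather than imputed. The initial growth rate is
the OLS slope over the first 7 days — the window is a package default,
configurable, since no canonical definition exists. Stress tolerance is the
relative change (stress − mild)/mild, undefined where the mild estimate is
zero. Aggregation is strictly hierarchical — replicates → plant → species ×
treatment × round → species × treatment — with $SE = SD_{rounds}/\sqrt{n}$
feeding the evolutionary models.

# Phylogenetic mixed models

Treatment, mean-centered median elevation, and their interaction are fixed
effects; sowing round and a phylogenetic species effect (covariance
$\propto C$, scaled to unit height) are random. The model is fitted by
maximum likelihood: fixed effects and the residual variance are profiled
analytically and the variance ratios are optimized on the log scale, with
all linear algebra routed through determinant/Woodbury identities on
precomputed crossproducts, so one likelihood evaluation costs
$O(q^3)$ in the total random-effect rank $q$ rather than $O(n^3)$.
Intervals and significance come from a parametric bootstrap (default 500
draws; bootstrap refits warm-start at the fitted ratios). Bootstrap
datasets are generated at REML-estimated variance components while the
reported estimates stay ML: ML components are biased downward, and
generating at them makes nominal 90% intervals cover only ~83–87% under
the null, whereas REML generation restores ~85–90% (the REML criterion is
validated against `lme4` to $10^{-8}$). 90% percentile
intervals mirror a 90% credible-interval convention, and the
probability-of-direction analogue (largest fraction of draws on one side of
zero) maps onto tiers `(.)` > 95%, `*` > 97.5%, `**` > 99.5%, `***` >
99.95%. Responses are Gaussian after an identity, log, or logit link;
proportion-valued resistance scores are shrunk from the boundary by
$y' = (y(n-1) + 0.5)/n$ before the logit — a deliberate, documented
replacement of beta-likelihood machinery that preserves the inferential
contrasts at desk scale. The contribution of the phylogeny is judged by the
AICc difference between fits with and without the phylogenetic effect
(negative favours keeping it).

# Multivariate trade-off screen

The species × (trait, treatment) matrix is selectively $\log_{10}$
transformed, then centered and scaled with the sample (n−1) SD convention.
Collinear traits are removed by iterative VIF pruning at threshold 10:
regress each column on all others, drop the worst while the maximum VIF
exceeds 10; perfectly collinear columns have infinite VIF and fall first,
ties going to the earlier column so the outcome is deterministic and
row-order invariant. A two-group DAPC follows: PCA, retain the number of
components chosen by repeated stratified 10%-holdout cross-validation
(minimum mean squared assignment error, ties to highest success then fewer
PCs), a linear discriminant on the scores, and contributions defined as the
squared entries of the discriminant axis mapped back to variable space
(normalized to sum 1, computed per axis with the quantile recomputed from
the data at hand). Traits above the third quartile of contributions are
carried into a pairwise-complete Pearson correlation screen with two-sided
$t$-based p-values and conventional stars; species with missing values are
excluded from the DAPC and counted.

# The synthetic-data generator

The generator emulates the full study: a pure-birth tree rescaled to a
configurable height (default 30 mya — an arbitrary but explicit calibration;
all rates are interpretable relative to it, and the OU likelihood is
invariant under joint rescaling of time and $(\alpha, \sigma^2)$); a
forward-simulated regime history with default switching rates 0.030/0.910
per mya (strongly asymmetric, with stationary low-state fraction
$0.910/0.940 \approx 0.968$); species elevations drawn uniformly within
400–1500 m (low) and 1500–2800 m (high); and a common-garden design of
100 taxa × 2 populations × 3 maternal lines × 3 temperature treatments =
1800 individuals, one maternal line per block, lines alternating between
two sowing rounds. Asymptotic size evolves under OUM with treatment-specific
regime optima of realistic magnitude (frost 57.15/30.44, mild 64.85/38.72,
heat 70.16/23.65 mm for low/high species) — these serve as plausible inputs,
never as ground truth to be re-derived; growth midpoint and scale evolve
under OU1; maternal-line, round, and residual noise are Gaussian with
configurable SDs; resistance scores are logit-normal in (0, 1).

What the generator does *not* emulate: germination failure and unbalanced
species coverage across rounds, block-position effects, non-Gaussian trait
noise, correlated evolution among traits, and diversified (birth–death)
trees. Passing simulation tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to every feature of real
common-garden data.

## Validation-study conditions

Two deliberate conditioning choices define the recovery studies:

* **Regime representation.** Comparative studies of elevational divergence
  sample both elevational classes by design, so validation histories are
  redrawn until the minority regime holds a minimum tip fraction
  (`simulate_study_history`).
* **Identifiability of optima.** Under the strongly asymmetric default
  rates, high-regime episodes last on average $1/0.910 \approx 1.1$ mya, so
  with $\alpha = 0.2$ a tip moves only $\approx 20\%$ of the way toward
  $\theta_{HIGH}$ and the high optimum is unidentifiable at any sample
  size. The optimum-recovery study therefore uses a symmetric history
  ($q = 0.05/0.05$, minority fraction $\ge 0.2$), where residence times are
  long and recovery is achievable; the asymmetric rates remain the default
  for everything that concerns the switching process itself.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes chosen to keep a full run on one core comfortable while leaving
Monte-Carlo error well inside the asserted bands: 100-tip trees with 50
(tests) or 25 (script) trait replicates for model-selection studies, 10,000
stochastic maps on a 5-tip tree for sampler calibration, 100 null datasets
of 40 species with 200-draw bootstraps for interval coverage, 500 noisy
series for growth recovery, and 1000 null replicates for correlation
calibration. The bootstrap default for half-life work is 200 in examples
(the analysis-scale convention is 10,000, available by argument).

# Known limitations

* Regime-specific $\alpha$ or $\sigma^2$ for OU models, >2 regimes, hidden
  rates, and correlated multi-trait likelihoods are out of scope.
* Optimum estimates conditional on *sampled* regime maps are attenuated
  relative to fits on the true history whenever the reconstruction is
  uncertain (moderate symmetric switching rates leave ~30% of tree time
  ambiguous): misplaced regime segments push $\hat\alpha$ down and the
  profiled optima outward or together. The consensus label is far more
  robust than the per-map parameter values.
* Null rates of selecting the multi-optimum model over the single-optimum
  one exceed the nominal chi-square(1) tail when $\alpha T$ is large and
  $\alpha$ weakly identified (~25% instead of ~12% on 40-tip trees in
  calibration runs); consensus conclusions should lean on well-separated
  optima, not borderline AICc margins.
* The high→low switching rate is weakly identified from tip data alone when
  the high regime is short-lived; point estimates can be off by a factor of
  several even on 200-tip trees (the likelihood surface, cross-checked
  against an independent implementation, is genuinely flat).
* AICc consensus across maps uses modal voting; when map-to-map variation
  is large the vote table, not just the label, should be inspected.
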