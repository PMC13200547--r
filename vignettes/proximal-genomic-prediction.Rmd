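---
title: "Sparse proximal-gradient models for genomic prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse proximal-gradient models for genomic prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoprox)
```

## The problem

Genomic prediction regresses a quantitative trait on genome-wide marker
dosages with far more markers than individuals (p >> n). Deep residual
networks can capture non-linear genotype-phenotype relationships but
overfit badly in this regime; weight decay and dropout are usually too weak.
This package trains 1D residual networks (and a matching linear baseline)
under explicit sparsity-inducing regularization,

$$\min_\theta \; F(\theta) = L(\theta) + \lambda R(\theta),$$

where $L$ is the mean-squared empirical loss and $R$ is one of twelve
penalties, by inserting the proximal operator of $R$ directly into a
stochastic adaptive gradient loop. Because the proximal step is exact, the
thresholding penalties produce weights that are *bit-exact* zeros, so model
sparsity is a well-defined, measurable quantity rather than an epsilon
convention.

## Penalties and their proximal operators

`penalty_spec()` supports the power family $L_q$ with
$q \in \{0, \tfrac12, \tfrac23, 1, \tfrac43, \tfrac32, 2, 3, 4, \infty\}$
plus SCAD ($a > 2$, default 3.7) and MCP ($\gamma > 1$, default 3.0) — the
field-standard shape defaults; neither changes qualitatively over their
usual ranges. All proximal operators use the canonical convention
$\mathrm{prox}_f(z) = \arg\min_x f(x) + \tfrac12 (x-z)^2$; a formulation
that drops the $\tfrac12$ is equivalent after $\lambda \to \lambda/2$, and
the $\tfrac12$ form matches the mapping actually applied inside the
optimizer.

Closed forms: soft thresholding ($L_1$), hard thresholding at
$\sqrt{2\lambda}$ ($L_0$), multiplicative shrinkage $z/(1+2\lambda)$
($L_2$), half thresholding via the trigonometric largest root of
$u^3 - |z|u + \lambda/2 = 0$ ($L_{1/2}$), the quartic-resolvent form for
$L_{2/3}$, quadratic/cubic root formulas for $q \in \{4/3, 3/2, 3\}$, a
safeguarded Newton bracket on $[0, |z|]$ (tolerance $10^{-12}$) for $q = 4$,
and piecewise candidate evaluation for SCAD/MCP at arbitrary metric scale.
The max-norm prox is solved exactly by sorting the $|z_i|$ breakpoints of
the piecewise-linear optimality condition; in the unweighted case it
satisfies the Moreau identity with projection onto the $\lambda$-radius
$L_1$ ball, which the test suite verifies to $10^{-10}$.

Two conventions for the non-convex penalties:

* **Tie-breaking.** At the threshold where the zero and nonzero local
  minimizers have equal objective, the prox returns 0 — prefer sparsity; the
  event has measure zero under any continuous input distribution.
* **Oracle arbitration.** Every closed form is validated against
  `prox_oracle_scalar()`, an independent dense-grid search with
  golden-section refinement, over thousands of seeded random
  $(z, \lambda, s)$ triples. The oracle, not the algebra, is the arbiter of
  correctness.

## The optimizer

`opt_step()` implements a diagonally preconditioned proximal update:
first moment $m_t = \beta_1 m_{t-1} + (1-\beta_1) g_t$, second moment
$v_t = \beta_2 v_{t-1} + (1-\beta_2) g_t^2$, preconditioner
$C_t = \sqrt{\hat v_t}$, gradient half-step
$u = \theta_t - \alpha\, \hat m_t / (C_t + \delta)$, followed by the prox of
$\alpha\lambda R$ in the metric $(C_t+\delta)$ — which for separable
penalties decomposes coordinatewise with effective scale
$\alpha/(c_i + \delta)$, and for the max-norm is solved jointly per
parameter array with metric weights $(c_i+\delta)/\alpha$.

Design points:

* The second-moment recursion is kept on the squared scale ($v_t$) with
  $C_t = \sqrt{v_t}$, the Adam-lineage convention; a recursion that nests
  the previous $C_{t-1}$ inside the square root is dimensionally mixed and
  coincides with ours at $t = 1$.
* Adam-style bias correction is on by default (`bias_correction = FALSE`
  reproduces the raw update exactly; the first-step hand values for both
  variants are frozen in the tests).
* Momentum defaults: $\beta_1 = 0.1$, $\beta_2 = 0.999$ for proximal
  training; the unregularized baseline uses plain Adam defaults
  ($\beta_1 = 0.9$, $\epsilon = 10^{-8}$). The learning rate is constant.
* Only convolution and fully connected *weight* arrays are penalized;
  biases and batch-normalization parameters are excluded from the prox and
  from sparsity counts, the standard practice for sparse network training.

## Network architecture

`depth_to_plan()` fixes a depth accounting convention: nominal depth equals
stem convolutions + (convolutions per block x blocks) + 1 for the output
layer; projection shortcuts are not counted. Basic blocks (2 convolutions)
serve depths up to 18, bottlenecks (3 convolutions, x4 expansion) beyond.
Odd depths are reconciled by extra stem convolutions — e.g. depth 15 = 2
stems + 6 basic blocks + head. Blocks spread over at most 4 stages, earlier
stages taking the remainder; each stage transition doubles channels
(base width 16) and strides by 2.

Residual blocks follow the identity form $X_{l+1} = \mathrm{shortcut}(X_l) +
E(X_l)$ with $E$ = conv-BN-ReLU-conv-BN and a projected (1x1 conv + BN)
shortcut exactly when shapes change; with the branch weights zeroed a block
is an exact identity, which the tests check. The default kernel size is 1,
following the 1x1-convolution block design; note that 1x1 convolutions mix
channels but not positions, so with global average pooling before the head
the network computes a (nearly) position-invariant function of the marker
sequence. `kernel_size = 3` and the bottleneck middle kernel are exposed
for position-mixing variants. This positional limitation is a property of
the architecture family itself, and is one reason the regularized variants'
advantage on our synthetic data manifests mostly as variance control
(shrinking toward a constant predictor) rather than signal recovery — a
caveat to keep in mind when extrapolating synthetic results to real data.

Forward/backward passes are hand-written array code (one BLAS call per 1x1
convolution, fused compiled kernels for batch normalization and ReLU) and
are verified against numerical differentiation to $10^{-4}$ in the test
suite for both block kinds.

## The linear baseline

`pgdlm()` is full-batch proximal gradient (ISTA) on
$\tfrac{1}{2n}\|y - X\theta - b\|^2 + \mathrm{pen}_\lambda(\theta)$ with the
same twelve penalties, an unpenalized intercept minimized exactly each
epoch, and `step = "auto"` set to $1/\hat L$ with
$\hat L = \sigma_{\max}^2(X)/n$ from power iteration. The $1/(2n)$ loss
scaling matches the mini-batch mean losses of the network models, so a
given $\lambda$ means the same thing in both. For convex penalties the
objective trace is non-increasing; on identity designs the converged
solution equals the penalty's prox at metric scale $n$, checked against the
grid oracle to $10^{-6}$.

### Support recovery

`recover_support()` tunes $\lambda$ over a 10-point logarithmic grid from
$\lambda_{\max} = \max_j |X^\top y|/n$ downward, scoring each candidate by
validation MSE **of the least-squares refit on the candidate support**
(relaxed tuning). This choice is deliberate: validation error of the
shrunken fit itself is minimized at a smaller $\lambda$ that systematically
over-selects (prediction-optimal and selection-optimal regularization
differ; we observe median support-F1 around 0.3-0.6 at prediction-optimal
$\lambda$, for this implementation and for an independent coordinate-descent
lasso alike), while the debiased refit makes validation error reflect
support quality. Under the refit convention the simulated benchmark
(n = 400, p = 2000, 10 causal markers of effect ±1, noise sd 0.5) is
recovered with F1 = 1 in the acceptance runs.

## Metrics

* **MSE** — plain mean of squared residuals.
* **dCor** — sample distance correlation, biased V-statistic form (the
  common default; the bias-corrected estimator is out of scope), with the
  convention dCor = 0 for constant inputs. Affine dependence gives 1;
  independent draws at n = 1000 stay below 0.1.
* **Exact Wilcoxon signed-rank** — zero differences dropped (Wilcoxon's
  original treatment), mid-ranks for ties, and an *exact* two-sided p-value
  from the full $2^n$ sign-assignment null distribution (computed by
  generating-function convolution; n of 25 or fewer). With the 10-repetition
  protocol, normal approximations are inappropriate; the exact tail for 10
  uniformly positive differences is $2/1024 \approx 0.00195$.
* **Sparsity** — the share of penalized weights that are exactly zero.
  Reports headline "sparsity (%)" as the *percentage of weights set to
  zero* (higher = sparser); the complementary nonzero fraction
  $\|w\|_0/d$ is also exposed in the `sparsity()` report since both
  conventions circulate.

## The synthetic-data generator

`simulate_genotypes()` draws per-marker MAFs uniformly (default range
0.05-0.5), then thresholds two latent AR(1) Gaussian haplotype chains
(adjacent-marker correlation `ld_rho`, default 0.3) at the MAF quantile and
sums them into dosages {0,1,2}. This one-parameter linkage-disequilibrium
model reproduces the two first-order features that matter for these methods
— realistic allele-frequency spectra and adjacent-marker correlation — and
nothing else: there is no population structure, kinship, dominance, or
long-range LD, so passing tests say nothing about robustness to
stratification in real cohorts.

`simulate_phenotype()` assigns `k_causal` markers additive effects (normal,
or ±`effect_sd` Rademacher), optionally adds pairwise products of
standardized causal dosages (epistasis), and scales Gaussian noise from the
*realized* genetic variance so that var(g)/var(y) hits the target
heritability; phenotypes are returned standardized, mirroring common
preprocessing of the real datasets this emulates. Realized h² lands within
±0.05 of target at n = 2000. The generating truth (causal set, effects,
genetic values, realized h²) is returned for recovery tests. Everything is
bit-reproducible from the configuration seed.

## Protocol

`make_cv_plan()` holds out 20% of individuals per repetition (10
repetitions, seeds `master_seed + r`) and partitions the rest into 5 folds
— always splitting individuals, never markers — so every method and penalty
sees byte-identical partitions. `fit_standardizer()` learns marker means/sds
on the training split only (leakage-safe reading of "normalized prior to
training") and applies them to validation and test splits; the phenotype is
standardized the same way.

`search_hyperparams()` searches learning rate ($[10^{-4}, 10^{-2}]$,
log-uniform), $\lambda$ ($[10^{-3}, 10^{2}]$, log-uniform) and batch size
({32, 64, 128}) for at most 100 evaluations, stopping early after 5
consecutive evaluations improving by less than $10^{-5}$ — whichever rule
fires first. The native backend is seeded random search; Bayesian
optimization backends (e.g. a tree-structured Parzen estimator) plug in as
a function with the same contract, keeping the search strategy orthogonal
to the method itself. Failed evaluations score $+\infty$ and the search
continues.

`run_experiment()` composes all of the above and emits per-repetition
results, aggregated mean (sd) tables, and exact Wilcoxon comparisons of
each regularized variant against the unregularized baseline on the paired
per-repetition test MSEs.

## Problem sizes used by the shipped checks

The acceptance checks run the full pipeline at desk scale: prox-oracle
sweeps of 1000 random cases per penalty; the optimizer-vs-lasso comparison
at n = 50, p = 100; support recovery at n = 400, p = 2000 over 5 seeds; and
the network comparison at n = 600, p = 500, k = 20, h² = 0.5 with depth-5
networks, 15 epochs, batch 128, over 10 seeds, with a single matched
$\lambda$ tuned for the half-norm penalty on the first repetition's
validation split over the grid {0.03, 0.1, 0.3, 1} and shared by all three
penalties across seeds, so the sparsity comparison is at identical penalty
strength. These sizes were chosen
as the smallest at which the directional claims (regularized ≤
unregularized test MSE; sparsity ordering $L_{1/2} \ge L_1 \ge L_2$) are
stable, and are stated here so that results are interpreted at the scale
they were computed.

## Known limitations

* With 1x1 kernels and global average pooling, the networks cannot express
  marker-position-specific effects (see above); the synthetic benchmark
  therefore measures regularization behavior, not architecture-driven
  signal recovery.
* The exact Wilcoxon enumeration is limited to 25 nonzero pairs, which
  covers the 10-repetition protocol with a wide margin.
* `pgdlm()` fits one $\lambda$ at a time (no warm-started paths);
  `recover_support()` simply refits along its grid.
* The simulator omits population structure and dominance by design.
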