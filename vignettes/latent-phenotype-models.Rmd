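---
title: "Latent phenotype models for MAVE data: methods and design"
author: "latentmave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent phenotype models for MAVE data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentmave)
```

## The model

Multiplex assays of variant effect (MAVEs) — deep mutational scans,
massively parallel reporter and splicing assays, sort-seq experiments —
measure a phenotype-correlated readout for thousands to millions of
sequence variants at once. The readout is rarely the biological quantity
of interest: selection experiments saturate, fluorescence sorting bins
coarsely, enrichment ratios compress. `latentmave` models every such
dataset in two stages:

1. a deterministic **genotype-phenotype (G-P) map** assigns each
   fixed-length sequence $x$ a scalar latent phenotype
   $\phi(x;\theta)$, and
2. a stochastic **measurement process** $p(y\mid\phi)$ describes how the
   assay reads that phenotype out.

Both stages are inferred jointly by maximizing an L2-regularized
likelihood. For continuous measurements (global epistasis, GE,
regression) the measurement process factors into a monotonic
nonlinearity $\hat y = g(\phi) = a + \sum_k b_k \tanh(c_k\phi + d_k)$
(with $b_k, c_k \ge 0$ enforcing monotonicity) and a noise model
$p(y\mid\hat y)$ that may be Gaussian, Cauchy, skewed-t (Jones–Faddy
form, with the mode pinned at $\hat y$), or an "empirical" Gaussian with
user-supplied per-measurement standard errors. Each noise-model
parameter is an exponentiated K-order polynomial in $\hat y$, so
heteroscedastic noise costs only K extra coefficients per parameter. For
binned measurements the measurement-process-agnostic (MPA) model puts a
one-hidden-layer tanh network with a softmax output on top of $\phi$:
$p(y\mid\phi) \propto \exp[a_y + \sum_k b_{yk}\tanh(c_{yk}\phi+d_{yk})]$.

Built-in G-P maps are additive, nearest-neighbor and all-pairs pairwise
(linear in one-hot and pair-product features), a multilayer-perceptron
"black box", and a custom-map contract used by the thermodynamic models
(three-state folding/binding and four-state promoter-activation
occupancy built on energy matrices).

## Identifiability: gauge and diffeomorphic modes

A G-P map's parameters are only interpretable after removing two kinds
of non-identifiable freedom. *Diffeomorphic* modes — affine changes of
$\phi$ absorbed by the measurement process — are fixed after training by
standardizing the training-set $\phi$ to mean 0 and standard deviation 1
while transforming $g$ (or the MPA input) so every prediction
$p(y\mid x)$ is bit-for-bit unchanged. *Gauge* modes — directions that
leave $\phi$ itself unchanged — are fixed with the hierarchical gauge:
relative to a position-factorized sequence distribution $p_{l:c}$
(uniform, empirical, or wildtype one-hot), constants are pushed into
$\theta_0$, additive marginals to zero, and interaction blocks to zero
$p$-weighted marginals in both positions. This makes the lower-order
terms carry the largest possible share of the variance of $\phi$ under
$p$; the package verifies $\phi$-preservation, idempotence and the
variance property in its test suite by brute-force enumeration on small
alphabets. Custom maps are never gauge-fixed automatically — their gauge
freedoms depend on the model's structure (energy matrices, for example,
have their own), and silently "fixing" the wrong modes would corrupt
them.

## Training

Parameters are fit by minibatch Adam (default learning rate $10^{-3}$,
batch 100, early stopping on validation loss with patience 30) on
$-\sum_n \ln p(y_n\mid\phi_n) + \lambda_\theta\|\theta\|^2 +
\lambda_\eta\|\eta\|^2$, with defaults $\lambda_\theta = 10^{-3}$ and
$\lambda_\eta = 10^{-1}$; the penalty includes all measurement
parameters, offsets included. Gradients are analytic throughout the G-P
maps (design matrices, MLP backpropagation, Boltzmann-occupancy
derivatives for thermodynamic maps) and through the GE nonlinearity and
MPA softmax; only the handful of noise-model polynomial coefficients,
and the per-datum derivative $\partial \ln p/\partial\hat y$, use
vectorized central differences — at most $3(K+1)$ extra density
evaluations per batch, which keeps the skewed-t family exact-enough
without hand-deriving its gradient. Monotonicity constraints are
enforced by optimizing unconstrained surrogates mapped through a
softplus.

Initialization matters more than the optimizer here. $\theta$ starts
from a ridge regression of the (standardized) measurements on the
sequence features; the nonlinearity starts from an isotonic regression
of $y$ on the initial $\phi$, converted into nonnegative tanh-node
amplitudes from the curve's increments; noise scales start from the
residual spread. This puts the optimizer inside the right basin; with a
clipped least-squares initialization (our first attempt) half the node
amplitudes came out negative and training from the repaired state took
an order of magnitude longer. Data are split 90:5:5 (train:validation:
test) by seeded shuffling by default; every stochastic step — split,
initialization, minibatch order, simulation — derives from the single
`seed` argument, so refits are bit-reproducible.

Libraries containing only single-mutation variants cannot constrain the
shape of $g$: single-mutant effects are confounded with any monotone
transformation. The package detects this (reference = most frequent
sequence, ties broken by first occurrence; user-overridable) and
restricts such data to an additive map with a linear nonlinearity,
heteroscedastic noise still allowed. A few hundred double mutants lift
the restriction, and the acceptance checks demonstrate that ~500 random
doubles recover the same nonlinearity as a 5000-double library.

## Information metrics

Model performance is reported in bits. *Variational information*
$I_{var} = H[y] - (\log_2 e/N)\,L_{like}$ scores the full model;
*predictive information* $I_{pre} = I[y;\phi]$ scores the G-P map alone
(it ignores the measurement process entirely); *intrinsic information*
$I_{int} = I[x;y]$ bounds what any map could achieve. On held-out data
$I_{var} \le I_{pre} \le I_{int}$ up to estimator error. Entropies use
the Kozachenko–Leonenko kNN estimator and mutual information the KSG
(algorithm 1) estimator with Chebyshev balls, $k = 5$ by default, with
O(N²) C++ kernels that are exact (no approximate neighbor search).
Duplicate values are broken with uniform jitter of $10^{-10}\times$ the
data range. Uncertainties come from R = 25 random half-samples,
$\delta E = \mathrm{std}(\{E_r\})/\sqrt 2$ (bootstrap resampling biases
kNN entropies and is deliberately not offered). Negative MI estimates
are floored at zero in reports, with the raw value kept as an attribute.

Two caveats are worth knowing. KSG is biased downward for strongly
dependent pairs at small n, so a near-perfect model evaluated on a few
hundred test points can show $I_{var}$ slightly above $I_{pre}$; the
inequality is therefore always checked within two joint standard
errors. And for discrete $y$ the decomposition
$I[y;\phi] = H[\phi] - \sum_y p(y)H_y[\phi]$ degrades when many reads
share identical $\phi$ (count-matrix data expanded to reads): the
per-bin kNN distances jump from the tie scale to the between-sequence
scale. Evaluate $I_{pre}$ for MPA models on pair-mode test data (one
read per sequence) where possible. The count-based upper bound on
$I_{int}$ (Poisson error propagation through a Gaussian conditional
entropy) is an upper reference only: it diverges as counts grow and is
unreliable for over-dispersed counts. A local-nonuniformity correction
for KSG is exposed as a flag but unimplemented — it is costly and not
needed at the scales the package targets.

## Simulation and parameter uncertainties

Every model doubles as a simulator: GE models sample the noise model at
$g(\phi)$, MPA models sample bins (or per-sequence multinomial read
counts). Parameter uncertainties use the parametric bootstrap: the
trained model is treated as ground truth, R datasets are simulated with
the sequences held fixed, each is refit with the same hyperparameters —
initialized at the trained parameters, which is both faithful to the
local-curvature interpretation of the parametric bootstrap and much
faster than cold starts — gauge-fixed identically, and
$\delta\theta_k = \mathrm{std}(\theta_k^{(r)})$. Black-box maps are
refused: per-weight uncertainties of an overparameterized network mean
nothing. Additive effects of (position, character) pairs never seen in
training are reported as `NA`, never as 0, and predictions touching them
are flagged.

## Thermodynamic maps

The two built-in biophysical maps follow standard quasi-equilibrium
Boltzmann form, $\phi = \sum_{s\in\text{readout}} e^{-\beta G_s} /
\sum_s e^{-\beta G_s}$ with a log-sum-exp guard, with state energies
assembled from additive energy matrices (kcal/mol) over footprints plus
scalar interaction terms; $\beta$ is fixed at $1/0.593$ mol/kcal
(≈300 K) and recorded with the model. Ligand and protein concentrations
are absorbed into binding offsets rather than modeled separately. For
display, the uniform hierarchical gauge can be applied to each energy
matrix independently.

## What the simulations do and do not show

The generator draws sequences uniformly (or as mutagenized wildtypes or
single/double-mutant libraries), with measurement noise exactly from the
assumed families. Real MAVE data add things the tests do not emulate:
over-dispersed and correlated read counts, library composition bias,
epistasis beyond the assumed order, replicate batch effects. Passing the
recovery checks therefore shows the inference machinery is correct and
well-conditioned under its own assumptions — not that any particular
experimental dataset satisfies them. Problem sizes used by the packaged
checks (n = 5000 for recovery, n = 2000 per draw for the information
inequality, 1000–1500 for the thermodynamic recovery) were chosen as the
smallest at which the estimators' sampling error is comfortably below
the tolerances being asserted. When two fitted nonlinearity curves are
compared (the double-mutant deconvolution check), their latent axes are
aligned by moment matching and the comparison runs over the central 90%
of the data-covered range: the extreme order statistics of a noisily
estimated $\phi$ axis suffer a winner's-curse displacement that makes
well-recovered curves look divergent at the 1% tails.

## Numerical choices

Log-density exponents for heteroscedastic scales are clipped at ±30;
zero-probability observations contribute a log-density of −690 with a
warning rather than an infinite loss; skew-t quantiles go through
`qbeta` (inverse regularized incomplete beta, accurate to ~1e-10);
degenerate G-P maps (zero variance in training $\phi$) abort the
diffeomorphic fix with an error; bin labels must be contiguous integers
from 0 (`binsToCounts`/`countsToBins` convert representations and the
two likelihood forms agree exactly). Case is normalized to upper case;
U and T are *not* interconverted — an RNA sequence against a DNA
alphabet is an error, because silent conversion hides data mix-ups.
Variable-length input is rejected; pad with a custom alphabet if needed.
Feature order is row-major by position then alphabet, fixed so exported
parameter files are portable. Positions are 0-based everywhere.

## A worked example

```{r example, eval = FALSE}
library(latentmave)
set.seed(7)
dna <- builtinAlphabet("dna")
truth <- latentModel(
  additiveGPMap(8, dna, thetaLC = matrix(rnorm(32), 8, 4)),
  geMeasurement(geNonlinearity(2, 2.5, 1.2, 0),
                skewTNoise(log(0.15), log(4), log(2))))
dat <- simulateDataset(truth, randomSequences(3000, 8, dna), seed = 1)
fit <- fitLatentModel(dat, "additive", noise = "skewt", seed = 2,
                      epochs = 200)
informationReport(fit, dat[fit@split$test])
exportParams(fit@gpmap)$additive  # tidy table for logo tools
```

## Limitations

One-dimensional latent phenotypes and scalar (or binned scalar)
measurements only; no multi-phenotype joint fits. No GPU or
hyperparameter search. MPA regression requires discrete bins. The CLI
(`inst/cli/mave.R`) is a thin wrapper over these functions for batch
use; the package API is the primary interface.
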