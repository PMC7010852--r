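---
title: "Methods: PU inductive matrix completion with heterogeneous feature fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PU inductive matrix completion with heterogeneous feature fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puimc)
```

## The problem

Known gene–disease associations are extremely sparse: in catalogues such as
OMIM most diseases have a single known causal gene and most genes have none,
and there is no catalogue of *negative* pairs at all. `puimc` treats
prioritization of candidate disease genes as completion of a sparse binary
association matrix $P \in \{0,1\}^{N_g \times N_d}$ under two assumptions:

1. **Functional similarity is informative.** Genes (or diseases) that sit in
   similar network neighborhoods, or have correlated measured features, tend
   to be involved in similar phenotypes. This motivates learning compact
   per-entity feature vectors from heterogeneous sources and modeling
   associations bilinearly through them.
2. **Unknown cells are mostly negative.** With thousands of genes per
   disease and a handful of true associations, an unobserved cell is far
   more likely unrelated than related. Unlabeled cells therefore enter the
   loss as weak negatives rather than being ignored — the
   positive–unlabeled (PU) treatment.

## The model

Each gene $i$ carries a feature vector $x_i \in \mathbb{R}^{f_g}$, each
disease $j$ a vector $y_j \in \mathbb{R}^{f_d}$. Associations are scored by
a bilinear form through a low-rank matrix $Z = GH^\top$ with
$G \in \mathbb{R}^{f_g \times k}$, $H \in \mathbb{R}^{f_d \times k}$:

$$\mathrm{score}(i, j) = x_i^\top G H^\top y_j .$$

The factors minimize

$$\sum_{(i,j)\in\Omega^+} \bigl(1 - x_i^\top G H^\top y_j\bigr)^2
  \;+\; \alpha \sum_{(i,j)\in\Omega^-} \bigl(x_i^\top G H^\top y_j\bigr)^2
  \;+\; \frac{\lambda}{2}\bigl(\lVert G\rVert_F^2 + \lVert H\rVert_F^2\bigr),$$

where $\Omega^+$ is the set of observed positives and $\Omega^-$ its full
complement. $\alpha < 1$ encodes the PU prior — known positives must weigh
more than unknown cells — and the Frobenius penalty is the factored
surrogate of the trace norm of $Z$, the standard convex relaxation of a
low-rank constraint. Because the model is *inductive* (cells are scored
through features, not through matrix indices), genes and diseases absent
from training still receive predictions from their feature vectors alone.

`fit_puimc()` alternates between the two convex subproblems (fix $H$, solve
for $G$; fix $G$, solve for $H$). Each subproblem is a weighted ridge
regression whose normal operator splits into an $\alpha$-uniform background
term with Kronecker structure,
$\alpha\, X^\top X \, G\, (YH)^\top (YH) + \tfrac{\lambda}{2} G$, plus a
sparse correction supported on $\Omega^+$ with weight $1-\alpha$. We solve
it with conjugate gradient preconditioned by the exact inverse of the
background term (two small eigendecompositions), warm-started at the
current factor. CG monotonically decreases the subproblem quadratic, so the
outer objective history is non-increasing at every half-sweep; the tests
assert this on every seeded run.

**Defaults** (all overridable): rank $k = 200$, ridge $\lambda = 0.02$, PU
weight $\alpha = 0.0035$, at most 50 sweeps, stopping when the relative
objective decrease over a sweep drops below $10^{-5}$. Factor entries are
initialized i.i.d. Gaussian with sd `init_scale = 0.01` under a fixed seed:
alternating minimization is initialization-dependent, so the seed is part of
the model specification. $\alpha$ is applied per cell (the literal objective
above), not normalized by $|\Omega^-|$; rescaling $\alpha$ trades off
identically. Diseases with no positives are retained — all their cells sit
in $\Omega^-$.

## Feature learning

### Networks: restart random walk + spectral compression

A weighted similarity network with adjacency $A$ is row-normalized,
$B_{ij} = A_{ij} / \sum_{j'} A_{ij'}$ (`row_normalize()`). Rows of isolated
nodes are undefined; the default policy substitutes the uniform
distribution $1/n$, which keeps $B$ stochastic and the walk well mixed (a
`self_loop` alternative is provided). For each source node $i$,
`rwr_diffusion()` iterates

$$s^{t+1} = (1 - p_r)\, s^t B + p_r\, \delta_i$$

to its fixed point, the node's *diffusion state*. The restart probability
$p_r$ (default 0.05) balances local against global topology — as
$p_r \to 1$ the state collapses onto the source, a monotonicity the test
suite checks. Convergence is declared when the per-row L1 change falls
below `tol` ($10^{-6}$ by default, with a 1000-iteration cap; hitting the
cap warns and flags `converged = FALSE` rather than aborting). We fix the
orientation rows-as-sources throughout; for the symmetric similarity
networks used here the choice is immaterial, but it is documented because
it matters for asymmetric weights.

Multiple networks over the same node universe are each diffused separately
and their state matrices concatenated column-wise
(`fuse_diffusion_states()`), then embedded jointly — nodes missing from one
network should be added to it as isolated rows first. Diffusion states are
high-dimensional and noisy, so `svd_embed()` compresses the log-transformed
matrix

$$L = \log(S + Q) - \log(Q), \qquad Q_{ij} = \text{pseudo-count}
  \;(= 1/n \text{ by default}),$$

by truncated SVD: $X = U_d \Sigma_d^{1/2}$, $W = V_d \Sigma_d^{1/2}$, the
best rank-$d$ Frobenius approximation of $L$. The pseudo-count guards the
logarithm at zero and with the $1/n$ default maps exact zeros of $S$ to
exact zeros of $L$; for rectangular fused input we keep $1/n$ with $n$ the
row count and apply the same formulas unchanged — the SVD is well defined
for any shape. Singular-vector signs are fixed by forcing the
largest-magnitude entry of each left vector positive, so embeddings are
reproducible across platforms. The softmax (multinomial-logistic)
formulation of this embedding, with its KL-divergence objective, is kept as
a diagnostic only (`kl_objective()`): the relaxed SVD route is what the
package optimizes, and the diagnostic lets a user measure the relaxation
gap on their own data. No threshold is imposed on that gap. Default
embedding dimensions follow the full-scale setting: 600 for genes within an
800-dimensional gene feature vector, 100 for diseases within 200
(`default_run_config()`).

### Feature tables: denoising autoencoder

Dense noisy tables (expression profiles, cross-species phenotype
associations) are compressed by a feedforward denoising autoencoder
(`train_dae()`): inputs are min–max scaled per feature to $[0,1]$, corrupted
with additive Gaussian noise of sd `noise_factor` (default 0.2; a masking
variant is available), and the network is trained with Adam to reconstruct
the *clean* input under mean squared error. The norm in the reconstruction
loss is taken as the squared L2 norm, the choice consistent with Gaussian
corruption and sigmoid outputs. Only encoder widths are specified (the
full-scale reference stacks are 3000-800-300-100 for expression and 200-100
for phenotype blocks); the decoder mirrors them symmetrically with untied
weights. The Adam step size defaults to $10^{-3}$, batch size 150, 100
epochs. Training is bitwise reproducible given the config seed. In the
linear, zero-noise, single-code-layer limit the model is an affine rank-$d$
autoencoder, so its reconstruction error must approach the truncated-SVD
(PCA) bound — an identity the acceptance tests exercise.

## Evaluation

Per disease, all non-excluded genes are sorted by descending score (ties
broken by ascending gene index, so rankings are deterministic). By default
a disease's *training* positives are excluded from its candidate list when
evaluating held-out pairs, preventing known associations from occupying top
slots; passing `exclude = NULL` disables this for literal replication of
protocols that rank all genes.

* `recall_precision_at_r()`: a hidden positive is a true positive when its
  gene lands in the top $r$ (default 100) of its disease's list. False
  positives are the remaining top-$r$ slots over evaluated diseases, with
  $\min(r, \text{candidates})$ slots when a list is short.
* `percentile_rank()`: position $p$ in a list of $N$ candidates maps to
  $100\,(p-1)/(N-1)$ %, which reproduces the defining endpoints exactly —
  0% for the top, 100% for the bottom. The interior interpolation is our
  choice; only the endpoints are externally fixed.
* `mpr()`: mean over test diseases of each disease's mean percentile rank
  of hidden genes. Diseases with no hidden genes are skipped (their
  summand is undefined). Random scores calibrate at 50%.

Protocols: `threefold_split()` partitions the positive set into three
near-equal folds (each positive hidden exactly once across folds);
`single_association_holdout()` implements the new-gene / new-disease
settings by hiding the unique positive of every row (or column) with
exactly one association.

## The synthetic fixture generator

Real association catalogues and the networks behind them are not bundled;
`make_network()`, `make_side_features()` and `plant_associations()` generate
structurally matched stand-ins, and every generated artifact round-trips
through the plain-text readers/writers:

* **Networks** are planted-partition graphs: `n_modules` communities,
  within-module edge probability `p_in = 0.15`, between `p_out = 0.02` —
  modular, sparse, with hub-free degrees around 12 at the default size.
* **Feature tables** are low-rank-plus-noise: latent $n \times k_{true}$
  Gaussian factors times random loadings, noise sd 0.1 by default against
  unit-scale signal (10% noise, a realistic middle ground; raising it
  degrades recovery monotonically, which the tests check).
* **Associations** are the top `density` fraction of cells of a random
  rank-$k_{true}$ bilinear score built from the same latent factors; 20%
  of the positives are withheld as hidden ground truth, the rest train the
  model and all remaining cells are unlabeled — exactly the PU regime.

`parameter_recovery_experiment()` chains the whole pipeline on one such
instance: 300 genes x 120 diseases, two gene networks and one disease
network (module labels from k-means on the latent factors, so network
topology genuinely carries association signal through the diffusion
branch), 40/30-column feature tables, rank-10 truth at 5% density. The
desk-scale analogues of the full-scale dimensions are: 30-dim gene and
20-dim disease network embeddings, 10-dim autoencoder codes (so 40- and
30-dim side features after per-column standardization), completion rank
$k = 20$; model parameters keep the published defaults $\lambda = 0.02$,
$\alpha = 0.0035$, $p_r = 0.05$, $r = 100$. These sizes were chosen once as
the smallest instance that still exercises every stage meaningfully; the
experiment runs in seconds on one CPU.

Two caveats are deliberate and documented. First, the fixture plants
associations from the same model family the completion step fits — a
favorable case by design. Passing the recovery test demonstrates that the
implementation recovers a recoverable signal; it says nothing about whether
real gene–disease data satisfies the low-rank bilinear assumption. Second,
the generator does not emulate several features of real data: scale-free
degree distributions, batch structure in expression, literature-driven
ascertainment bias in which associations get discovered, and disease
comorbidity correlations. Negative results on real data therefore cannot be
ruled out by any test here.

## Numerical choices and degenerate inputs

* Power iteration converges linearly at rate $1 - p_r$; oracle-grade
  comparisons in the tests run it to `tol = 1e-12` against the closed form
  $s_i = p_r \delta_i (I - (1-p_r)B)^{-1}$.
* The inner CG runs to relative residual $10^{-12}$ (cap 500 iterations);
  with $\alpha = 1$ the preconditioner is the exact operator and CG
  terminates immediately, reproducing the closed-form ridge solution.
* Zero-sum adjacency rows, zero-variance feature columns (guarded in
  standardization), empty positive sets, all-equal planted scores, and
  single-candidate percentiles are all rejected or handled explicitly with
  informative errors.
* All randomness (initialization, corruption, shuffling, splits,
  generators) flows through per-call seeds; no function touches the global
  RNG state without restoring it.

## Limitations

The KL-optimizing variant of the network embedding is intentionally not
implemented (the SVD relaxation supersedes it; the KL value remains as a
diagnostic). Persistence uses plain-text formats (TSV, MatrixMarket, JSON,
YAML) throughout. Training the autoencoder at full-scale widths
(3000-800-300-100 over ~9,000 genes) is feasible but slow in pure R; the
implementation targets desk-scale widths, and the defaults in
`fixture_config()` reflect that.
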