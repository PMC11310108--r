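---
title: "Differentiable phylogenetics on the hyperboloid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable phylogenetics on the hyperboloid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypernj)
```

## The problem

Likelihood-based phylogenetics searches a discrete space of unrooted
bifurcating topologies, each carrying continuous branch lengths. Gradients are
not defined *between* topologies, so classical programs alternate discrete
rearrangements (NNI, SPR) with continuous optimization. `hypernj` instead
encodes a tree continuously: every taxon gets a location on a hyperboloid, and
the configuration of locations is decoded to a tree by neighbour joining. If
the decoder were differentiable, the whole map

$$(\mathbb{H}^d)^n \;\xrightarrow{\;d_\kappa\;}\; \mathbb{R}^{\binom{n}{2}}
\;\xrightarrow{\;\text{soft-NJ}\;}\; \mathcal{T}_n
\;\xrightarrow{\;L\;}\; \mathbb{R}$$

could be optimized by gradient ascent — over topologies and branch lengths at
once. Soft-NJ, a relaxation of neighbour joining built on soft-sort, is that
decoder.

## Hyperbolic geometry

We use the hyperboloid model
$\mathbb{H}^d = \{u \in \mathbb{R}^{d+1} : \langle u,u\rangle = -1\}$ with the
Lorentz product $\langle u,v\rangle = -u_0v_0 + \sum_{i\ge 1} u_iv_i$ and
distance

$$d_\kappa(u, v) = \frac{1}{\sqrt{-\kappa}}\,
\operatorname{arcosh}(-\langle u,v\rangle), \qquad \kappa < 0 .$$

Negative curvature matters because tree metrics embed into hyperbolic space
with low distortion, and the curvature magnitude tunes how "tree-like" the
geometry is. Numerical choices:

* Points are stored in ambient coordinates but **optimized in the tangent
  space at the origin**: unconstrained $z \in \mathbb{R}^d$ is lifted by
  $z_0 = \sqrt{1 + \lVert z\rVert^2}$ (`projectToHyperboloid`), so the
  constraint holds exactly by construction. An exponential-map wrapping was
  not implemented; the projection is cheap and standard.
* The `arcosh` argument is clamped below at $1 + 10^{-9}$: floating-point
  error can push $-\langle u,v\rangle$ slightly under 1 for near-coincident
  points, where the derivative diverges. The price is a distance floor of
  $\operatorname{arcosh}(1+10^{-9})/\sqrt{-\kappa} \approx 4.5\times
  10^{-5}/\sqrt{-\kappa}$, far below any biologically meaningful branch
  length.
* Curvature is parametrized as $\kappa = -e^{c}$ with $c$ unconstrained, so
  it stays strictly negative at every optimization step. Defaults: $d = 3$,
  initial $\kappa = -100$.

## Forward-mode dual numbers

No automatic-differentiation framework ships with this toolchain, and
differentiability is the entire point of the method, so the package carries
its own vectorised forward-mode engine (`dualSeed`, `dualValue`, `dualGrad`).
A dual holds a value vector and its Jacobian with respect to a fixed seed
vector; arithmetic, the `Math` group, indexing, concatenation and linear maps
propagate derivatives by the chain rule. An optional second order
(`order = 2`) propagates full Hessians; it is used exactly once, for the
gradient of the variational volume correction (below). Problem sizes here are
small (tens of seed variables), where forward mode is simpler and faster than
building a tape. One step is *not* dual-powered: derivatives of GTR
transition matrices with respect to the substitution parameters go through an
eigendecomposition, and are computed analytically as a Fréchet derivative
with divided differences, which is robust to degenerate eigenvalue spectra
(tied exchangeabilities — including the JC69 limit — are degenerate).

## Soft-NJ

Classical neighbour joining repeatedly joins the pair $(i,j)$ minimizing the
Studier–Keppler criterion
$Q_{ij} = (m-2)D_{ij} - \sum_k D_{ik} - \sum_k D_{jk}$, assigns branch
lengths by the Saitou–Nei formulas, and agglomerates
$D_{uk} = \tfrac12 (D_{ik} + D_{jk} - D_{ij})$. The discrete step is the
arg-min. Soft-NJ replaces it with the last row of a soft-sort permutation,
which for the minimum reduces to a temperature softmax
$\mathrm{softmax}(-Q^\flat/\eta)$ over the flattened upper triangle
(row-major). Ties are broken differentiably by a second soft-sort pass over
$P^l \cdot (2 - C)$, $C_i = \sum_{k \le i} P^l_k$, which selects the *first*
minimal entry in flattened order. The resulting row/column weight vectors are
used as weights everywhere an index would be used: the joined distance, the
row sums, and the agglomerated distance row are weighted combinations over
all active nodes. Consequently every branch length is a smooth function of
every entry of $D$, and gradients flow through the recursion even when the
temperature is so cold that the weights are numerically one-hot.

Bookkeeping (which rows to delete, how to assemble the tree) follows the
hard arg-max of the selection weights; values remain soft. Design choices:

* The flattened vector is built from the upper-triangle entries directly
  rather than masking the full matrix with a sentinel — equivalent, and it
  keeps softmax inputs on the scale of the data.
* Classical NJ can emit negative branch lengths; the likelihood and the
  priors need positive ones. Lengths pass through a smooth maximum with
  floor $\varepsilon = 10^{-6}$ (width $\sqrt{\delta} = 10^{-8}$), so the
  map stays $C^\infty$.
* Default temperature $\eta = 10^{-5}$: the decoder then agrees with an
  independent classical NJ implementation to RF distance 0 and branch
  lengths within $10^{-6}$ on random inputs (see the test suite). Gradient
  checks against finite differences are run at $\eta = 0.1$, where the
  relaxation is genuinely soft; at $\eta = 10^{-5}$ the selection weights
  saturate in floating point and their local gradient is zero, exactly as in
  the hard limit.

## Embedding initialization (hyperbolic MDS)

`embedDistances` places taxa so that pairwise hyperbolic distances
approximate a target matrix (usually tip–tip path distances of a start
tree). At zero stress the matrix $\cosh(\sqrt{-\kappa} D)$ would be the
Lorentz Gram matrix of the configuration, so its eigendecomposition supplies
a spectral initialization (dominant eigenvector → time coordinates, most
negative eigenvalues → spatial directions, radially rescaled onto the
sheet). The configuration is then refined by minimizing the unweighted
squared-error stress $\sum_{i<j} (d_\kappa(z_i,z_j) - D_{ij})^2$ with
chunked L-BFGS on the tangent coordinates, gradients from the dual engine.
Stress is non-convex, so the refinement restarts from a few seeded random
configurations (4 starts by default) and keeps the lowest-stress solution —
standard MDS practice. Checkpointed stress values are non-increasing by
construction and exposed as `attr(emb, "stressTrace")`. Weighted (relative)
stress was considered and not adopted; the plain squared error is the
simplest contract and the tests pin its behaviour.

Encoding is approximate: a tree whose shortest internal branch is below the
embedding's residual per-pair error (empirically $\sim 10^{-3}$–$10^{-2}$ at
$n = 8$, $d = 3$, $\kappa = -100$) may decode to a different resolution of
that split. This is a representational limit, not an optimizer artifact; the
round-trip acceptance check therefore requires 90% topology recovery over
seeded replicates rather than 100%.

## Likelihood and priors

`treeLogLikelihood` is Felsenstein pruning over compressed site patterns
(`phyDat`), with per-node rescaling for long alignments, written against the
dual API so branch lengths (and model parameters) can carry derivatives.
Gaps and ambiguity codes contribute their contrast rows, i.e. missing data.
JC69 uses the closed form; GTR builds the reversible generator from six
exchangeabilities and four frequencies (each a simplex via softmax when
optimized), normalizes to mean rate one, and exponentiates through the
symmetrized eigendecomposition.

Priors for Bayesian runs: the Gamma–Dirichlet tree prior — Gamma(1, 0.1) on
the total tree length, flat Dirichlet over branch proportions, with the
$(B-1)\log\Sigma\ell$ Jacobian of the reparametrization — plus flat
Dirichlets on the GTR simplexes; or, alternatively, i.i.d. Exp(10) branch
lengths with a uniform topology prior whose $-\log(2n-5)!!$ normalizer is
included (it matters for marginal-likelihood values, not for optimization)
and can be disabled.

## Maximum likelihood

`maximizeLikelihood` runs Adam (learning rate 0.1, decayed by
$(t+1)^{-1/2}$, 2000 epochs by default) on the composite objective, jointly
over tangent coordinates, the curvature parameter, and GTR parameters. The
start tree defaults to classical NJ on JC-corrected alignment distances, so
no external tool is needed. Because the stochastic soft decoding can wobble
near topology boundaries, the tree of the *best* epoch (not the last) is
returned; the running best is non-decreasing by construction, and the
initial value is the NJ-start objective, so the result can never fall below
its start. `refineBranchLengths` then polishes continuous parameters by
per-branch Brent sweeps that only accept improvements. Whether to optimize
GTR parameters from the first epoch or in stages was an open choice; they
are optimized jointly from epoch 0, which kept the implementation simple
and behaved well on fixtures.

## Variational inference

Each taxon gets a $K$-component mixture of diagonal ("mean-field")
multivariate normals in the tangent space, projected to the hyperboloid —
a distribution over configurations, hence over trees. Initialization
centres all components at the embedding, with standard deviation
$\sigma = \min_{i<j} D_{ij} / 20$ (a coefficient of variation of 20 against
the smallest tip–tip distance, taken globally — the per-taxon alternative
was rejected as under-determined) and equal weights $\alpha_k = 1/K$.

The objective is the stratified importance-weighted bound

$$\mathcal{L}_{\mathrm{SIWAE}} = \mathbb{E}\left[\log \frac1M \sum_{m=1}^M
\sum_{k=1}^K \alpha_k \frac{p(T_{mk}, D)}{q_k(T_{mk})}\right],$$

with one fresh reparametrized draw per $(m,k)$ pair per evaluation. With
$K = M = 1$ it reduces exactly to the one-sample ELBO estimator, which the
tests verify on shared draws. Mixture weights are optimized along with means
and scales; the curvature is held fixed during VI (exposed as a
configuration choice).

Because sampling passes through the dimension-changing map
$z \in \mathbb{R}^{nd} \mapsto \ell \in \mathbb{R}^{2n-3}$, the density on
tree space carries the generalized-Jacobian factor: $q(T) =
\mathcal{N}(z)\,\det(JJ^\top)^{-1/2}$ with $J$ the Jacobian of the
tangent-to-branch-length map, assembled exactly by the dual engine. Note
$JJ^\top$ (the Gram matrix over the $2n-3$-dimensional range), not
$J^\top J$, which is rank-deficient whenever $nd > 2n-3$ — for $d \ge 2$,
always. The correction applies the co-area volume factor along the range;
no exact dimension-preserving case of the decoder exists (that would need
$d = 2 - 3/n$), so the corrected density is the standard practical choice
rather than an exact pushforward. Configurations whose Jacobian loses rank
(e.g. effectively collinear embeddings, where a decoded branch pins at the
floor) are detected by an eigenvalue-ratio test ($\lambda_{\min} /
\lambda_{\max} < 10^{-10}$; healthy fixtures sit around $10^{-2}$,
degenerate ones at $10^{-18}$) and raise an error rather than returning a
meaningless density. The gradient of $\tfrac12 \log\det(JJ^\top)$ with
respect to the draw needs $\partial J/\partial z$ — second derivatives of
branch lengths — and is propagated exactly with second-order duals; the
remaining parameter gradients use the pathwise (reparametrization) identity,
under which the sampled component's mean gradient of its own entropy term
cancels analytically and the scale gradient contributes $+1$ per dimension.

`estimateMarginalLikelihood` implements importance sampling with the fitted
variational distribution as proposal,
$\hat p(D) = \frac1N \sum_i p(D\mid T_i)\,p(T_i)/q(T_i)$, averaged in log
space with a delta-method Monte-Carlo standard error
(`importanceEvidence`).

## What the synthetic data emulate — and what they do not

`simulateTree` draws topologies uniformly over unrooted binary labelled
topologies and branch lengths i.i.d. Exp(10) (mean 0.1
substitutions/site), matching the exponential prior used in the Bayesian
comparisons; `simulateAlignment` evolves i.i.d. sites forward under
JC69/GTR. Real alignments violate these assumptions in known ways: rate
heterogeneity across sites, indels, non-stationary composition, and
selection are all absent, and Exp(10) produces occasional internal branches
(below ~$10^{-3}$) that no method can resolve at moderate alignment
lengths. Passing the recovery checks therefore demonstrates the machinery
— encode, decode, differentiate, optimize — not performance on empirical
data, where likelihood surfaces are rougher and local optima (the
"geometric frustration" of embedded configurations) are the dominant
failure mode.

## Problem sizes and determinism

The test and acceptance workloads use small instances chosen as the
smallest sizes at which each property is meaningful: soft/hard NJ agreement
on 4–30 taxa, exhaustive-likelihood oracles at $n = 4$ (where summing
$4^{n-2}$ internal states is cheap), recovery experiments at $n = 6$–8 with
$L$ up to 2000, VI against a long-run Metropolis–Hastings oracle at
$n = 6$, $L = 300$, and reduced epoch counts (150–500) relative to the
2000-epoch default. Every stochastic entry point takes an explicit seed and
is reproducible bit-for-bit given it.

## Known limitations

* Full-rank covariances and normalizing flows for the variational family
  are not implemented (mean-field only), and curvature is not optimized in
  VI mode.
* No rate heterogeneity (Γ/invariant sites) or codon/amino-acid models.
* The decoder relaxes classical NJ only; soft variants of UPGMA/BioNJ/
  rapid-NJ are out of scope.
* Escaping local optima by re-embedding within a tree's pre-image is not
  implemented; the ML engine reports the best epoch of a single trajectory.
* Forward-mode AD scales linearly in the number of seed variables; the
  engines are intended for the tens-of-taxa regime, not hundreds.
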