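---
title: "Invariant measures from latent Markov models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariant measures from latent Markov models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentmarkov)
```

## The problem

Many questions about a dynamical system -- equilibrium populations of
molecular conformations, node importance in a network, coherent structures
in a flow -- reduce to one object: the *invariant measure* $\mu$ of a
Markov chain, the stationary probability vector satisfying
$\mu = \Lambda \mu$.  The classical data-driven route (Ulam's approach)
discretizes phase space into $n$ boxes, turns the observed trajectory into
a label sequence $X(0), X(\tau), \ldots$, estimates the column-stochastic
transfer operator $\Lambda_{ij} = P[X(s+\tau) = x(i) \mid X(s) = x(j)]$ by
the empirical frequency estimator
$\Lambda_{ij} = N_{ij} / \sum_i N_{ij}$ (the maximizer of the
log-likelihood $\mathcal L = \sum_{ij} N_{ij}\log\Lambda_{ij}$), and takes
the dominant eigenvector.

This route has three failure modes that this package addresses.  First,
the empirical estimator treats all source columns as statistically
independent; when transitions are jointly driven by an unobserved process
(a "latent" variable -- e.g. which attractor wing or which metastable
conformation the system currently occupies), the independent estimate is
biased.  Second, $n(n-1)$ free parameters overfit badly at realistic
sample sizes.  Third, one trajectory rarely samples every box well:
terminal states without return paths act as probability traps and can
absorb the entire estimated measure.

## The latent factorization

The package's core model factorizes the transfer operator through a
$K$-dimensional latent categorical process $\hat X$:

$$\pi(s+\tau) = \hat\lambda\,\hat\Gamma\,\pi(s),$$

where $\hat\Gamma$ ($K \times n$, column-stochastic) holds
$P[\hat X(s+\tau) = \hat x(k) \mid X(s) = x(j)]$ and $\hat\lambda$
($n \times K$, column-stochastic) holds
$P[X(s) = x(i) \mid \hat X(s) = \hat x(k)]$.  Both factors follow from
the law of total probability, so the model is exact Bayesian bookkeeping,
not an approximation scheme; what is restricted is only the latent
dimension $K$.  Unlike a hidden Markov model, no hidden path has to be
decoded: the factors relate consecutive *observed* states directly.

Two consequences make the factorization useful:

* **Limits.** $K = 1$ collapses the chain to a memoryless Bernoulli model
  whose "invariant measure" is the empirical probability density of the
  data; $K = n$ (with identity affiliation) reproduces the full Markov
  model and the empirical frequency estimator exactly.  Varying $K$ scans
  the whole model family in between.  Both limits are enforced by tests.
* **Reduced eigenproblem.** Powers of $\hat\lambda\hat\Gamma$ telescope:
  $(\hat\lambda\hat\Gamma)^N = \hat\lambda (\hat P_K)^{N-1} \hat\Gamma$
  with $\hat P_K = \hat\Gamma\hat\lambda$ a $K \times K$ column-stochastic
  *reduced transfer operator*.  If $\hat P_K$ has a unique stationary
  vector $\hat\mu_K$, the full invariant measure is the lift
  $\mu = \hat\lambda \hat\mu_K / \sum_k (\hat\mu_K)_k$.  The $n \times n$
  operator is never formed: the eigenproblem is $K \times K$, which is
  what makes the method scale quadratically rather than cubically in $n$
  for fixed $K$.  `latent_invariant_measure()` implements the lift;
  an acceptance-level test verifies it against full-space power iteration
  of $\hat\lambda\hat\Gamma$ to $10^{-10}$ in $\ell_1$ on random models.

## Fitting the factors

Both fitters maximize the same factorized likelihood
$\sum_{ij} N_{ij}\log((\hat\lambda\hat\Gamma)_{ij})$ over the observed
count entries only.

**Hard fitting (`fit_dbmr()`).** Each source state is assigned to exactly
one latent state (every $\hat\Gamma$ column is a 0/1 unit vector).  Given
assignments, the optimal emission matrix aggregates each cluster's count
columns; given $\hat\lambda$, each column moves to its best-scoring latent
state.  At the optimal emission the objective has the closed form
$\sum_k \sum_i A_k[i]\log(A_k[i]/T_k)$ -- a minimum-weighted-entropy
clustering of source columns -- which the test suite exploits as an
exhaustive oracle on small instances.  Both half-steps are exact
coordinate ascent, so the likelihood trace is monotone; this is asserted
on every fit in the suite.  Ties in the assignment step go to the lowest
latent index, making runs deterministic given the seed.  An emptied
cluster is repaired by donating the worst-scoring column from a cluster
with at least two members; because the donated column gets its own
optimal emission and the donor's remaining members re-optimize theirs,
the repair cannot decrease the recorded likelihood.

**Soft fitting (`fit_plsa()`).** Standard EM on the same objective (the
conditional form of probabilistic latent semantic analysis):
responsibilities $r[k \mid i,j] \propto \hat\lambda_{ik}\hat\Gamma_{kj}$
over the nonzero counts, then column-renormalized re-estimation from
responsibility-weighted counts.  Monotonicity is the usual EM guarantee.

**Initialization.** Likelihood surfaces of short-lag trajectories are
pathologically multimodal: when self-transition probability is high
(0.94 on the scaled Lorenz benchmark below), *any* assignment is close to
a fixed point of the coordinate ascent, because a column's own self-count
dominates its score wherever it currently sits.  Random restarts
therefore stall.  The package seeds one additional run from k-means on
the subdominant eigenvectors of the *reversibilized* empirical operator
(counts symmetrized as $(N + N^\top)/2$, whitened by the square root of
the total-count diagonal).  Symmetrization matters: strongly
non-reversible dynamics (rotation around an attractor lobe) give the raw
operator complex subdominant eigenvalues that mask the metastable modes,
whereas the symmetrized spectrum is real and its leading nontrivial
eigenvectors are constant on metastable sets.  The embedding is used
*only* as a seed; the likelihood being ascended remains the
non-reversible one.  On the Lorenz benchmark the spectral seed reaches a
likelihood no random restart attains and lands on the two-wing partition.
A deterministic `j mod K` seed provides a reproducibility floor and, for
$K = n$, the identity initialization that reproduces the empirical
estimator exactly.

## Model selection and uncertainty

A latent model has $K(n-1) + n(K-1)$ free parameters (column-stochastic
columns of $\hat\lambda$ and $\hat\Gamma$), which stays below the full
model's $n(n-1)$ exactly when $K < n^2/(2n-1)$; `max_latent_dim()`
computes this overfitting bound in exact integer arithmetic (100 for
$n = 200$).  The same parameter counting is used for hard models: the
formula is the one consistent with the bound, and it penalizes the
assignment structure conservatively.

`score_models()` ranks candidates by AIC or BIC with sample size
$M$ = number of observed transitions (not frames: the transitions are the
likelihood's independent units).  `cross_validate()` uses a contiguous
50/50 temporal split by default -- contiguous rather than shuffled to
respect serial dependence, 50/50 because the method needs both halves to
produce well-populated count matrices; validation probabilities are
floored at `reg_eps/n = 1e-6/n` and column-renormalized so a state first
visited in validation does not produce an infinite score, and training is
never regularized.  `bootstrap_measure()` resamples the $M$ observed
transition pairs with replacement (implemented as a multinomial redraw of
the nonzero counts -- the nonparametric bootstrap at the level of the
likelihood's independent units), refits, and reports per-state quantile
envelopes; replicates with a reducible reduced operator are dropped and
counted.  Resampling pairs rather than frames or blocks is a declared
design choice: the estimators consume counts, so pairs are the natural
exchangeable unit, and block variants are out of scope.

## Numerical choices and degenerate inputs

* Matrices are column-stochastic throughout, destination on rows; the
  normalization of the empirical estimator runs over the destination
  index for each fixed source column (the only reading that makes the
  operator column-stochastic).  State labels are 0-based.
* Grid boxes are half-open except the last bin of each dimension;
  linearization is row-major with the first coordinate slowest, so labels
  are portable.  Points outside the grid are clamped into boundary bins
  with a warning (trajectory bounding boxes estimated from data can be
  grazed by the data itself); the default grid pads the bounding box by
  1% to keep hull points interior.
* Zero-count source columns have no maximum-likelihood distribution; the
  estimator fills them (uniform by default, self-loop optionally) and
  flags them `undefined` so the pathology stays visible.
* Stationary vectors: `"eig"` uses a dense eigendecomposition up to
  `dense_limit` (600) and power iteration above it; `"power"` iterates
  the master equation from the uniform vector to an $\ell_1$ change below
  `tol = 1e-13`.  If eigenvalue 1 is multiple within $10^{-9}$ -- a
  reducible chain -- the functions refuse and name the closed
  communicating classes (computed from the strong components of the
  support graph) instead of silently returning one basin.  Small negative
  eigenvector entries (below $10^{-8}$ of the maximum in magnitude) are
  clipped and renormalized; larger ones are an error.
* Fitters: `tol = 1e-8` relative likelihood change, `max_iter = 500`,
  10 restarts by default; the hard fitter additionally stops at an exact
  assignment fixed point.  Scoring uses no flooring: an observed
  transition with probability zero scores $-\infty$, and a column whose
  every latent score is $-\infty$ falls back to the latent state with the
  largest count-support overlap rather than contaminating the likelihood
  with an $\epsilon$.
* The reduced eigenproblem is always dense ($K$ stays small by
  construction); the dominant vector is taken at the eigenvalue of
  maximal real part within $10^{-9}$ of 1.  Lifted eigenvectors are
  scaled so the largest-modulus entry is positive real; complex
  subdominant pairs are returned as-is with a warning, never silently
  realified.

## What the generators emulate

`simulate_lorenz()` integrates the Lorenz-63 system with fixed-step
classical fourth-order Runge-Kutta.  A fixed-step integrator (rather than
an adaptive one) keeps runs bit-reproducible across platforms; accuracy
is validated by step-halving (observed order $\ge 4$ on $[0,1]$), and at
$dt = 10^{-3}$ the wing decomposition is insensitive to integrator
details.  The default initial state $(1,1,1)$ with a $10^4$-step burn-in
lands on the attractor.  The benchmark configuration used in the tests
and the acceptance script -- $2\times10^5$ samples at $\tau = 10^{-3}$ on
a $20 \times 20 \times 20$ grid ($\sim$760 occupied boxes) -- is a
desk-scale rendition of the classical $100^3$-grid experiment; it
preserves the phenomenon under study (two metastable wings, strong
self-transition dominance, rotational non-reversibility) at a size where
the whole pipeline runs in seconds.

`sample_markov_chain()` and `sample_latent_chain()` realize the full and
factorized master equations generatively and are the bridge between
planted truth and estimated models.  `make_planted_model()` builds hard
models with tunable emission separation; at the default separation 0.9
and $2\times10^5$ transitions the planted partition is exactly
recoverable (adjusted Rand index 1), which the acceptance tests assert.
`block_chain_operator()` builds metastable block chains whose columns are
identical within a block -- exact latent aggregates with an analytic
second eigenvalue ($1 - \epsilon_1 - \epsilon_2$ in the two-block case)
used by the spectral tests, and the substrate of the absorbing-trap
scenario (a metastable main chain followed by a terminal one-way trap
holding 1% of frames, emulating an MD trajectory absorbed in a terminal
conformation).

What the generators do *not* emulate: continuous observation noise,
non-Markovian memory in the observed process beyond the planted latent
structure, state-space discretization error other than the Lorenz box
grid, and the feature-extraction/projection pipeline of real molecular
data.  Passing tests therefore demonstrate correctness of the estimators
on data that satisfies the model assumptions, and robustness to the
specific pathologies modeled (traps, short-lag self-dominance); they do
not certify behavior on arbitrary experimental time series.

## Problem sizes

The test and acceptance configurations were chosen as the smallest sizes
at which each phenomenon is stable: the Lorenz benchmark uses
$2\times10^5$ samples on a $20^3$ grid; recovery and selection studies
use $n = 60$, $K = 3$, $2\times10^5$ transitions; the trap scenario uses
30 states and $10^5$ frames; bootstrap calibration uses 40 replicates on
$2\times10^4$-frame chains.  All are fixed by seed and run in a few
minutes total.

## Known limitations

* The hard fitter is a local optimizer; the spectral seed removes the
  known stalling mode but global optimality is only verified exhaustively
  on small instances.
* Cross-validation materializes dense $n \times n$ prediction matrices
  and is intended for $n$ up to a few thousand.
* `"eig"` above `dense_limit` falls back to power iteration, whose
  convergence degrades as the spectral gap closes; strongly metastable
  operators are better analyzed through the latent route, which is the
  package's point.
* Reversible (detailed-balance-constrained) estimation, adaptive
  discretizations, and learned projections are out of scope.
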