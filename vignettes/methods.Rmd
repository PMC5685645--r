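---
title: "Learning mixed causal graphs from multivariate information: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning mixed causal graphs from multivariate information: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalmi)
```

## The problem

Genomic datasets — single-cell expression profiles, tumor mutation tables,
gene-property catalogues — are usually purely observational: no time series,
no controlled perturbations. `causalmi` learns a mixed graphical model over
categorical variables from such data. The learned graph can contain
undirected (`-`), directed (`->`) and bidirected (`<->`) edges; a bidirected
edge is the observational signature of an unobserved (latent) common cause,
which is the typical situation when, say, an unmeasured transcription factor
co-regulates two measured genes.

The method is constraint-based: starting from a complete graph it removes
every edge whose dependence can be explained away by other observed
variables, then orients what remains using the one pattern that
observational data can orient — the unshielded collider (v-structure)
`X -> Z <- Y` with `X` and `Y` non-adjacent.

## Information-theoretic machinery

All dependence measures are plug-in estimates on categorical contingency
tables, in nats. The mutual information decomposes relative to any set of
variables `{A_i}`:

    I(X;Y) = I(X;Y | {A_i}) + I(X;Y ; {A_i})

where the second term is the indirect contribution carried by `{A_i}`. The
conditional 3-point information

    I(X;Y;Z | {A}) = I(X;Y | {A}) - I(X;Y | {A} u {Z})

is the central quantity: positive when `Z` carries part of the X–Y
dependence (a contributor, e.g. a mediator or common cause), negative when
conditioning on `Z` *creates* dependence — collider evidence. Iterating the
decomposition telescopes exactly:

    I(X;Y) = I(X;Y;A1) + I(X;Y;A2|A1) + ... + I(X;Y | {A_i}_n)

The test suite verifies both identities to 1e-12 on a thousand random
tables; they hold by construction because every term in a decomposition is
computed on the same complete-case sample.

### Finite-size corrections

A plug-in conditional information is never exactly zero, so every
information value is paired with a complexity penalty `k` and decisions use
the shifted value `I' = I - k/n`. Two penalties are available:

* `bic`: `k = (r_X - 1)(r_Y - 1) prod_i r_Ai * log(n) / 2` — the classical
  BIC/MDL dimension count;
* `nml` (default): a decomposable normalized-maximum-likelihood regret. For
  the multinomial complexity `C(K, n)` we use the exact summation for the
  binary case up to `n = 1000`, an asymptotic expansion
  `C(2,n) ~ sqrt(n*pi/2) + 2/3 + sqrt(pi/2)/(12*sqrt(n))` above it
  (relative error < 1e-6 at the switch point, checked in the tests), and
  the linear recurrence `C(K,n) = C(K-1,n) + n/(K-2) C(K-2,n)` in log
  space for `K >= 3`, memoized. The per-test regret is symmetrized over X
  and Y: `k = (kX + kY)/2` with
  `kX = sum_u log C(r_X, n_u) - sum_v log C(r_X, n_v)` where `u` runs over
  the non-empty strata of `{A} x Y` and `v` over the strata of `{A}`.
  Empty strata contribute nothing, and the whole term is floored at zero.

The exact published form of this decomposable regret lives in supplementary
material we treat as unavailable; the symmetrized form above is this
package's documented choice. It reduces to the factorized regret on a bare
pair, is symmetric in X and Y by construction, and approaches the BIC
penalty as `n` grows on fixed dimensions (verified numerically in the test
suite over `n = 100` to `1e6`).

NML is the default because the BIC penalty over-prunes small datasets; the
asymptotic agreement means nothing is lost at large `n`.

### Missing data

Every contingency table is built on the complete cases of its own variable
tuple (`N_a <= N`), assuming data are missing completely at random; `N_a`
also drives the finite-size terms of that test. A conditional 3-point
difference is evaluated on the complete cases of the *union* tuple so the
defining identity stays exact.

## Step 1 — skeleton

Starting from the complete graph, each pair first drops out if its
unconditional `I'(X;Y) <= 0` (equivalent to the first loop iteration, done
as a cheap pre-pass). Surviving edges collect contributors one at a time:
the candidate `Z` maximizing the shifted gain
`I'3 = [I(X;Y|{A}) - I(X;Y|{A} u Z)] - dk/n`, subject to `I'3 > 0`, where
`dk` is the complexity increment of the larger conditioning set. Penalizing
`dk` here is essential: without it, the finite-sample inflation of plug-in
conditional information makes irrelevant candidates look attractive, and
true edges accumulate junk contributors until the complexity kills them.

A global priority queue processes the edge with the highest rank
`R = n * I'3(best candidate)` first; after the edge absorbs its candidate it
is removed if `I'(X;Y|{A}) <= 0` (its contributors become the separating
set) or re-ranked with its next best candidate. Only the touched edge is
rescored per iteration (lazy refresh); whether re-ranking untouched edges
would change anything is not derivable from the main published account, and
the lazy variant keeps the loop linear. All ties break lexicographically,
so a run is a pure function of data and configuration.

With `latent = TRUE` (default) candidates are drawn from *all* observed
variables, not just current neighbors — necessary in the presence of
latent variables, where separating sets can contain non-adjacent nodes (the
`latentSepBN()` test fixture is a seven-node network where a pair is
separable only through a non-adjacent variable). The classic
neighbors-only search is available as `latent = FALSE`.

## Step 2 — confidence and signs

Each retained edge gets a removal probability
`P_XY = min(1, exp(-n I'(X;Y|{A_i})))`; using the shifted information
absorbs the unknown normalization of the raw `exp(-N I)` form. The
edge-specific confidence is the ratio `C_XY = P_XY / <P_rand>` over `B`
replicates in which every column is permuted independently (missing
positions travel with their values). A ratio, unlike a permutation p-value,
does not saturate for strong edges — virtually all permutations give
`P_rand` near 1 — so the default `B = 100` suffices; `B` only controls
Monte-Carlo error on the denominator. By default each replicate re-runs the
full per-pair contributor search; `fastMode` scores unconditional
information only and is documented as an approximation. Filtering keeps
edges with `C_XY` below the threshold (default `1e-3`).

Edge signs are the sign of the partial correlation of X and Y given the
edge's contributors, computed on level codes ranked in sorted label order
via residual regression (identical to the precision-matrix form but defined
even for perfectly correlated pairs). A negative sign marks a partial
anti-correlation, e.g. a repression in a regulatory network.

## Step 3 — orientation

For every unshielded triple `<X, Z, Y>` the conditional 3-point information
is computed given the stored separating set of `(X, Y)` minus `Z` — the
separating set is exactly the certificate that made the pair non-adjacent.
The raw value is shrunk toward zero by the complexity increment (`dk/n`),
so weak signals are treated as noise, and mapped to an orientation
probability `p_v = 1/(1 + exp(n I'3))`. This logistic map is the simplest
calibrated choice consistent with two requirements: `p_v > 1/2` exactly
when the shrunk 3-point information is negative, and a greedy loop that
stops when no probability exceeds 1/2. The published exact expression is in
supplementary material we treat as unavailable; if it surfaces, this map is
the one component to revisit.

Triples are processed greedily by decreasing probability (lexicographic
tie-break), to a fixpoint:

* collider evidence (`I'3 < 0`) on `X *-o Z o-* Y` or `X *-> Z o-* Y`:
  arrowheads into `Z`;
* non-collider evidence (`I'3 > 0`) on `X *-> Z o-o Y` or
  `X *-> Z o-> Y`: propagate `Z -> Y`.

Marks set by earlier (higher-probability) triples are never overwritten;
refused overwrites are logged as conflicts in the run report. No further
completion rules are applied. Edges with arrowheads at both ends are
bidirected — the latent-common-cause signature. `ancestralViolations()`
reports (never repairs) any directed cycle, almost-directed cycle, or
arrowhead into an undirected edge remaining in the final graph.

## Effective sample size for correlated samples

Consecutive Monte Carlo configurations are autocorrelated, which inflates
every `n` in the formulas above. For an exponentially decaying
autocorrelation `c(n) ~ alpha^n`, the variance of a sample mean over `N`
correlated draws equals that of `N (1-alpha)/(1+alpha)` independent draws,
so `effectiveN()` returns `round(N (1-alpha)/(1+alpha))`. `alpha` is fitted
by least squares on `log c(n)` using lags with `c(n) > 0.05` (below that
floor, log-scale noise dominates; the floor and the 50-lag cap are exposed
as arguments). Variables are pooled with lag-0-variance weights. Setting
`effectiveSamples(data) <- nEff` (or `nEff` in the pipeline config) rescales
every complexity term and removal-probability exponent; NML stratum counts
are rescaled (and rounded) by `nEff/N_a`.

At `alpha = 0.872` and `0.87` — decay rates typical of the Metropolis
samplers below — the ratio `N_eff/N` is 0.068–0.069.

## Benchmark machinery

* `randomDAG(P, avgDegree)` draws a DAG with a fixed topological order and
  forward-edge probability `avgDegree/(P-1)`, level counts uniform on 2–4,
  and CPT rows from a symmetric Dirichlet(1). These defaults emulate the
  sparse multinomial benchmark networks used throughout: `P = 20`,
  `avgDegree = 2`, `N = 10,000` is the recovery condition exercised in the
  acceptance suite (20 seeds, mean skeleton F >= 0.90).
* `hideLatents()` masks nodes uniformly among those with a *significant
  topological effect*: childless nodes and parentless single-child nodes
  are ineligible, since hiding them changes no conditional independence
  among the rest.
* `dSeparated()` answers exact d-separation via moralized-ancestral-graph
  reachability; `oracleReferenceGraph()` runs the skeleton + orientation
  pipeline with this oracle substituted for every data-driven decision.
  The result is this pipeline's own oracle fixpoint restricted to observed
  nodes — a reference for convergence checks, not a certified complete
  partial ancestral graph (no discriminating-path or completion rules).
* `isingCalibrate()` turns a causal reference network into a non-causal
  Ising system: reference variables are binarized at the most balanced
  level cut, and each skeleton edge's coupling `k_ij` is bisected until the
  model's pairwise mutual information matches the reference pair's
  empirical MI (tolerance 10% by default). Calibrating against *marginal*
  pairwise MI is a documented simplification of "approximately reproduce
  the pairwise conditional mutual information"; for small systems the MI
  during bisection is computed by exact Boltzmann enumeration
  (`estimator = "enumerate"`, up to 16 spins), otherwise from short
  Metropolis runs.
* `metropolisSample()` proposes flips of each spin with an adaptive
  fraction (start 0.10, multiplicative update toward 50% acceptance every
  1000 proposals, clipped to [0.01, 0.5]) and accepts with
  `min(1, exp(-dE))`. The chain state after every proposal is recorded —
  a rejection repeats the configuration — which is what makes the
  stationary distribution exactly Boltzmann; the two-spin marginal is
  checked against exact enumeration in the tests. Recording only accepted
  moves would bias the sample toward high-energy states (we measured
  P(x1 = x2) of 0.55 instead of the exact 0.73 on a two-spin system).

The generators emulate the benchmark conditions (sparse random DAGs,
multinomial CPTs, symmetric spin couplings); they do not emulate real
genomic data — no dropout, no batch structure, no mixed measurement types,
and missingness only enters as MCAR masks. Passing the suites therefore
demonstrates correctness of the machinery under its stated model, not
performance on any particular real dataset.

## Evaluation

`skeletonMetrics()` compares unordered adjacencies
(`Prec = TP/(TP+FP)`, `Rec = TP/(TP+FN)`, F = harmonic mean).
`endpointMetrics()` additionally classes a true-positive adjacency as
misoriented when an endpoint's arrowhead status differs from the reference
(arrowhead vs tail-or-circle; tail-vs-circle is not penalized) and scores
`TP' = TP - TP_mis`, `FP' = FP + TP_mis`. Conventions: precision 0 when
nothing is predicted but edges exist; all metrics 1 when both graphs are
empty.

## Problem sizes and numerical choices

The shipped test and acceptance suites run at deliberately modest sizes —
identity checks on 1000 random 25-sample tables; exhaustive oracle
verification over all 29,852 labeled DAGs on up to five nodes; recovery on
20-node DAGs at N = 10,000 over 20 seeds; a 15-spin Ising chain sampled for
30,000 Metropolis steps; a 100,000-step Markov chain for the
effective-sample check. These sizes were chosen so each suite completes in
minutes on one core while keeping every binomial/Monte-Carlo tolerance at
least 3 sigma wide.

Other conventions: `0 log 0 = 0`; single-level variables carry zero
information and are warned about, never fatal mid-pipeline; conditional
informations are clamped to zero only within 1e-12 of it; joint cells are
counted sparsely (sort + run-length encoding of a mixed-radix index in
double arithmetic), so cost scales with `N log N` and not with the nominal
table volume; all randomness flows from explicit integer seeds, and
permutation replicates are seeded per edge so results do not depend on
evaluation order.

## Known limitations

* Orientation probabilities use a surrogate logistic map, and the edge rank
  a surrogate `n * I'3`; both preserve the documented ordering semantics
  but are not the published supplementary forms.
* No FCI-style completion rules (R1–R10) or discriminating paths: the
  output is a partially oriented mixed graph, not a maximally informative
  PAG.
* Ising calibration targets marginal, not conditional, pairwise MI.
* The latent-variable machinery detects confounding via bidirected edges
  but does not attempt to locate or count the latent variables themselves.
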