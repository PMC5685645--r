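# causalmi

Causal and non-causal mixed graphical models from multivariate information.

`causalmi` learns network models over categorical variables from purely
observational data — no time series, no perturbation experiments — while
accounting for unobserved latent variables. It targets the situations common
in genomics: single-cell expression states, mutation/ploidy tables,
gene-property catalogues, where an unmeasured regulator can confound every
pairwise association.

The learned graph mixes three edge types:

* `X - Y` — dependence with no orientable direction,
* `X -> Y` — causal direction, identified through unshielded colliders
  (v-structures), the only causal signature present in observational data,
* `X <-> Y` — neither variable causes the other: the signature of a latent
  common cause.

## Method

The reconstruction is constraint-based, rephrased in information-theoretic
terms. For any set of variables `{A_i}`, mutual information decomposes as

    I(X;Y) = I(X;Y | {A_i}) + I(X;Y ; {A_i})

Step 1 starts from the complete graph and, for each pair, iteratively
collects the contributors `A_n` maximizing the shifted conditional 3-point
information `I'(X;Y;A_n | {A_i})` (positive terms only, penalized by a
finite-size complexity increment), processing edges by rank
`R = n * I'3`. An edge is removed once `I'(X;Y|{A_i}) = I - k/n <= 0`, its
contributors becoming its separating set; `k` is a BIC/MDL or (default)
decomposable normalized-maximum-likelihood complexity. With latent variables
allowed, contributors are searched among **all** observed variables, not
just neighbors.

Step 2 scores each retained edge with the removal probability
`P_XY = min(1, exp(-n I'))` and the permutation confidence ratio
`C_XY = P_XY / <P_XY^rand>` (columns permuted independently per replicate);
low `C_XY` means high confidence, and edges at or above a threshold
(default 1e-3) are dropped. Edges also get the sign of the partial
correlation `rho_{XY.A}` (negative = anti-correlation, e.g. repression).

Step 3 orients unshielded triples `<X, Z, Y>` by the sign of
`I(X;Y;Z | sep(X,Y) \ Z)` — negative is collider evidence — greedily by
orientation probability `1/(1 + exp(n I'3))`, with one propagation rule,
stopping at probability 1/2. Arrowheads meeting from both sides leave a
bidirected edge. For samples that are mutually correlated (e.g. consecutive
Monte Carlo configurations), the effective sample size
`N_eff = N (1-alpha)/(1+alpha)` replaces `N` in every finite-size term.

The package also ships the benchmark machinery used to validate all of the
above: random Bayesian networks with multinomial CPTs and forward sampling,
latent-variable masking, an exact d-separation oracle and oracle reference
graphs, Ising-model calibration with Metropolis sampling, and
skeleton/endpoint precision–recall–F scoring.

## Worked example

Two genes co-regulated by an unobserved factor, a third gene driven by one
of them together with an independent marker:

```r
library(causalmi)
set.seed(7)
n  <- 5000
tf <- sample(c("on","off"), n, TRUE)                      # hidden co-regulator
g1 <- ifelse(runif(n) < ifelse(tf=="on", .85, .25), "high", "low")
g2 <- ifelse(runif(n) < ifelse(tf=="on", .80, .20), "high", "low")
m  <- sample(c("pos","neg"), n, TRUE)
g3 <- ifelse(runif(n) < .15 + .35*(g1=="high") + .35*(m=="pos"), "high", "low")

d   <- categoricalData(data.frame(G1=g1, G2=g2, G3=g3, M=m))
res <- runPipeline(d, pipelineConfig(confidence = confidenceConfig(nPermutations = 25, seed = 2)))
res$graph
#> MixedGraph: 4 nodes, 3 edges
#>   G1 o-o G2
#>   G1 o-> G3
#>   G3 <-o M

edgeSummary(res$states, res$graph)[, c("x","y","ai","info","info_shifted","confidence","sign","category")]
#>    x  y   ai   info info_shifted confidence sign           category
#> 1 G1 G2 G3,M 0.0592       0.0567  6.38e-124    1 partially-oriented
#> 2 G1 G3   G2 0.0500       0.0487  2.03e-106    1 partially-oriented
#> 3 G3  M      0.0584       0.0577  6.47e-126   -1 partially-oriented
```

Reading the output: the spurious `G1–G3–M` shield never forms and the
collider `G1 *-> G3 <-* M` is oriented from the negative 3-point
information; the confounded pair `G1 o-o G2` stays adjacent (no observed
variable separates it) but is correctly left unoriented. `info` is
`I(X;Y|{A_i})` in nats, `info_shifted` its complexity-penalized version,
`confidence` the permutation ratio `C_XY` (all far below the 1e-3 cutoff),
and `sign` the partial-correlation sign on level codes in sorted label
order — the `-1` on `G3–M` reflects that `"high" < "low"` and
`"neg" < "pos"` sort in opposite directions to their effects.

Simulation utilities follow the same style:

```r
bn  <- randomDAG(20, avgDegree = 2, seed = 1)   # ground truth
d   <- forwardSample(bn, 10000, seed = 2)
sk  <- learnSkeleton(d)
skeletonMetrics(sk$graph, dagMixedGraph(bn))    # precision / recall / F
```

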