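# Benchmark generators: random DAGs, forward sampling, latent masking,
# d-separation, oracle graphs, Ising calibration and Metropolis sampling.

test_that("random DAGs: reproducibility, acyclicity, degree calibration", {
  b1 <- randomDAG(10, 3, seed = 5)
  b2 <- randomDAG(10, 3, seed = 5)
  expect_identical(b1@parents, b2@parents)
  expect_identical(b1@cpts, b2@cpts)
  # topological-order parent constraint makes cycles impossible; validity
  # already enforces it, but check explicitly for an ensemble
  degs <- vapply(1:100, function(s) {
    bn <- randomDAG(10, 3, seed = s)
    expect_true(validObject(bn))
    2 * sum(lengths(bn@parents)) / 10
  }, 0)
  expect_equal(mean(degs), 3, tolerance = 0.1)
  # CPT rows are distributions
  expect_true(all(abs(rowSums(b1@cpts[["V005"]]) - 1) < 1e-12))
})

test_that("forward sampling reproduces the generating distribution", {
  # deterministic CPTs: a single repeated row
  bn <- bayesNet(c("A", "B"), parents = list(B = "A"),
                 levels = c(A = 2L, B = 2L),
                 cpts = list(A = matrix(c(1, 0), 1, 2), B = cptLink(1)))
  d <- forwardSample(bn, 50, seed = 1)
  expect_true(all(d@codes == 1L))
  # root marginals within 3 sigma at N = 10000
  bn2 <- randomDAG(6, 2, seed = 9)
  d2 <- forwardSample(bn2, 10000, seed = 10)
  root <- bn2@nodes[lengths(bn2@parents[bn2@nodes]) == 0][1]
  p <- bn2@cpts[[root]][1, ]
  for (lv in seq_along(p)) {
    phat <- mean(d2@codes[, root] == lv)
    expect_lt(abs(phat - p[lv]), 3 * sqrt(p[lv] * (1 - p[lv]) / 10000) + 1e-9)
  }
  # empirical MI of a strong two-node link matches the CPT-exact value
  bn3 <- bayesNet(c("A", "B"), parents = list(B = "A"),
                  levels = c(A = 2L, B = 2L),
                  cpts = list(A = cptRoot(0.4), B = cptLink(0.9)))
  joint <- rbind(0.4 * c(0.9, 0.1), 0.6 * c(0.1, 0.9))
  px <- rowSums(joint); py <- colSums(joint)
  exact <- sum(joint * log(joint / outer(px, py)))
  d3 <- forwardSample(bn3, 50000, seed = 11)
  expect_equal(condMutualInfo(d3, "A", "B")@info, exact, tolerance = 0.01)
})

test_that("latent masking honors the topological-effect eligibility rule", {
  bn <- randomDAG(37, 2.5, seed = 15)
  nChildren <- vapply(bn@nodes, function(v)
    sum(vapply(bn@parents, function(p) v %in% p, TRUE)), 0L)
  nParents <- lengths(bn@parents)
  for (s in 1:25) {
    h <- hideLatents(bn, 0.2, seed = s)
    expect_length(h$hidden, 7L) # 0.2 * 37 rounds to 7
    for (v in h$hidden) {
      expect_gt(nChildren[[v]], 0L)
      expect_false(nParents[[v]] == 0L && nChildren[[v]] == 1L)
    }
  }
  expect_error(hideLatents(bn, 1000, seed = 1), "eligible")
})

test_that("d-separation oracle: textbook cases and the latent-conditioning fixture", {
  chain <- chainBN()
  expect_true(dSeparated(chain, "A", "C", "B"))
  expect_false(dSeparated(chain, "A", "C"))
  coll <- colliderBN()
  expect_true(dSeparated(coll, "A", "B"))
  expect_false(dSeparated(coll, "A", "B", "C"))
  expect_error(dSeparated(coll, "A", "Q"), "unknown")
  # pair {Z, T}: separable given {X, Y, W}, or with a latent variable in
  # the conditioning set, but by no observed subset that omits W
  bn <- latentSepBN()
  expect_true(dSeparated(bn, "Z", "T", c("X", "Y", "W")))
  expect_true(dSeparated(bn, "Z", "T", c("X", "L")))
  expect_true(dSeparated(bn, "Z", "T", c("Y", "Lp")))
  others <- c("X", "Y")
  for (k in 0:2) for (S in utils::combn(others, k, simplify = FALSE))
    expect_false(dSeparated(bn, "Z", "T", S))
})

test_that("oracle reference graphs: exact recovery and latent signatures", {
  # no hidden nodes: skeleton equals the DAG skeleton, v-structures oriented
  bn <- bnFromAdj(rbind(c(0, 0, 1, 0), c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 0, 0, 0)))
  og <- oracleReferenceGraph(bn)
  expect_identical(graphEdges(og$graph)[, c("x", "y")],
                   graphEdges(trueSkeletonGraph(rbind(c(0, 0, 1, 0), c(0, 0, 1, 0),
                                                      c(0, 0, 0, 1), c(0, 0, 0, 0))))[, c("x", "y")])
  expect_identical(graphVStructures(og$graph), "A|C|B")
  # hidden collider-path cause: bidirected edge appears
  og2 <- oracleReferenceGraph(latentColliderBN(), hidden = "L")
  e <- graphEdges(og2$graph)
  i <- which(e$x == "Y" & e$y == "Z")
  expect_identical(c(e$markX[i], e$markY[i]), c("arrow", "arrow"))
  # bidirected edges arise only between nodes sharing a hidden cause
  set.seed(20)
  for (s in 1:10) {
    adjs <- enumerateDAGs(4)
    adj <- adjs[[sample(length(adjs), 1)]]
    bn4 <- bnFromAdj(adj, nodes = c("A", "B", "C", "D"))
    h <- intersect(bn4@nodes[lengths(bn4@parents) == 0], bn4@nodes)
    h <- h[1]
    og3 <- oracleReferenceGraph(bn4, hidden = h)
    e3 <- graphEdges(og3$graph)
    bidir <- which(e3$markX == "arrow" & e3$markY == "arrow")
    for (b in bidir) {
      # both ends must be children of the hidden root
      kids <- bn4@nodes[vapply(bn4@parents, function(p) h %in% p, TRUE)]
      expect_true(all(c(e3$x[b], e3$y[b]) %in% kids))
    }
  }
})

test_that("Ising: exact pair distribution, calibration, Metropolis balance", {
  # two-spin closed form: P(x1 = x2) = e^k / (e^k + e^-k)
  m <- isingModel(c("a", "b"), matrix(c(0, .5, .5, 0), 2, 2))
  pd <- isingPairDistribution(m, "a", "b")
  expect_equal(pd[1, 1] + pd[2, 2], exp(.5) / (exp(.5) + exp(-.5)), tolerance = 1e-12)
  # zero couplings: acceptance 1, i.i.d. uniform spins
  m0 <- isingModel(c("a", "b", "c"), matrix(0, 3, 3))
  s0 <- metropolisSample(m0, 4000, seed = 30)
  expect_equal(attr(s0, "acceptanceRate"), 1)
  expect_equal(mean(s0@codes == 2L), 0.5, tolerance = 0.05)
  # two-spin sampler matches Boltzmann
  s <- metropolisSample(m, 30000, seed = 31)
  expect_equal(mean(s@codes[, 1] == s@codes[, 2]),
               exp(.5) / (exp(.5) + exp(-.5)), tolerance = 0.02)
  # calibration: bisection against exact enumeration recovers the coupling
  # that reproduces the reference MI (independent closed-form inversion)
  bn <- bayesNet(c("A", "B"), parents = list(B = "A"),
                 levels = c(A = 2L, B = 2L),
                 cpts = list(A = cptRoot(), B = cptLink(0.88)))
  im <- isingCalibrate(bn, mcBudget = 20000, seed = 32, tol = 1e-8,
                       estimator = "enumerate")
  k <- im@couplings[1, 2]
  expect_identical(im@couplings, t(im@couplings))
  # invert MI(k) by bisection on the closed form
  ref <- forwardSample(bn, 20000, seed = 32)
  tab <- table(ref@codes[, 1], ref@codes[, 2]) / 20000
  px <- rowSums(tab); py <- colSums(tab)
  target <- sum(tab * log(tab / outer(px, py)))
  miOf <- function(kk) {
    peq <- exp(kk) / (exp(kk) + exp(-kk))
    p <- matrix(c(peq / 2, (1 - peq) / 2, (1 - peq) / 2, peq / 2), 2, 2)
    sum(p * log(p / outer(rowSums(p), colSums(p))))
  }
  lo <- 0; hi <- 3
  for (it in 1:50) { mid <- (lo + hi) / 2; if (miOf(mid) > target) hi <- mid else lo <- mid }
  expect_equal(k, (lo + hi) / 2, tolerance = 1e-3)
  # target MI of zero keeps the coupling at zero
  bn0 <- bayesNet(c("A", "B"), parents = list(B = "A"),
                  levels = c(A = 2L, B = 2L),
                  cpts = list(A = cptRoot(), B = cptLink(0.5)))
  im0 <- isingCalibrate(bn0, mcBudget = 5000, seed = 33, estimator = "enumerate")
  expect_lt(abs(im0@couplings[1, 2]), 0.1)
})

test_that("adaptive flip fraction settles near the 50% acceptance target", {
  # moderate couplings: the single-spin-flip acceptance ceiling stays above
  # the 50% target so the controller can actually reach it
  im <- isingCalibrate(spinChainBN(10, 0.7), mcBudget = 2000, seed = 40,
                       estimator = "enumerate")
  s <- metropolisSample(im, 20000, seed = 41)
  expect_gte(attr(s, "acceptanceRate"), 0.4)
  expect_lte(attr(s, "acceptanceRate"), 0.6)
})
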