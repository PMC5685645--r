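# Step 3: triple scoring, probabilistic orientation, propagation, and
# ancestral-graph consistency.

test_that("triple probability: indifference point, limits, closed form", {
  expect_equal(tripleProbability(0, 1000L), 0.5)
  expect_equal(tripleProbability(-1e6, 10L), 1)
  expect_equal(tripleProbability(-2, 1L), 1 / (1 + exp(-2)))
  expect_equal(tripleProbability(-0.002, 1000L), 1 / (1 + exp(-2)))
})

test_that("unshielded triples are enumerated correctly", {
  tri <- mixedGraph(c("A", "B", "C"),
                    data.frame(x = c("A", "A", "B"), y = c("B", "C", "C"),
                               stringsAsFactors = FALSE))
  d <- randomTable(n = 50, p = 3, seed = 1)
  names(d@levels) <- colnames(d@codes) <- c("A", "B", "C")
  expect_equal(nrow(unshieldedTriples(tri, NULL, d)), 0L)
  path <- mixedGraph(c("A", "B", "C"),
                     data.frame(x = c("A", "B"), y = c("B", "C"),
                                stringsAsFactors = FALSE))
  tt <- unshieldedTriples(path, NULL, d)
  expect_equal(nrow(tt), 1L)
  expect_identical(tt$z, "B")
})

test_that("collider data orient as a v-structure, chains stay unoriented", {
  d <- forwardSample(colliderBN(), 10000, seed = 51)
  res <- runPipeline(d, pipelineConfig(confidence = NULL))
  expect_identical(graphVStructures(res$graph), "A|C|B")
  e <- graphEdges(res$graph)
  expect_true(all(e$markY[e$y == "C"] == "arrow" | e$markX[e$x == "C"] == "arrow"))
  d2 <- forwardSample(chainBN(), 10000, seed = 52)
  res2 <- runPipeline(d2, pipelineConfig(confidence = NULL))
  expect_equal(arrowheadFraction(res2$graph), 0)
})

test_that("orientation propagates through downstream edges", {
  # A -> C <- B with C -> D: after the v-structure, the (A, C, D) triple is
  # a non-collider (C in sep(A, D)), so C -> D is propagated
  bn <- bayesNet(c("A", "B", "C", "D"),
                 parents = list(C = c("A", "B"), D = "C"),
                 levels = c(A = 2L, B = 2L, C = 2L, D = 2L),
                 cpts = list(A = cptRoot(), B = cptRoot(), C = cptPair(),
                             D = cptLink(0.9)))
  d <- forwardSample(bn, 20000, seed = 53)
  res <- runPipeline(d, pipelineConfig(confidence = NULL))
  e <- graphEdges(res$graph)
  i <- which(e$x == "C" & e$y == "D")
  expect_equal(e$markX[i], "tail")
  expect_equal(e$markY[i], "arrow")
  expect_identical(graphVStructures(res$graph), "A|C|B")
})

test_that("hidden common cause leaves a bidirected edge", {
  bn <- latentColliderBN()
  og <- oracleReferenceGraph(bn, hidden = "L")
  e <- graphEdges(og$graph)
  i <- which(e$x == "Y" & e$y == "Z")
  expect_length(i, 1L)
  expect_identical(c(e$markX[i], e$markY[i]), c("arrow", "arrow"))
})

test_that("orientation never alters the skeleton", {
  d <- forwardSample(randomDAG(8, 2, seed = 61), 4000, seed = 62)
  sk <- learnSkeleton(d)
  tri <- unshieldedTriples(sk$graph, sk$states, d)
  ori <- orientEdges(sk$graph, tri)
  expect_identical(graphEdges(ori$graph)[, c("x", "y")],
                   graphEdges(sk$graph)[, c("x", "y")])
})

test_that("orientation is independent of triple ordering", {
  d <- forwardSample(colliderBN(), 5000, seed = 63)
  sk <- learnSkeleton(d)
  tri <- unshieldedTriples(sk$graph, sk$states, d)
  ori1 <- orientEdges(sk$graph, tri)
  ori2 <- orientEdges(sk$graph, tri[rev(seq_len(nrow(tri))), , drop = FALSE])
  expect_identical(graphEdges(ori1$graph), graphEdges(ori2$graph))
})

test_that("ancestral constraint violations are detected", {
  cyc <- mixedGraph(c("A", "B", "C"), data.frame(
    x = c("A", "B", "A"), y = c("B", "C", "C"),
    markX = c("tail", "tail", "arrow"), markY = c("arrow", "arrow", "tail"),
    stringsAsFactors = FALSE)) # A->B->C->A
  v <- ancestralViolations(cyc)
  expect_true(any(vapply(v, function(x) x$type == "directed-cycle", TRUE)))
  almost <- mixedGraph(c("A", "B"), data.frame(
    x = "A", y = "B", markX = "arrow", markY = "arrow",
    stringsAsFactors = FALSE))
  # add a directed path A -> B alongside A <-> B via a relay node
  almost2 <- mixedGraph(c("A", "B", "C"), data.frame(
    x = c("A", "A", "B"), y = c("B", "C", "C"),
    markX = c("arrow", "tail", "arrow"), markY = c("arrow", "arrow", "tail"),
    stringsAsFactors = FALSE)) # A<->B, A->C, C->B
  v2 <- ancestralViolations(almost2)
  expect_true(any(vapply(v2, function(x) x$type == "almost-directed-cycle", TRUE)))
  und <- mixedGraph(c("A", "B", "C"), data.frame(
    x = c("A", "B"), y = c("B", "C"),
    markX = c("tail", "tail"), markY = c("tail", "arrow"),
    stringsAsFactors = FALSE)) # A-B undirected, B->C... arrow into C fine
  expect_length(ancestralViolations(und), 0L)
  bad <- mixedGraph(c("A", "B", "C"), data.frame(
    x = c("A", "B"), y = c("B", "C"),
    markX = c("tail", "tail"), markY = c("arrow", "tail"),
    stringsAsFactors = FALSE)) # A->B with B-C undirected
  v3 <- ancestralViolations(bad)
  expect_true(any(vapply(v3, function(x) x$type == "arrowhead-into-undirected", TRUE)))
  # a valid partially oriented pattern reports nothing
  ok <- mixedGraph(c("A", "B", "C"), data.frame(
    x = c("A", "B"), y = c("B", "C"),
    markX = c("circle", "tail"), markY = c("arrow", "arrow"),
    stringsAsFactors = FALSE))
  expect_length(ancestralViolations(ok), 0L)
})
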