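# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# CategoricalData from integer (or character) vectors
makeData <- function(...) {
  df <- data.frame(lapply(list(...), as.character), stringsAsFactors = FALSE)
  categoricalData(df)
}

# binary root CPT
cptRoot <- function(p1 = 0.5) matrix(c(p1, 1 - p1), 1, 2)

# binary node with one binary parent: P(child = parent's value) = a
cptLink <- function(a) matrix(c(a, 1 - a, 1 - a, a), 2, 2, byrow = TRUE)

# binary node with two binary parents: P(C = 1 | a, b) = base + wa*(a-1) + wb*(b-1)
cptPair <- function(base = 0.15, wa = 0.35, wb = 0.35) {
  p1 <- c(base, base + wa, base + wb, base + wa + wb) # configs (a,b): 11,21,12,22
  cbind(1 - p1, p1)
}

chainBN <- function(a = 0.85) {
  nodes <- c("A", "B", "C")
  bayesNet(nodes,
           parents = list(B = "A", C = "B"),
           levels = c(A = 2L, B = 2L, C = 2L),
           cpts = list(A = cptRoot(), B = cptLink(a), C = cptLink(a)))
}

colliderBN <- function() {
  nodes <- c("A", "B", "C")
  bayesNet(nodes,
           parents = list(C = c("A", "B")),
           levels = c(A = 2L, B = 2L, C = 2L),
           cpts = list(A = cptRoot(), B = cptRoot(), C = cptPair()))
}

# collider-path topology X -> Z <- L -> Y <- W whose bidirected Z<->Y
# signature appears once L is hidden
latentColliderBN <- function() {
  # two binary parents, both influential: configs 11,21,12,22
  cpt2 <- function() matrix(c(.9, .1, .4, .6, .6, .4, .1, .9), 4, 2, byrow = TRUE)
  bayesNet(c("L", "W", "X", "Y", "Z"),
           parents = list(Z = c("X", "L"), Y = c("L", "W")),
           levels = c(L = 2L, W = 2L, X = 2L, Y = 2L, Z = 2L),
           cpts = list(L = cptRoot(), W = cptRoot(), X = cptRoot(),
                       Y = cpt2(), Z = cpt2()))
}

# Seven-node DAG (two latent roots L, Lp) whose observed pair {Z, T} is
# separable only by conditioning sets that include the non-adjacent W;
# synthetic construction frozen from a search over small DAGs for exactly
# these d-separation properties.
latentSepBN <- function() {
  nodes <- c("L", "Lp", "X", "W", "Y", "Z", "T")
  parents <- list(Z = "L", W = c("Lp", "X"), Y = c("L", "W", "X"),
                  T = c("Lp", "Y"))
  levels <- stats::setNames(rep(2L, 7), nodes)
  cpts <- list(L = cptRoot(), Lp = cptRoot(), X = cptRoot(),
               Z = cptLink(0.8),
               W = cptPair(), Y = cptPair(0.1, 0.3, 0.25),
               T = cptPair())
  # Y has 3 parents: 8 parent configs
  p1 <- c(.1, .4, .35, .65, .3, .6, .55, .9)
  cpts$Y <- cbind(1 - p1, p1)
  bayesNet(nodes, parents, levels, cpts)
}

# observed-only view of a sample (drop hidden columns)
observedData <- function(d, hidden) {
  keep <- setdiff(varNames(d), hidden)
  new("CategoricalData", codes = d@codes[, keep, drop = FALSE],
      levels = d@levels[keep], nEff = d@nEff)
}

# --- exhaustive DAG enumeration over k nodes -------------------------------

# all labeled DAGs on k nodes as adjacency matrices (adj[i,j]=1 means i->j)
enumerateDAGs <- function(k) {
  pairs <- utils::combn(k, 2)
  np <- ncol(pairs)
  out <- vector("list", 0L)
  states <- rep(0L, np)
  total <- 3^np
  for (code in 0:(total - 1)) {
    c0 <- code
    adj <- matrix(0L, k, k)
    for (p in seq_len(np)) {
      s <- c0 %% 3L; c0 <- c0 %/% 3L
      if (s == 1L) adj[pairs[1, p], pairs[2, p]] <- 1L
      else if (s == 2L) adj[pairs[2, p], pairs[1, p]] <- 1L
    }
    if (isAcyclic(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

isAcyclic <- function(adj) {
  k <- nrow(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, k)
  for (step in seq_len(k)) {
    z <- which(active & indeg == 0L)
    if (!length(z)) return(FALSE)
    for (v in z) {
      active[v] <- FALSE
      indeg <- indeg - adj[v, ]
    }
    if (!any(active)) return(TRUE)
  }
  !any(active)
}

# BayesNet from an adjacency matrix (uniform-ish CPTs; only the structure
# matters for oracle runs)
bnFromAdj <- function(adj, nodes = LETTERS[seq_len(nrow(adj))]) {
  topo <- nodes[topoOrder(adj)]
  parents <- stats::setNames(lapply(seq_along(nodes), function(j)
    nodes[which(adj[, j] == 1L)]), nodes)
  levels <- stats::setNames(rep(2L, length(nodes)), nodes)
  cpts <- stats::setNames(lapply(seq_along(nodes), function(j) {
    np <- sum(adj[, j])
    matrix(0.5, 2^np, 2)
  }), nodes)
  bayesNet(topo, parents[topo], levels, cpts)
}

topoOrder <- function(adj) {
  k <- nrow(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, k)
  ord <- integer(0)
  while (any(active)) {
    z <- which(active & indeg == 0L)
    v <- z[1L]
    ord <- c(ord, v)
    active[v] <- FALSE
    indeg <- indeg - adj[v, ]
    indeg[!active] <- 1L
    indeg[v] <- 0L
  }
  ord
}

trueSkeletonGraph <- function(adj, nodes = LETTERS[seq_len(nrow(adj))]) {
  und <- which(adj == 1L, arr.ind = TRUE)
  if (!nrow(und)) return(mixedGraph(nodes))
  mixedGraph(nodes, data.frame(x = nodes[und[, 1]], y = nodes[und[, 2]],
                               stringsAsFactors = FALSE))
}

# set of true v-structures "x|z|y" (x < y) of a DAG adjacency
trueVStructures <- function(adj, nodes = LETTERS[seq_len(nrow(adj))]) {
  k <- nrow(adj)
  out <- character(0)
  for (z in seq_len(k)) {
    pa <- which(adj[, z] == 1L)
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in (i + 1L):length(pa)) {
      a <- pa[i]; b <- pa[j]
      if (adj[a, b] == 0L && adj[b, a] == 0L) {
        xy <- sort(c(nodes[a], nodes[b]))
        out <- c(out, paste(xy[1], nodes[z], xy[2], sep = "|"))
      }
    }
  }
  sort(out)
}

# v-structures present in a mixed graph (both arrowheads into z, ends
# non-adjacent)
graphVStructures <- function(graph) {
  vStructures(graph)
}

arrowheadFraction <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) return(0)
  (sum(e$markX == "arrow") + sum(e$markY == "arrow")) / (2 * nrow(e))
}

# chain BayesNet over P binary spins with link strength a
spinChainBN <- function(P = 15L, a = 0.85) {
  nodes <- sprintf("S%02d", seq_len(P))
  parents <- stats::setNames(c(list(character(0)),
                               lapply(seq_len(P - 1L), function(i) nodes[i])), nodes)
  cpts <- stats::setNames(c(list(cptRoot()),
                            replicate(P - 1L, cptLink(a), simplify = FALSE)), nodes)
  bayesNet(nodes, parents, stats::setNames(rep(2L, P), nodes), cpts)
}

# two-state Markov chain with stay probability `stay` (alpha = 2 stay - 1)
markovChainData <- function(N, stay = 0.9, seed = 5L) {
  set.seed(seed)
  x <- integer(N); x[1] <- 1L
  r <- stats::runif(N)
  for (t in 2:N) x[t] <- if (r[t] < stay) x[t - 1L] else 1L - x[t - 1L]
  makeData(S = x)
}

# random small CategoricalData for property loops
randomTable <- function(n = 30L, p = 3L, maxLevels = 3L, seed = 1L) {
  set.seed(seed)
  cols <- lapply(seq_len(p), function(j) {
    r <- if (maxLevels <= 2L) 2L else sample(2:maxLevels, 1L)
    sample.int(r, n, replace = TRUE)
  })
  names(cols) <- LETTERS[seq_len(p)]
  do.call(makeData, cols)
}
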