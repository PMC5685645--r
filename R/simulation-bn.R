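# Benchmark ground-truth generation: random DAGs with multinomial CPTs,
# forward sampling, hidden-variable masking, and a d-separation oracle.

#' Construct a BayesNet
#'
#' @param nodes node names in topological order.
#' @param parents named list of parent vectors (missing entries = no
#'   parents).
#' @param levels named integer vector of level counts.
#' @param cpts named list of CPT matrices: one row per parent configuration
#'   (mixed-radix, first parent fastest), one column per own level.
#' @return A \linkS4class{BayesNet}.
#' @export
bayesNet <- function(nodes, parents = list(), levels, cpts) {
  full <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) full[[v]] <- if (is.null(parents[[v]])) character(0) else parents[[v]]
  new("BayesNet", nodes = nodes, parents = full,
      levels = stats::setNames(as.integer(levels[nodes]), nodes),
      cpts = cpts[nodes])
}

setMethod("show", "BayesNet", function(object) {
  ne <- sum(lengths(object@parents))
  cat(sprintf("BayesNet: %d nodes, %d edges, levels %d-%d\n",
              length(object@nodes), ne, min(object@levels), max(object@levels)))
})

#' Random DAG with multinomial CPTs
#'
#' Generates a benchmark causal network: nodes are placed in a fixed
#' topological order and each forward pair is an edge independently with
#' probability avgDegree / (P - 1), so the expected average degree matches
#' the target. Level counts are uniform in \code{levelRange} and every CPT
#' row is drawn from a symmetric Dirichlet(1).
#'
#' @param P number of nodes (>= 2).
#' @param avgDegree target average degree (0 < avgDegree < P - 1).
#' @param levelRange integer range of per-node level counts (default 2-4).
#' @param seed integer seed.
#' @return A \linkS4class{BayesNet}.
#' @export
randomDAG <- function(P, avgDegree, levelRange = c(2L, 4L), seed = 1L) {
  stopifnot(P >= 2L, avgDegree > 0, avgDegree < P - 1)
  set.seed(seed)
  nodes <- sprintf("V%03d", seq_len(P))
  q <- avgDegree / (P - 1)
  parents <- stats::setNames(replicate(P, character(0), simplify = FALSE), nodes)
  for (j in 2:P) {
    sel <- stats::runif(j - 1L) < q
    parents[[j]] <- nodes[seq_len(j - 1L)][sel]
  }
  levels <- stats::setNames(
    sample(seq(levelRange[1L], levelRange[2L]), P, replace = TRUE), nodes)
  cpts <- lapply(nodes, function(v) {
    r <- levels[[v]]
    npc <- prod(levels[parents[[v]]])
    m <- matrix(stats::rgamma(npc * r, shape = 1), nrow = npc, ncol = r)
    m / rowSums(m)
  })
  names(cpts) <- nodes
  bayesNet(nodes, parents, levels, cpts)
}

#' Ancestral (forward) sampling from a BayesNet
#'
#' Draws N joint samples by sampling each node given its parents in
#' topological order. No missing values are produced.
#'
#' @param bn a \linkS4class{BayesNet}.
#' @param N number of samples.
#' @param seed integer seed.
#' @return A \linkS4class{CategoricalData} whose level sets are the full
#'   level ranges of the network (even if some levels go unobserved).
#' @export
forwardSample <- function(bn, N, seed = 1L) {
  set.seed(seed)
  nodes <- bn@nodes
  codes <- matrix(NA_integer_, N, length(nodes), dimnames = list(NULL, nodes))
  for (v in nodes) {
    r <- bn@levels[[v]]
    pa <- bn@parents[[v]]
    cpt <- bn@cpts[[v]]
    if (!length(pa)) {
      codes[, v] <- sample.int(r, N, replace = TRUE, prob = cpt[1L, ])
    } else {
      pidx <- codes[, pa[1L]]
      mult <- bn@levels[[pa[1L]]]
      if (length(pa) > 1L) for (k in 2:length(pa)) {
        pidx <- pidx + (codes[, pa[k]] - 1L) * mult
        mult <- mult * bn@levels[[pa[k]]]
      }
      for (u in unique(pidx)) {
        rows <- which(pidx == u)
        codes[rows, v] <- sample.int(r, length(rows), replace = TRUE, prob = cpt[u, ])
      }
    }
  }
  lv <- lapply(nodes, function(v) as.character(seq_len(bn@levels[[v]])))
  names(lv) <- nodes
  new("CategoricalData", codes = codes, levels = lv, nEff = NA_integer_)
}

#' Pick latent variables with a significant topological effect
#'
#' Chooses nodes to hide uniformly at random among the eligible pool:
#' parentless vertices with a single child and childless vertices are
#' excluded, since hiding them leaves the conditional-independence structure
#' over the remaining variables unchanged.
#'
#' @param bn a \linkS4class{BayesNet}.
#' @param fractionOrCount hidden fraction (value < 1) or count (>= 1).
#' @param seed integer seed.
#' @return list with \code{observed} and \code{hidden} name vectors.
#' @export
hideLatents <- function(bn, fractionOrCount, seed = 1L) {
  set.seed(seed)
  nodes <- bn@nodes
  nChildren <- vapply(nodes, function(v)
    sum(vapply(bn@parents, function(p) v %in% p, TRUE)), 0L)
  nParents <- lengths(bn@parents)
  eligible <- nodes[nChildren >= 1L & !(nParents == 0L & nChildren == 1L)]
  count <- if (fractionOrCount < 1) round(fractionOrCount * length(nodes))
           else as.integer(fractionOrCount)
  if (count > length(eligible))
    stop(sprintf("requested %d hidden nodes but only %d are eligible",
                 count, length(eligible)))
  hidden <- sort(sample(eligible, count))
  list(observed = setdiff(nodes, hidden), hidden = hidden)
}

#' d-separation oracle
#'
#' Answers whether X and Y are d-separated given a conditioning set S in the
#' network's DAG, via the moralized-ancestral-graph reachability
#' construction (equivalent to Bayes-ball): restrict to the ancestors of
#' {X, Y} u S, marry co-parents, drop S, and test undirected connectivity.
#'
#' @param bn a \linkS4class{BayesNet}.
#' @param x,y node names (distinct, not in \code{cond}).
#' @param cond conditioning set (character, possibly empty).
#' @return TRUE if X and Y are d-separated given cond.
#' @export
dSeparated <- function(bn, x, y, cond = character(0)) {
  nodes <- bn@nodes
  unknown <- setdiff(c(x, y, cond), nodes)
  if (length(unknown)) stop(sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")))
  stopifnot(x != y, !(x %in% cond), !(y %in% cond))
  pa <- bn@parents
  # ancestral closure of {x, y} u cond
  A <- unique(c(x, y, cond))
  repeat {
    more <- setdiff(unique(unlist(pa[A])), A)
    if (!length(more)) break
    A <- c(A, more)
  }
  # undirected adjacency of the moralized ancestral subgraph
  idx <- stats::setNames(seq_along(A), A)
  adj <- matrix(FALSE, length(A), length(A))
  for (v in A) {
    ps <- intersect(pa[[v]], A)
    for (p in ps) { adj[idx[[p]], idx[[v]]] <- TRUE; adj[idx[[v]], idx[[p]]] <- TRUE }
    if (length(ps) > 1L) for (i in seq_len(length(ps) - 1L)) for (j in (i + 1L):length(ps)) {
      adj[idx[[ps[i]]], idx[[ps[j]]]] <- TRUE
      adj[idx[[ps[j]]], idx[[ps[i]]]] <- TRUE
    }
  }
  blocked <- A %in% cond
  # BFS from x avoiding conditioned nodes
  seen <- logical(length(A))
  seen[idx[[x]]] <- TRUE
  frontier <- idx[[x]]
  ty <- idx[[y]]
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      nb <- which(adj[f, ] & !seen & !blocked)
      nxt <- c(nxt, nb)
      seen[nb] <- TRUE
    }
    if (seen[ty]) return(FALSE)
    frontier <- nxt
  }
  TRUE
}

#' Oracle-driven reference mixed graph
#'
#' Runs the skeleton and orientation pipeline with exact d-separation on the
#' full DAG (including hidden nodes) standing in for every data-driven
#' conditional-independence decision, then restricts the result to the
#' observed nodes. For each observed pair, separating sets are searched
#' among observed variables by increasing size; unshielded triples become
#' colliders exactly when the middle node is outside the stored separating
#' set, and the same propagation rule as the data pipeline is applied. The
#' result is this pipeline's own oracle fixpoint (not a certified complete
#' partial ancestral graph).
#'
#' @param bn a \linkS4class{BayesNet} (the full ground truth).
#' @param hidden character vector of hidden node names.
#' @return list with \code{graph} (a \linkS4class{MixedGraph} over observed
#'   nodes) and \code{sepSets} (named list of separating sets; NULL entry =
#'   pair adjacent).
#' @export
oracleReferenceGraph <- function(bn, hidden = character(0)) {
  observed <- sort(setdiff(bn@nodes, hidden))
  sepSets <- list()
  edges <- list()
  for (i in seq_len(length(observed) - 1L)) for (j in (i + 1L):length(observed)) {
    x <- observed[i]; y <- observed[j]
    others <- setdiff(observed, c(x, y))
    sep <- NULL
    for (size in 0:length(others)) {
      for (S in utils::combn(length(others), size, simplify = FALSE)) {
        if (dSeparated(bn, x, y, others[S])) { sep <- others[S]; break }
      }
      if (!is.null(sep)) break
    }
    if (is.null(sep)) {
      edges[[length(edges) + 1L]] <- c(x, y)
    } else {
      sepSets[[.edgeKey(x, y)]] <- sep
    }
  }
  g <- mixedGraph(observed, if (length(edges)) {
    data.frame(x = vapply(edges, `[`, "", 1L), y = vapply(edges, `[`, "", 2L),
               stringsAsFactors = FALSE)
  } else NULL)
  # oracle triple scores: collider iff z outside sepset(x, y)
  rows <- list()
  for (z in observed) {
    nb <- .neighbors(g, z)
    if (length(nb) < 2L) next
    for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
      x <- nb[a]; y <- nb[b]
      if (.hasEdge(g, x, y)) next
      sep <- sepSets[[.edgeKey(x, y)]]
      isV <- !(z %in% sep)
      rows[[length(rows) + 1L]] <- data.frame(
        x = x, z = z, y = y, info3 = if (isV) -1 else 1,
        shrunk = if (isV) -1 else 1, nUsed = 100L,
        kind = if (isV) "v" else "non-v",
        probability = 1 / (1 + exp(-100)), stringsAsFactors = FALSE)
    }
  }
  triples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = character(0), z = character(0), y = character(0),
               info3 = numeric(0), shrunk = numeric(0), nUsed = integer(0),
               kind = character(0), probability = numeric(0),
               stringsAsFactors = FALSE)
  ori <- orientEdges(g, triples)
  list(graph = ori$graph, sepSets = sepSets)
}

#' True-DAG mixed graph
#'
#' The fully oriented ground-truth graph of a BayesNet (tail at each parent,
#' arrowhead at each child), mainly used as an evaluation reference when no
#' variables are hidden.
#'
#' @param bn a \linkS4class{BayesNet}.
#' @return A \linkS4class{MixedGraph}.
#' @export
dagMixedGraph <- function(bn) {
  rows <- list()
  for (v in bn@nodes) for (p in bn@parents[[v]]) {
    rows[[length(rows) + 1L]] <- data.frame(x = p, y = v, markX = "tail",
                                            markY = "arrow", stringsAsFactors = FALSE)
  }
  mixedGraph(bn@nodes, if (length(rows)) do.call(rbind, rows) else NULL)
}
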