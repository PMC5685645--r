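# Step 1: iterative edge removal by one-by-one collection of the most likely
# information contributors of each pair.

.edgeKey <- function(x, y) {
  if (x < y) paste(x, y, sep = "|") else paste(y, x, sep = "|")
}

.newEdgeState <- function(x, y) {
  if (x > y) { tmp <- x; x <- y; y <- tmp }
  list(x = x, y = y, status = "pending", contributors = character(0),
       info = NA_real_, cplx = NA_real_, shifted = NA_real_,
       nUsed = NA_integer_, rank = -Inf, nextCandidate = NA_character_,
       nextCore = NULL, sepSet = NULL,
       pXY = NA_real_, confidence = NA_real_, sign = NA_integer_)
}

#' Best next contributor of an edge
#'
#' Scans a candidate pool for the variable Z maximizing the shifted
#' conditional 3-point information
#' I'(X;Y;Z|{A}) = [I(X;Y|{A}) - I(X;Y|{A} u {Z})] - dk/n, the part of the
#' X-Y dependence explained away by also conditioning on Z, penalized by the
#' complexity increment dk that the extra conditioning variable costs. Only
#' strictly positive shifted gains qualify, so candidates whose apparent
#' contribution is within the finite-size noise floor are never collected.
#' Ties break on the lexicographically smallest candidate name.
#'
#' @param data a \linkS4class{CategoricalData} object.
#' @param x,y the edge endpoints.
#' @param contributors current conditioning set {A_i} of the edge.
#' @param searchSet candidate pool (x, y and current contributors are
#'   excluded automatically).
#' @param mode complexity criterion, "nml" or "bic".
#' @return \code{NULL} if no candidate has positive gain, else a list with
#'   \code{candidate}, \code{gain} (shifted 3-point information), and
#'   \code{core} (the InfoResult-like core of the extended conditioning).
#' @export
bestContributor <- function(data, x, y, contributors = character(0),
                            searchSet = varNames(data), mode = c("nml", "bic")) {
  mode <- match.arg(mode)
  pool <- sort(setdiff(searchSet, c(x, y, contributors)))
  if (!length(pool)) return(NULL)
  cur <- .condInfoCore(data, x, y, contributors, mode)
  best <- NULL
  bestGain <- 0
  for (z in pool) {
    cand <- .condInfoCore(data, x, y, c(contributors, z), mode)
    gain <- (cur$info - cand$info) -
      max(0, cand$cplx - cur$cplx) / cand$nUsed
    if (gain > bestGain) {
      bestGain <- gain
      best <- list(candidate = z, gain = gain, core = cand)
    }
  }
  best
}

#' Learn the graph skeleton (Step 1)
#'
#' Starting from a fully connected undirected graph, iteratively removes all
#' dispensable edges. Each edge XY collects its most likely contributors
#' {A_i} one at a time, in the order of a global edge ranking
#' R = n * I'(X;Y;A_n|{A_i}) of the best next contributor; after each
#' collection, the edge is removed if its complexity-penalized conditional
#' information I'(X;Y|{A_i}) drops to or below zero, the contributors then
#' serving as its separating set. With \code{latent = TRUE} contributors are
#' searched among all observed variables (required in the presence of latent
#' variables, where separating sets may contain non-adjacent nodes); with
#' \code{latent = FALSE} only current neighbors of X or Y are considered.
#'
#' A cheap pre-pass removes every pair whose unconditional I'(X;Y) <= 0
#' (equivalent to the first iteration on an empty conditioning set). Only the
#' touched edge's rank is refreshed per iteration; the global maximum is
#' re-selected each round. All ties break lexicographically, making the
#' procedure deterministic.
#'
#' @param data a \linkS4class{CategoricalData} object (>= 2 variables).
#' @param latent search contributors among all variables (TRUE, default) or
#'   neighbors only (FALSE).
#' @param mode complexity criterion, "nml" (default) or "bic".
#' @param verbose narrate removals (edge, separating set, I').
#' @return list with \code{graph} (a \linkS4class{MixedGraph}, all retained
#'   edges circle-circle) and \code{states} (per-pair edge records, named by
#'   "x|y" keys).
#' @export
learnSkeleton <- function(data, latent = TRUE, mode = c("nml", "bic"),
                          verbose = FALSE) {
  stopifnot(is(data, "CategoricalData"))
  mode <- match.arg(mode)
  vars <- varNames(data)
  if (length(vars) < 2L) stop("need at least 2 variables")
  const <- vars[vapply(data@levels, length, 1L) < 2L]
  if (length(const))
    warning(sprintf("constant column(s) carry no information: %s",
                    paste(const, collapse = ", ")))
  ord <- sort(vars)
  states <- list()
  # pre-pass: unconditional shifted information
  for (i in seq_len(length(ord) - 1L)) for (j in (i + 1L):length(ord)) {
    x <- ord[i]; y <- ord[j]
    st <- .newEdgeState(x, y)
    core <- .condInfoCore(data, x, y, character(0), mode)
    st$info <- core$info; st$cplx <- core$cplx; st$nUsed <- core$nUsed
    st$shifted <- core$info - core$cplx / core$nUsed
    if (st$shifted <= 0) {
      st$status <- "removed"; st$sepSet <- character(0)
      if (verbose) message(sprintf("remove %s-%s (unconditional, I' = %.4g)", x, y, st$shifted))
    }
    states[[.edgeKey(x, y)]] <- st
  }
  neighborsOf <- function(v) {
    nb <- character(0)
    for (st in states) if (st$status != "removed") {
      if (st$x == v) nb <- c(nb, st$y) else if (st$y == v) nb <- c(nb, st$x)
    }
    nb
  }
  searchFor <- function(st) {
    pool <- if (latent) vars else union(neighborsOf(st$x), neighborsOf(st$y))
    bestContributor(data, st$x, st$y, st$contributors, pool, mode)
  }
  # initial candidates for surviving edges
  for (k in names(states)) {
    st <- states[[k]]
    if (st$status != "pending") next
    cand <- searchFor(st)
    if (is.null(cand)) {
      st$status <- "retained"
    } else {
      st$nextCandidate <- cand$candidate
      st$nextCore <- cand$core
      st$rank <- st$nUsed * cand$gain
    }
    states[[k]] <- st
  }
  # priority loop (lazy refresh: only the touched edge is rescored)
  repeat {
    keys <- names(states)
    pend <- keys[vapply(states, function(s) s$status == "pending", TRUE)]
    if (!length(pend)) break
    ranks <- vapply(states[pend], function(s) s$rank, 0)
    top <- pend[order(-ranks, pend)][1L]
    st <- states[[top]]
    st$contributors <- c(st$contributors, st$nextCandidate)
    core <- st$nextCore
    st$info <- core$info; st$cplx <- core$cplx; st$nUsed <- core$nUsed
    st$shifted <- core$info - core$cplx / core$nUsed
    st$nextCandidate <- NA_character_; st$nextCore <- NULL; st$rank <- -Inf
    if (st$shifted <= 0) {
      st$status <- "removed"
      st$sepSet <- st$contributors
      if (verbose) message(sprintf("remove %s-%s | {%s} (I' = %.4g)", st$x, st$y,
                                   paste(st$sepSet, collapse = ","), st$shifted))
      states[[top]] <- st
    } else {
      cand <- searchFor(st)
      if (is.null(cand)) {
        st$status <- "retained"
      } else {
        st$nextCandidate <- cand$candidate
        st$nextCore <- cand$core
        st$rank <- st$nUsed * cand$gain
      }
      states[[top]] <- st
    }
  }
  list(graph = .skeletonGraph(vars, states), states = states)
}

.skeletonGraph <- function(nodes, states) {
  keep <- states[vapply(states, function(s) s$status != "removed", TRUE)]
  e <- if (length(keep)) {
    data.frame(x = vapply(keep, `[[`, "", "x"),
               y = vapply(keep, `[[`, "", "y"),
               markX = "circle", markY = "circle",
               stringsAsFactors = FALSE, row.names = NULL)
  } else .emptyEdges()
  new("MixedGraph", nodes = nodes, edges = e)
}

.emptyEdges <- function() {
  data.frame(x = character(0), y = character(0),
             markX = character(0), markY = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a MixedGraph
#'
#' @param nodes character node names.
#' @param edges data.frame with columns x, y, markX, markY (marks default to
#'   "circle" if absent); pairs are reordered so x < y (marks follow).
#' @return A \linkS4class{MixedGraph}.
#' @export
mixedGraph <- function(nodes, edges = NULL) {
  if (is.null(edges) || !nrow(edges)) {
    return(new("MixedGraph", nodes = nodes, edges = .emptyEdges()))
  }
  if (is.null(edges$markX)) edges$markX <- "circle"
  if (is.null(edges$markY)) edges$markY <- "circle"
  flip <- edges$x > edges$y
  if (any(flip)) {
    tmp <- edges$x[flip]; edges$x[flip] <- edges$y[flip]; edges$y[flip] <- tmp
    tmp <- edges$markX[flip]; edges$markX[flip] <- edges$markY[flip]; edges$markY[flip] <- tmp
  }
  edges <- edges[order(edges$x, edges$y), c("x", "y", "markX", "markY")]
  row.names(edges) <- NULL
  new("MixedGraph", nodes = nodes, edges = edges)
}

#' @rdname mixedGraph
#' @param object a MixedGraph.
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' @rdname mixedGraph
#' @export
setMethod("graphNodes", "MixedGraph", function(object) object@nodes)

#' @rdname mixedGraph
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname mixedGraph
#' @export
setMethod("graphEdges", "MixedGraph", function(object) object@edges)

setMethod("show", "MixedGraph", function(object) {
  e <- object@edges
  cat(sprintf("MixedGraph: %d nodes, %d edges\n", length(object@nodes), nrow(e)))
  if (nrow(e)) {
    sym <- c(tail = "-", arrow = ">", circle = "o")
    lsym <- c(tail = "-", arrow = "<", circle = "o")
    for (i in seq_len(min(nrow(e), 25L)))
      cat(sprintf("  %s %s-%s %s\n", e$x[i], lsym[[e$markX[i]]], sym[[e$markY[i]]], e$y[i]))
    if (nrow(e) > 25L) cat(sprintf("  ... and %d more\n", nrow(e) - 25L))
  }
})

# adjacency helpers ---------------------------------------------------------

.hasEdge <- function(graph, a, b) {
  e <- graph@edges
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  any(e$x == a & e$y == b)
}

.edgeIndex <- function(graph, a, b) {
  e <- graph@edges
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  which(e$x == a & e$y == b)
}

.neighbors <- function(graph, v) {
  e <- graph@edges
  sort(c(e$y[e$x == v], e$x[e$y == v]))
}

#' Edge category of each edge in a mixed graph
#'
#' Maps endpoint marks to the usual edge classes: tail-tail = undirected,
#' tail-arrow = directed, arrow-arrow = bidirected (the latent-common-cause
#' signature), anything involving a circle = partially-oriented.
#' @param graph a MixedGraph.
#' @return character vector, one entry per edge row.
#' @export
edgeCategories <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) return(character(0))
  vapply(seq_len(nrow(e)), function(i) {
    mx <- e$markX[i]; my <- e$markY[i]
    if (mx == "arrow" && my == "arrow") "bidirected"
    else if (mx == "tail" && my == "tail") "undirected"
    else if ((mx == "tail" && my == "arrow") || (mx == "arrow" && my == "tail")) "directed"
    else "partially-oriented"
  }, "")
}
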