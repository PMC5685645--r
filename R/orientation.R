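# Step 3: probabilistic orientation of unshielded triples from the sign of
# conditional 3-point information, with propagation and ancestral-graph
# consistency reporting.

#' Score all unshielded triples of a skeleton
#'
#' An unshielded triple <X, Z, Y> has X and Y both adjacent to the middle
#' node Z but not to each other. For each such triple the conditional
#' 3-point information I(X;Y;Z|{A_i}) is computed with the conditioning set
#' taken from the stored separating set of the pair (X, Y), minus Z if
#' present — the separating set is precisely the certificate that made X and
#' Y non-adjacent. A negative (complexity-shrunk) value is collider
#' evidence; the orientation probability is the logistic map
#' 1 / (1 + exp(n I'3)) (or its complement for non-v evidence).
#'
#' @param graph a \linkS4class{MixedGraph} skeleton.
#' @param states edge-state list from \code{\link{learnSkeleton}} (source of
#'   separating sets); may be NULL for an empty conditioning set.
#' @param data the \linkS4class{CategoricalData} the skeleton was learned on.
#' @param mode complexity criterion for the 3-point shrinkage.
#' @return data.frame with one row per triple: x, z, y, info3 (raw),
#'   shrunk, nUsed, kind ("v"/"non-v"), probability (of its kind, > 1/2
#'   only when the evidence is non-zero).
#' @export
unshieldedTriples <- function(graph, states = NULL, data = NULL,
                              mode = c("nml", "bic")) {
  mode <- match.arg(mode)
  rows <- list()
  for (z in sort(graph@nodes)) {
    nb <- .neighbors(graph, z)
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) for (j in (i + 1L):length(nb)) {
      x <- nb[i]; y <- nb[j]
      if (.hasEdge(graph, x, y)) next
      sep <- character(0)
      if (!is.null(states)) {
        st <- states[[.edgeKey(x, y)]]
        if (!is.null(st) && !is.null(st$sepSet)) sep <- setdiff(st$sepSet, z)
      }
      tp <- threePointInfo(data, x, y, z, sep, mode)
      pv <- tripleProbability(tp@shifted, tp@nUsed)
      kind <- if (tp@shifted < 0) "v" else "non-v"
      rows[[length(rows) + 1L]] <- data.frame(
        x = x, z = z, y = y, info3 = tp@info, shrunk = tp@shifted,
        nUsed = tp@nUsed, kind = kind, probability = max(pv, 1 - pv),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(x = character(0), z = character(0), y = character(0),
                      info3 = numeric(0), shrunk = numeric(0),
                      nUsed = integer(0), kind = character(0),
                      probability = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Orientation probability of a triple
#'
#' p_v = 1 / (1 + exp(n * info3)): exceeds 1/2 exactly when info3 < 0
#' (collider evidence), reaches 1/2 at the indifference point info3 = 0, and
#' tends to 1 as n * info3 -> -Inf. The non-v probability is 1 - p_v.
#'
#' @param info3 conditional 3-point information (nats; typically the
#'   complexity-shrunk value).
#' @param nUsed sample count.
#' @return probability that the triple is a v-structure.
#' @export
tripleProbability <- function(info3, nUsed) {
  1 / (1 + exp(nUsed * info3))
}

#' Orient a skeleton from scored triples
#'
#' Greedy loop over triples in decreasing orientation probability (ties
#' break lexicographically on x, z, y), applying the two rules until no
#' probability above 1/2 yields a new endpoint mark:
#' \itemize{
#'   \item collider evidence (shrunk info3 < 0) on X*-oZ o-*Y or X*->Z o-*Y:
#'     set arrowheads into Z on both edges (v-structure X -> Z <- Y);
#'   \item non-collider evidence (shrunk info3 > 0) on X*->Z o-o Y or
#'     X*->Z o->Y: propagate to Z -> Y (tail at Z, arrowhead at Y).
#' }
#' Marks set by earlier (higher-probability) assignments are never
#' overwritten; attempts to do so are logged as conflicts. Edges that end up
#' with arrowheads at both ends are bidirected — the signature of a latent
#' common cause. The adjacency structure is never modified.
#'
#' @param graph a \linkS4class{MixedGraph} skeleton (circle marks).
#' @param triples data.frame from \code{\link{unshieldedTriples}}.
#' @return list with \code{graph} (oriented MixedGraph) and
#'   \code{conflicts} (character log of refused overwrites).
#' @export
orientEdges <- function(graph, triples) {
  e <- graph@edges
  conflicts <- character(0)
  markAt <- function(a, b) { # mark at the a-end of edge {a,b}
    i <- .edgeIndex(graph, a, b)
    if (e[i, "x"] == a) e[i, "markX"] else e[i, "markY"]
  }
  setMark <- function(a, b, mark) { # returns TRUE if a mark changed
    i <- .edgeIndex(graph, a, b)
    col <- if (e[i, "x"] == a) "markX" else "markY"
    cur <- e[i, col]
    if (cur == mark) return(FALSE)
    if (cur != "circle") {
      conflicts <<- c(conflicts, sprintf(
        "refused %s mark at %s on edge %s-%s (already %s)", mark, a,
        e[i, "x"], e[i, "y"], cur))
      return(FALSE)
    }
    e[i, col] <<- mark
    TRUE
  }
  if (nrow(triples)) {
    triples <- triples[order(-triples$probability, triples$x, triples$z, triples$y), ,
                       drop = FALSE]
    repeat {
      changed <- FALSE
      for (t in seq_len(nrow(triples))) {
        if (triples$probability[t] <= 0.5) next
        x <- triples$x[t]; z <- triples$z[t]; y <- triples$y[t]
        mxz <- markAt(z, x); myz <- markAt(z, y)
        if (triples$kind[t] == "v") {
          # need both z-marks circle-or-arrow, at least one circle
          if (mxz %in% c("circle", "arrow") && myz %in% c("circle", "arrow") &&
              (mxz == "circle" || myz == "circle")) {
            if (setMark(z, x, "arrow")) changed <- TRUE
            if (setMark(z, y, "arrow")) changed <- TRUE
          }
        } else {
          # propagate x *-> z o-o y (or o->) to z -> y; and symmetrically
          if (mxz == "arrow" && myz == "circle") {
            if (setMark(z, y, "tail")) changed <- TRUE
            if (setMark(y, z, "arrow")) changed <- TRUE
          } else if (myz == "arrow" && mxz == "circle") {
            if (setMark(z, x, "tail")) changed <- TRUE
            if (setMark(x, z, "arrow")) changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  out <- new("MixedGraph", nodes = graph@nodes, edges = e)
  list(graph = out, conflicts = conflicts)
}

#' Ancestral-graph constraint violations
#'
#' Checks the three defining constraints of ancestral mixed graphs and
#' reports every violation found (an empty list certifies a valid ancestral
#' pattern): no directed cycles; no almost directed cycles (a directed path
#' between the two ends of a bidirected edge); no arrowheads pointing at a
#' node incident to an undirected (tail-tail) edge.
#'
#' @param graph a \linkS4class{MixedGraph}.
#' @return list of violation records (type + offending edge/path).
#' @export
ancestralViolations <- function(graph) {
  e <- graph@edges
  out <- list()
  if (!nrow(e)) return(out)
  cat2 <- edgeCategories(graph)
  # directed adjacency: tail -> arrow
  from <- character(0); to <- character(0)
  for (i in seq_len(nrow(e))) {
    if (e$markX[i] == "tail" && e$markY[i] == "arrow") {
      from <- c(from, e$x[i]); to <- c(to, e$y[i])
    } else if (e$markX[i] == "arrow" && e$markY[i] == "tail") {
      from <- c(from, e$y[i]); to <- c(to, e$x[i])
    }
  }
  reach <- function(a, b) { # directed path a ==> b?
    seen <- a; frontier <- a
    while (length(frontier)) {
      nxt <- unique(to[from %in% frontier])
      nxt <- setdiff(nxt, seen)
      if (b %in% nxt) return(TRUE)
      seen <- c(seen, nxt); frontier <- nxt
    }
    FALSE
  }
  for (k in seq_along(from)) {
    if (reach(to[k], from[k]))
      out[[length(out) + 1L]] <- list(type = "directed-cycle",
                                      edge = c(from[k], to[k]))
  }
  bidir <- which(cat2 == "bidirected")
  for (i in bidir) {
    a <- e$x[i]; b <- e$y[i]
    if (reach(a, b) || reach(b, a))
      out[[length(out) + 1L]] <- list(type = "almost-directed-cycle",
                                      edge = c(a, b))
  }
  undirected <- which(cat2 == "undirected")
  arrowAt <- unique(c(e$x[e$markX == "arrow"], e$y[e$markY == "arrow"]))
  for (i in undirected) {
    bad <- intersect(c(e$x[i], e$y[i]), arrowAt)
    for (v in bad)
      out[[length(out) + 1L]] <- list(type = "arrowhead-into-undirected",
                                      edge = c(e$x[i], e$y[i]), node = v)
  }
  out
}

#' V-structures present in a mixed graph
#'
#' Enumerates the unshielded colliders of a graph: triples <X, Z, Y> with X
#' and Y non-adjacent, both adjacent to Z, and arrowheads into Z on both
#' edges.
#'
#' @param graph a \linkS4class{MixedGraph}.
#' @return sorted character vector of "x|z|y" keys (x < y).
#' @export
vStructures <- function(graph) {
  e <- graph@edges
  out <- character(0)
  for (z in graph@nodes) {
    nb <- .neighbors(graph, z)
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) for (j in (i + 1L):length(nb)) {
      x <- nb[i]; y <- nb[j]
      if (.hasEdge(graph, x, y)) next
      ix <- .edgeIndex(graph, x, z)
      iy <- .edgeIndex(graph, y, z)
      mzx <- if (e$x[ix] == z) e$markX[ix] else e$markY[ix]
      mzy <- if (e$x[iy] == z) e$markX[iy] else e$markY[iy]
      if (mzx == "arrow" && mzy == "arrow")
        out <- c(out, paste(x, z, y, sep = "|"))
    }
  }
  sort(out)
}
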