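# Step 2: permutation-based edge-specific confidence ratios, filtering, and
# partial-correlation edge signs.

#' Confidence-assessment configuration
#'
#' @param nPermutations number of permutation replicates B (>= 1; default
#'   100 — the ratio-based confidence needs far fewer replicates than a
#'   p-value would, since for strong edges virtually every permutation gives
#'   a larger removal probability than the observed data).
#' @param threshold confidence cutoff; edges with C_XY at or above it are
#'   dropped by \code{\link{filterEdges}} (default 1e-3).
#' @param seed integer seed for the permutation draws.
#' @param fastMode if TRUE, permuted replicates score the unconditional
#'   shifted information only (approximation); the default re-runs the full
#'   per-pair contributor search on each replicate.
#' @return list of class "ConfidenceConfig".
#' @export
confidenceConfig <- function(nPermutations = 100L, threshold = 1e-3,
                             seed = 1L, fastMode = FALSE) {
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(nPermutations = as.integer(nPermutations),
                 threshold = threshold, seed = as.integer(seed),
                 fastMode = isTRUE(fastMode)),
            class = "ConfidenceConfig")
}

#' Probability that an edge is dispensable
#'
#' P_XY = min(1, exp(-n I'(X;Y|{A_i}))): the likelihood that the XY edge
#' should be removed given its conditional information. The shifted
#' (complexity-penalized) information is used, which absorbs the unknown
#' normalization of the raw exp(-N I) form; an edge at or below the
#' significance boundary (I' <= 0) gets probability 1.
#'
#' @param shifted the shifted conditional information I' of the edge (nats),
#'   or an edge-state list with fields \code{shifted} and \code{nUsed}.
#' @param nUsed sample count (ignored when \code{shifted} is an edge state).
#' @return removal probability in (0, 1].
#' @export
edgeProbability <- function(shifted, nUsed = NULL) {
  if (is.list(shifted)) { nUsed <- shifted$nUsed; shifted <- shifted$shifted }
  min(1, exp(-nUsed * shifted))
}

#' Edge-specific confidence ratio (permutation null)
#'
#' C_XY = P_XY / <P_XY^rand>: the ratio of the observed removal probability
#' to its average over datasets in which every variable's column has been
#' permuted independently, destroying all dependences while preserving
#' marginals (missing-value positions travel with their values). The lower
#' C_XY, the higher the confidence in the edge. By default each replicate
#' re-runs the full contributor search for the pair; \code{fastMode} scores
#' unconditional information only.
#'
#' @param data a \linkS4class{CategoricalData} object.
#' @param state an edge-state record from \code{\link{learnSkeleton}}.
#' @param cfg a \code{\link{confidenceConfig}}.
#' @param mode complexity criterion used for the permuted re-scores.
#' @return confidence ratio C_XY >= 0.
#' @export
confidenceRatio <- function(data, state, cfg = confidenceConfig(),
                            mode = c("nml", "bic")) {
  mode <- match.arg(mode)
  pObs <- edgeProbability(state)
  pRand <- .permutedRemovalProbs(data, state$x, state$y, cfg, mode)
  pObs / mean(pRand)
}

.permutedRemovalProbs <- function(data, x, y, cfg, mode) {
  set.seed(cfg$seed)
  n <- nSamples(data)
  vapply(seq_len(cfg$nPermutations), function(b) {
    perm <- data
    for (j in seq_len(ncol(perm@codes)))
      perm@codes[, j] <- perm@codes[sample.int(n), j]
    if (cfg$fastMode) {
      core <- .condInfoCore(perm, x, y, character(0), mode)
      edgeProbability(core$info - core$cplx / core$nUsed, core$nUsed)
    } else {
      st <- .pairSearch(perm, x, y, mode)
      edgeProbability(st$shifted, st$nUsed)
    }
  }, 0)
}

# per-pair contributor collection (the Step-1 inner loop restricted to one
# pair, search set = all other variables)
.pairSearch <- function(data, x, y, mode) {
  core <- .condInfoCore(data, x, y, character(0), mode)
  contributors <- character(0)
  shifted <- core$info - core$cplx / core$nUsed
  repeat {
    if (shifted <= 0) break
    cand <- bestContributor(data, x, y, contributors, varNames(data), mode)
    if (is.null(cand)) break
    contributors <- c(contributors, cand$candidate)
    core <- cand$core
    shifted <- core$info - core$cplx / core$nUsed
  }
  list(contributors = contributors, info = core$info, cplx = core$cplx,
       shifted = shifted, nUsed = core$nUsed)
}

#' Filter edges on their confidence ratio
#'
#' Drops every edge whose C_XY is at or above the threshold; survivors (and
#' their endpoint marks) are untouched. Idempotent, and monotone in the
#' threshold.
#'
#' @param graph a \linkS4class{MixedGraph}.
#' @param states edge-state list with \code{confidence} filled.
#' @param threshold confidence cutoff (default 1e-3).
#' @return the filtered MixedGraph.
#' @export
filterEdges <- function(graph, states, threshold = 1e-3) {
  e <- graph@edges
  if (!nrow(e)) return(graph)
  keep <- vapply(seq_len(nrow(e)), function(i) {
    st <- states[[.edgeKey(e$x[i], e$y[i])]]
    cxy <- if (is.null(st)) NA_real_ else st$confidence
    is.na(cxy) || cxy < threshold
  }, TRUE)
  new("MixedGraph", nodes = graph@nodes, edges = {
    ee <- e[keep, , drop = FALSE]; row.names(ee) <- NULL; ee
  })
}

#' Sign of a retained edge
#'
#' Sign of the partial correlation coefficient rho_{XY.A} between the
#' integer-coded levels of X and Y given the edge's contributors {A_i}:
#' the correlation of the residuals of X and Y after regressing each on the
#' contributors (numerically identical to the precision-matrix form, but
#' robust to perfectly correlated pairs). Levels are encoded by their rank
#' in sorted label order, so ordered labels ("0"/"1", "low"/"normal"/...)
#' map onto a monotone numeric scale. Degenerate cases (zero residual
#' variance) give 0. A negative sign marks a partial anti-correlation.
#'
#' @param data a \linkS4class{CategoricalData} object.
#' @param state edge-state record (fields x, y, contributors), or NULL if
#'   \code{x}, \code{y}, \code{cond} given directly.
#' @param x,y,cond direct specification, used when \code{state} is NULL.
#' @return +1, -1 or 0.
#' @export
edgeSign <- function(data, state = NULL, x = NULL, y = NULL, cond = character(0)) {
  if (!is.null(state)) { x <- state$x; y <- state$y; cond <- state$contributors }
  vars <- c(x, y, cond)
  cd <- data@codes[, vars, drop = FALSE]
  cd <- cd[stats::complete.cases(cd), , drop = FALSE]
  if (nrow(cd) < 3L) return(0L)
  M <- .numericCodes(data, vars, cd)
  if (length(cond)) {
    A <- cbind(1, M[, -(1:2), drop = FALSE])
    rx <- stats::lm.fit(A, M[, 1L])$residuals
    ry <- stats::lm.fit(A, M[, 2L])$residuals
  } else {
    rx <- M[, 1L] - mean(M[, 1L])
    ry <- M[, 2L] - mean(M[, 2L])
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(0L)
  rho <- stats::cor(rx, ry)
  if (!is.finite(rho) || rho == 0) return(0L)
  as.integer(sign(rho))
}

#' Compute confidences and signs for all retained edges
#'
#' Convenience wrapper running \code{\link{confidenceRatio}} and
#' \code{\link{edgeSign}} over every retained edge state, filling the
#' \code{pXY}, \code{confidence} and \code{sign} fields. Each edge's
#' permutation stream is seeded independently (base seed + edge index) so
#' results do not depend on edge evaluation order.
#'
#' @inheritParams confidenceRatio
#' @param states edge-state list from \code{\link{learnSkeleton}}.
#' @return the updated states list.
#' @export
assessConfidence <- function(data, states, cfg = confidenceConfig(),
                             mode = c("nml", "bic")) {
  mode <- match.arg(mode)
  keys <- sort(names(states))
  for (i in seq_along(keys)) {
    st <- states[[keys[i]]]
    if (st$status == "removed") next
    st$pXY <- edgeProbability(st)
    ecfg <- cfg
    ecfg$seed <- cfg$seed + i
    st$confidence <- confidenceRatio(data, st, ecfg, mode)
    st$sign <- edgeSign(data, st)
    states[[keys[i]]] <- st
  }
  states
}
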