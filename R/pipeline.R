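# Pipeline orchestration: Steps 1-3, edge-summary emission, run report.

#' Pipeline configuration
#'
#' @param latent search contributors among all variables (default TRUE).
#' @param complexity "nml" (default) or "bic".
#' @param confidence a \code{\link{confidenceConfig}}; NULL skips Step 2
#'   entirely (no confidences, no filtering).
#' @param orient run Step 3 (default TRUE).
#' @param propagate apply the non-v propagation rule (default TRUE; FALSE
#'   keeps only v-structure orientations).
#' @param nEff optional effective sample size forced onto the data.
#' @param seed integer seed (base seed for permutation replicates).
#' @param verbose narrate Step-1 removals.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(latent = TRUE, complexity = c("nml", "bic"),
                           confidence = confidenceConfig(), orient = TRUE,
                           propagate = TRUE, nEff = NA_integer_, seed = 1L,
                           verbose = FALSE) {
  complexity <- match.arg(complexity)
  structure(list(latent = isTRUE(latent), complexity = complexity,
                 confidence = confidence, orient = isTRUE(orient),
                 propagate = isTRUE(propagate), nEff = as.integer(nEff),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "PipelineConfig")
}

#' Run the full reconstruction pipeline
#'
#' Executes the three steps in order: (1) learn the skeleton by iterative
#' removal of dispensable edges with contributor collection; (2) assess
#' edge-specific permutation confidences and partial-correlation signs, and
#' filter low-confidence edges; (3) orient unshielded triples from the sign
#' of conditional 3-point information and propagate. Returns the final
#' mixed graph, the per-edge states, and a run report sufficient to re-run
#' the pipeline identically.
#'
#' @param data a \linkS4class{CategoricalData} object.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with \code{graph}, \code{states}, \code{triples}, and
#'   \code{report}.
#' @export
runPipeline <- function(data, cfg = pipelineConfig()) {
  stopifnot(is(data, "CategoricalData"))
  t0 <- proc.time()[["elapsed"]]
  if (!is.na(cfg$nEff)) effectiveSamples(data) <- cfg$nEff
  set.seed(cfg$seed)
  sk <- learnSkeleton(data, latent = cfg$latent, mode = cfg$complexity,
                      verbose = cfg$verbose)
  graph <- sk$graph
  states <- sk$states
  edgesBefore <- nrow(graph@edges)
  if (!is.null(cfg$confidence)) {
    ccfg <- cfg$confidence
    ccfg$seed <- cfg$seed
    states <- assessConfidence(data, states, ccfg, mode = cfg$complexity)
    graph <- filterEdges(graph, states, ccfg$threshold)
  }
  edgesAfter <- nrow(graph@edges)
  triples <- NULL
  conflicts <- character(0)
  if (cfg$orient) {
    triples <- unshieldedTriples(graph, states, data, mode = cfg$complexity)
    if (!cfg$propagate && nrow(triples))
      triples <- triples[triples$kind == "v", , drop = FALSE]
    ori <- orientEdges(graph, triples)
    graph <- ori$graph
    conflicts <- ori$conflicts
  }
  naCounts <- vapply(states, function(s) s$nUsed, 0L)
  report <- list(
    config = unclass(cfg)[setdiff(names(cfg), "verbose")],
    seed = cfg$seed,
    nSamples = nSamples(data),
    nVariables = nVariables(data),
    nUsedRange = if (length(naCounts)) range(naCounts) else c(NA, NA),
    nEff = effectiveSamples(data),
    edgesBeforeFilter = edgesBefore,
    edgesAfterFilter = edgesAfter,
    conflicts = conflicts,
    ancestralViolations = ancestralViolations(graph),
    wallTime = proc.time()[["elapsed"]] - t0)
  list(graph = graph, states = states, triples = triples, report = report)
}

#' Per-edge summary table
#'
#' Assembles the 13-column edge summary: endpoints, contributors, sample
#' count, information, complexity, shifted information, removal probability,
#' confidence, sign, endpoint marks and edge category. Retained edges come
#' first; removed edges can be appended with category "removed" and their
#' separating set in the contributor column.
#'
#' @param states edge-state list.
#' @param graph the final \linkS4class{MixedGraph}.
#' @param includeRemoved append removed edges (default FALSE).
#' @return data.frame with columns x, y, ai, n_xy_ai, info, cplx,
#'   info_shifted, p_xy, confidence, sign, endpoint_x, endpoint_y, category.
#' @export
edgeSummary <- function(states, graph, includeRemoved = FALSE) {
  e <- graph@edges
  cats <- edgeCategories(graph)
  rows <- list()
  for (i in seq_len(nrow(e))) {
    st <- states[[.edgeKey(e$x[i], e$y[i])]]
    rows[[length(rows) + 1L]] <- data.frame(
      x = e$x[i], y = e$y[i],
      ai = paste(st$contributors, collapse = ","),
      n_xy_ai = st$nUsed, info = st$info, cplx = st$cplx,
      info_shifted = st$shifted, p_xy = st$pXY, confidence = st$confidence,
      sign = st$sign, endpoint_x = e$markX[i], endpoint_y = e$markY[i],
      category = cats[i], stringsAsFactors = FALSE)
  }
  if (includeRemoved) {
    for (k in sort(names(states))) {
      st <- states[[k]]
      if (st$status != "removed") next
      rows[[length(rows) + 1L]] <- data.frame(
        x = st$x, y = st$y, ai = paste(st$sepSet, collapse = ","),
        n_xy_ai = st$nUsed, info = st$info, cplx = st$cplx,
        info_shifted = st$shifted, p_xy = NA_real_, confidence = NA_real_,
        sign = NA_integer_, endpoint_x = "", endpoint_y = "",
        category = "removed", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(x = character(0), y = character(0), ai = character(0),
                      n_xy_ai = integer(0), info = numeric(0), cplx = numeric(0),
                      info_shifted = numeric(0), p_xy = numeric(0),
                      confidence = numeric(0), sign = integer(0),
                      endpoint_x = character(0), endpoint_y = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Write the edge summary to a TSV file
#'
#' @inheritParams edgeSummary
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEdgeSummary <- function(states, graph, path, includeRemoved = FALSE) {
  df <- edgeSummary(states, graph, includeRemoved = includeRemoved)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge summary back into a MixedGraph
#'
#' Inverse of \code{\link{writeEdgeSummary}} for the retained rows; node
#' names default to those appearing in the edges unless supplied.
#'
#' @param path edge-summary TSV path.
#' @param nodes optional full node set.
#' @return A \linkS4class{MixedGraph}.
#' @export
readEdgeSummary <- function(path, nodes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  df <- df[df$category != "removed", , drop = FALSE]
  if (is.null(nodes)) nodes <- sort(unique(c(df$x, df$y)))
  mixedGraph(nodes, if (nrow(df)) data.frame(
    x = df$x, y = df$y, markX = df$endpoint_x, markY = df$endpoint_y,
    stringsAsFactors = FALSE) else NULL)
}
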