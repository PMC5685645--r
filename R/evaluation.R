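# Skeleton and endpoint-aware precision/recall/F-score against a reference
# mixed graph.

.pairKeys <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) return(character(0))
  paste(e$x, e$y, sep = "|")
}

.metricsReport <- function(tp, fp, fn, mis, mode) {
  tpp <- tp - mis
  fpp <- fp + mis
  prec <- if (tpp + fpp > 0) tpp / (tpp + fpp) else if (fn + mis > 0) 0 else 1
  rec  <- if (tp + fn > 0) tpp / (tp + fn) else if (fpp > 0) 0 else 1
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  if (tp + fp + fn + mis == 0) { prec <- 1; rec <- 1; f <- 1 } # both graphs empty
  new("MetricsReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tpMisorient = as.integer(mis),
      precision = prec, recall = rec, fscore = f, mode = mode)
}

#' Skeleton precision/recall/F-score
#'
#' Compares unordered adjacencies of a predicted graph against a reference:
#' Prec = TP / (TP + FP), Rec = TP / (TP + FN), F = 2 P R / (P + R). An
#' empty prediction against a non-empty reference scores 0; two empty
#' graphs score 1.
#'
#' @param pred,ref \linkS4class{MixedGraph}s over the same node set.
#' @return A \linkS4class{MetricsReport} with mode "skeleton".
#' @export
skeletonMetrics <- function(pred, ref) {
  if (!setequal(pred@nodes, ref@nodes)) stop("node sets differ")
  kp <- .pairKeys(pred); kr <- .pairKeys(ref)
  tp <- length(intersect(kp, kr))
  .metricsReport(tp, length(kp) - tp, length(kr) - tp, 0L, "skeleton")
}

#' Endpoint-aware precision/recall/F-score
#'
#' As \code{\link{skeletonMetrics}}, but true-positive adjacencies whose
#' endpoint marks disagree with the reference on arrowhead status (arrowhead
#' versus tail-or-circle, at either end; tail-versus-circle differences are
#' not penalized) are counted as misoriented and moved to the false-positive
#' side: TP' = TP - TP_misorient and FP' = FP + TP_misorient.
#'
#' @inheritParams skeletonMetrics
#' @return A \linkS4class{MetricsReport} with mode "endpoint".
#' @export
endpointMetrics <- function(pred, ref) {
  if (!setequal(pred@nodes, ref@nodes)) stop("node sets differ")
  kp <- .pairKeys(pred); kr <- .pairKeys(ref)
  common <- intersect(kp, kr)
  mis <- 0L
  for (k in common) {
    ip <- match(k, kp); ir <- match(k, kr)
    pm <- c(pred@edges$markX[ip], pred@edges$markY[ip]) == "arrow"
    rm <- c(ref@edges$markX[ir], ref@edges$markY[ir]) == "arrow"
    if (any(pm != rm)) mis <- mis + 1L
  }
  .metricsReport(length(common), length(kp) - length(common),
                 length(kr) - length(common), mis, "endpoint")
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s): TP=%d FP=%d FN=%d%s  Prec=%.3f Rec=%.3f F=%.3f\n",
              object@mode, object@tp, object@fp, object@fn,
              if (object@mode == "endpoint")
                sprintf(" TPmis=%d", object@tpMisorient) else "",
              object@precision, object@recall, object@fscore))
})

#' @rdname skeletonMetrics
#' @param object a MetricsReport.
#' @export
setGeneric("fscore", function(object) standardGeneric("fscore"))

#' @rdname skeletonMetrics
#' @export
setMethod("fscore", "MetricsReport", function(object) object@fscore)
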