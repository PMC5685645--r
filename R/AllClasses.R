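#' @import methods
NULL

#' CategoricalData: an N x P table of categorical observations
#'
#' Core data container for the package. Observations are stored as integer
#' level codes (1-based indices into per-variable level label vectors), with
#' \code{NA} marking missing values. An optional effective sample size
#' \code{nEff} overrides the nominal number of rows in every finite-size
#' (complexity and edge-probability) term, which is how autocorrelated
#' samples (e.g. consecutive Monte Carlo configurations) are handled.
#'
#' @slot codes integer matrix, N rows (samples) x P columns (variables);
#'   \code{NA} encodes a missing value.
#' @slot levels named list of character vectors; per-variable level labels in
#'   first-appearance order. Codes index into these vectors.
#' @slot nEff integer; effective number of independent samples, or
#'   \code{NA_integer_} when the nominal N applies.
#'
#' @export
setClass("CategoricalData",
  representation(codes = "matrix", levels = "list", nEff = "integer"),
  prototype(nEff = NA_integer_)
)

setValidity("CategoricalData", function(object) {
  msgs <- character(0)
  cd <- object@codes
  lv <- object@levels
  if (!is.integer(cd)) msgs <- c(msgs, "codes must be an integer matrix")
  if (is.null(colnames(cd))) msgs <- c(msgs, "codes must have column names")
  if (!identical(colnames(cd), names(lv)))
    msgs <- c(msgs, "names(levels) must match colnames(codes)")
  for (j in seq_along(lv)) {
    l <- lv[[j]]
    if (length(l) < 1L) msgs <- c(msgs, sprintf("empty level set for '%s'", names(lv)[j]))
    if (anyDuplicated(l)) msgs <- c(msgs, sprintf("duplicate levels for '%s'", names(lv)[j]))
    v <- cd[, j]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < 1L || max(v) > length(l)))
      msgs <- c(msgs, sprintf("codes out of level range for '%s'", names(lv)[j]))
  }
  if (!is.na(object@nEff) && (object@nEff < 1L || object@nEff > nrow(cd)))
    msgs <- c(msgs, "nEff must satisfy 1 <= nEff <= N")
  if (length(msgs)) msgs else TRUE
})

#' ContingencyTable: multi-way counts over a variable tuple
#'
#' Counts are computed on complete cases only: rows with a missing value in
#' any variable of the tuple are dropped, and \code{nAvailable} records the
#' number of rows actually used.
#'
#' @slot counts integer/numeric array; one dimension per variable, extents
#'   equal to the full level-set sizes.
#' @slot nAvailable integer; number of complete cases the counts are built on.
#' @slot vars character; variable names, in dimension order.
#' @export
setClass("ContingencyTable",
  representation(counts = "array", nAvailable = "integer", vars = "character")
)

setValidity("ContingencyTable", function(object) {
  if (any(object@counts < 0)) return("negative counts")
  if (!isTRUE(all.equal(sum(object@counts), as.numeric(object@nAvailable))))
    return("counts must sum to nAvailable")
  TRUE
})

#' InfoResult: an information value with its finite-size correction
#'
#' @slot info numeric; plug-in (conditional) information in nats.
#' @slot complexity numeric; complexity penalty k >= 0 in nats.
#' @slot shifted numeric; info - complexity / nUsed.
#' @slot nUsed integer; sample count entering the correction (the effective
#'   sample size when set, otherwise the number of complete cases).
#' @export
setClass("InfoResult",
  representation(info = "numeric", complexity = "numeric",
                 shifted = "numeric", nUsed = "integer")
)

#' MixedGraph: endpoint-marked mixed graph
#'
#' Edges are unordered pairs carrying an endpoint mark at each end, one of
#' \code{"tail"} (-), \code{"arrow"} (>) or \code{"circle"} (o). Undirected
#' (tail-tail), directed (tail-arrow) and bidirected (arrow-arrow) edges are
#' all representable, as are partially oriented edges with circle marks.
#'
#' @slot nodes character vector of node names.
#' @slot edges data.frame with columns \code{x}, \code{y}, \code{markX},
#'   \code{markY}; \code{x < y} lexicographically; marks at the x- and y-ends.
#' @export
setClass("MixedGraph",
  representation(nodes = "character", edges = "data.frame")
)

.validMarks <- c("tail", "arrow", "circle")

setValidity("MixedGraph", function(object) {
  e <- object@edges
  if (!all(c("x", "y", "markX", "markY") %in% names(e)))
    return("edges needs columns x, y, markX, markY")
  if (nrow(e)) {
    if (!all(e$x %in% object@nodes) || !all(e$y %in% object@nodes))
      return("edge endpoints must be graph nodes")
    if (any(e$x >= e$y)) return("edges must satisfy x < y")
    if (anyDuplicated(paste(e$x, e$y))) return("duplicate edges")
    if (!all(e$markX %in% .validMarks) || !all(e$markY %in% .validMarks))
      return("endpoint marks must be tail/arrow/circle")
  }
  TRUE
})

#' BayesNet: a discrete Bayesian network (DAG + multinomial CPTs)
#'
#' @slot nodes character; node names in a fixed topological order.
#' @slot parents named list of character vectors (parents per node).
#' @slot levels named integer vector; number of levels per node.
#' @slot cpts named list; per node, a matrix with one row per parent-level
#'   configuration (row-major in parent order) and one column per own level;
#'   rows sum to 1.
#' @export
setClass("BayesNet",
  representation(nodes = "character", parents = "list",
                 levels = "integer", cpts = "list")
)

setValidity("BayesNet", function(object) {
  for (v in object@nodes) {
    cpt <- object@cpts[[v]]
    if (ncol(cpt) != object@levels[[v]]) return(sprintf("CPT of %s has wrong width", v))
    if (any(abs(rowSums(cpt) - 1) > 1e-12)) return(sprintf("CPT rows of %s must sum to 1", v))
    for (p in object@parents[[v]]) {
      if (match(p, object@nodes) >= match(v, object@nodes))
        return("nodes must be listed in topological order")
    }
  }
  TRUE
})

#' IsingModel: pairwise-interacting binary spins
#'
#' Spins take values in {-1, +1}; the energy of a configuration x is
#' E(x) = -sum over edges of k_ij x_i x_j, with symmetric couplings.
#'
#' @slot nodes character vector of spin names.
#' @slot couplings numeric symmetric matrix of k_ij (zero diagonal); zero
#'   entries mean no interaction.
#' @export
setClass("IsingModel",
  representation(nodes = "character", couplings = "matrix")
)

setValidity("IsingModel", function(object) {
  K <- object@couplings
  if (nrow(K) != length(object@nodes) || ncol(K) != length(object@nodes))
    return("couplings must be P x P")
  if (max(abs(K - t(K))) > 1e-12) return("couplings must be symmetric")
  if (any(diag(K) != 0)) return("couplings must have zero diagonal")
  TRUE
})

#' MetricsReport: precision/recall/F against a reference graph
#'
#' @slot tp,fp,fn integers; true/false positives and false negatives on
#'   unordered adjacencies.
#' @slot tpMisorient integer; true-positive adjacencies whose arrowhead marks
#'   disagree with the reference (endpoint mode only; 0 in skeleton mode).
#' @slot precision,recall,fscore numerics in [0, 1].
#' @slot mode character; "skeleton" or "endpoint".
#' @export
setClass("MetricsReport",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tpMisorient = "integer", precision = "numeric",
                 recall = "numeric", fscore = "numeric", mode = "character")
)

#' AutocorrFit: exponential fit of a sample-autocorrelation decay
#'
#' @slot c0 numeric; pooled lag-0 variance.
#' @slot c numeric; normalized autocorrelation per lag (c[n] for lag n).
#' @slot alpha numeric; fitted per-step decay in [0, 1).
#' @slot decayLength numeric; R = -1 / log(alpha) (0 when alpha = 0).
#' @slot nEff integer; round(N (1 - alpha) / (1 + alpha)).
#' @slot n integer; series length N.
#' @export
setClass("AutocorrFit",
  representation(c0 = "numeric", c = "numeric", alpha = "numeric",
                 decayLength = "numeric", nEff = "integer", n = "integer")
)
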