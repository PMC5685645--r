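#' Multi-way contingency table on complete cases
#'
#' Tabulates the joint counts of a tuple of categorical variables using only
#' the rows where none of them is missing; the number of rows actually used,
#' N_a, is recorded and is the basis of all finite-size corrections (missing
#' values are assumed missing completely at random).
#'
#' @param data a \linkS4class{CategoricalData} object.
#' @param vars character vector of variable names (non-empty).
#' @return A \linkS4class{ContingencyTable}.
#' @examples
#' d <- categoricalData(data.frame(X = c("a","b","a","b"), Y = c("u","u","v","v")))
#' contingencyTable(d, c("X", "Y"))
#' @export
contingencyTable <- function(data, vars) {
  stopifnot(is(data, "CategoricalData"))
  if (!length(vars)) stop("vars must be non-empty")
  unknown <- setdiff(vars, varNames(data))
  if (length(unknown)) stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")))
  cnt <- .jointCounts(data, vars)
  if (attr(cnt, "n") == 0L)
    stop("degenerate input: no complete cases for the requested variables")
  new("ContingencyTable", counts = cnt, nAvailable = attr(cnt, "n"), vars = vars)
}

# Fast joint tabulation: mixed-radix index over complete cases, tabulate().
# Returns a counts array with dim = level sizes and attr "n" = N_a.
.jointCounts <- function(data, vars) {
  cd <- data@codes[, vars, drop = FALSE]
  r <- .nLevels(data, vars)
  ok <- !is.na(cd[, 1L])
  if (ncol(cd) > 1L) for (k in 2:ncol(cd)) ok <- ok & !is.na(cd[, k])
  cd <- cd[ok, , drop = FALSE]
  idx <- cd[, 1L]
  mult <- r[[1L]]
  if (ncol(cd) > 1L) for (k in 2:ncol(cd)) {
    idx <- idx + (cd[, k] - 1L) * mult
    mult <- mult * r[[k]]
  }
  cnt <- tabulate(idx, nbins = mult)
  dim(cnt) <- r
  attr(cnt, "n") <- nrow(cd)
  cnt
}

#' Plug-in entropy of a contingency table
#'
#' Maximum-likelihood (plug-in) Shannon entropy -sum p log p in nats, with
#' the convention 0 log 0 = 0.
#'
#' @param table a \linkS4class{ContingencyTable} (or a bare count vector/array).
#' @return entropy in nats (>= 0).
#' @export
plugInEntropy <- function(table) {
  cnt <- if (is(table, "ContingencyTable")) table@counts else table
  n <- sum(cnt)
  if (n < 1) stop("empty table")
  .entCounts(cnt, n)
}

.entCounts <- function(cnt, n) {
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

# Core engine: conditional mutual information I(X;Y|{A}) plus complexity,
# from a single sparse joint tabulation over (X, Y, A...) complete cases.
# Joint cells are counted by sorting the mixed-radix cell index (double
# arithmetic: the index space may exceed 2^31), and margins are grouped
# sums over the non-empty cells only, so cost is O(N log N) regardless of
# the nominal table dimensions. Returns list(info, cplx, nAvail, nUsed).
.condInfoCore <- function(data, x, y, cond = character(0),
                          mode = c("nml", "bic")) {
  mode <- match.arg(mode)
  vars <- c(x, y, cond)
  cd <- data@codes[, vars, drop = FALSE]
  r <- .nLevels(data, vars)
  cd <- cd[stats::complete.cases(cd), , drop = FALSE]
  n <- nrow(cd)
  if (n == 0L) stop("degenerate input: no complete cases")
  rx <- r[[1L]]; ry <- r[[2L]]
  idx <- as.numeric(cd[, 1L])
  mult <- as.numeric(rx)
  if (ncol(cd) > 1L) for (k in 2:ncol(cd)) {
    idx <- idx + (cd[, k] - 1) * mult
    mult <- mult * r[[k]]
  }
  rl <- rle(sort.int(idx, method = "quick"))
  cells <- rl$lengths                       # non-empty joint cell counts
  rest <- (rl$values - 1) %/% rx            # (iy - 1) + (is - 1) * ry
  ixm1 <- (rl$values - 1) %% rx
  ism1 <- rest %/% ry
  iym1 <- rest %% ry
  cXA <- as.vector(rowsum(cells, ixm1 + rx * ism1))   # counts per (X, A) cell
  cYA <- as.vector(rowsum(cells, iym1 + ry * ism1))   # counts per (Y, A) cell
  nA  <- if (length(cond)) as.vector(rowsum(cells, ism1)) else n
  hXYA <- .entCounts(cells, n)
  hXA  <- .entCounts(cXA, n)
  hYA  <- .entCounts(cYA, n)
  hA   <- if (length(cond)) .entCounts(nA, n) else 0
  info <- hXA + hYA - hA - hXYA
  if (info < 0 && info > -1e-12) info <- 0
  nUsed <- .nUsed(data, n)
  nStrataA <- if (length(cond)) prod(r[-(1:2)]) else 1
  cplx <- .complexityCore(rx, ry, nStrataA, nA, cXA, cYA, n, nUsed, mode)
  list(info = info, cplx = cplx, nAvail = n, nUsed = nUsed)
}

.infoResult <- function(core) {
  new("InfoResult", info = core$info, complexity = core$cplx,
      shifted = core$info - core$cplx / core$nUsed,
      nUsed = as.integer(core$nUsed))
}

#' Conditional mutual information with finite-size complexity
#'
#' Computes the plug-in conditional mutual information
#' I(X;Y|{A_i}) = -H({A}) + H(X,{A}) + H(Y,{A}) - H(X,Y,{A}) on the complete
#' cases of the full tuple, together with a complexity penalty k (BIC/MDL or
#' decomposable NML) and the shifted value I' = I - k/n used throughout the
#' skeleton step. An empty conditioning set gives the plain mutual
#' information.
#'
#' @param data a \linkS4class{CategoricalData} object.
#' @param x,y variable names (distinct, not in \code{cond}).
#' @param cond character vector of conditioning variables (may be empty).
#' @param mode complexity criterion, \code{"nml"} (default) or \code{"bic"}.
#' @return An \linkS4class{InfoResult}.
#' @examples
#' d <- categoricalData(data.frame(X = c("a","a","a","b","b","b"),
#'                                 Y = c("u","u","v","u","v","v")))
#' condMutualInfo(d, "X", "Y")  # ~0.0566 nats
#' @export
condMutualInfo <- function(data, x, y, cond = character(0), mode = c("nml", "bic")) {
  stopifnot(is(data, "CategoricalData"))
  if (x == y) stop("x and y must differ")
  if (x %in% cond || y %in% cond) stop("x and y must not be in cond")
  mode <- match.arg(mode)
  if (length(data@levels[[x]]) < 2L || length(data@levels[[y]]) < 2L)
    warning("single-level variable: information is 0")
  .infoResult(.condInfoCore(data, x, y, cond, mode))
}

#' Multivariate (interaction) information
#'
#' Inclusion-exclusion alternating sum of subset entropies over p variables:
#' sum_S (-1)^(|S|-1) H(S). For p = 2 this is the mutual information; for
#' p = 3 the 3-point information, which may be negative. All entropies are
#' computed on the complete cases of the full tuple so the alternating sum is
#' internally consistent.
#'
#' @param data a \linkS4class{CategoricalData} object.
#' @param vars character vector of >= 2 variable names (at most 12: the
#'   number of entropy terms grows as 2^p).
#' @return interaction information in nats.
#' @export
multivariateInformation <- function(data, vars) {
  stopifnot(is(data, "CategoricalData"))
  p <- length(vars)
  if (p < 2L) stop("need at least 2 variables")
  if (p > 12L) stop("more than 12 variables rejected (2^p subset blow-up)")
  cnt <- .jointCounts(data, vars)
  n <- attr(cnt, "n")
  if (n == 0L) stop("degenerate input: no complete cases")
  total <- 0
  for (k in seq_len(p)) {
    sgn <- (-1)^(k - 1)
    for (S in utils::combn(p, k, simplify = FALSE)) {
      m <- if (k == p) cnt else apply(cnt, S, sum)
      total <- total + sgn * .entCounts(m, n)
    }
  }
  total
}

#' Conditional 3-point information
#'
#' I(X;Y;Z|{A}) = I(X;Y|{A}) - I(X;Y|{A} u {Z}), computed on the complete
#' cases of the full (X, Y, Z, {A}) tuple so that the defining difference is
#' exact. A negative value is evidence for a collider (v-structure) at Z; a
#' positive value means Z contributes part of the X-Y information (e.g. an
#' intermediate node). The returned complexity is the increment
#' k(X;Y|{A} u Z) - k(X;Y|{A}) incurred by conditioning on Z, and
#' \code{shifted} is the signed value shrunk toward zero by that increment
#' over n (weak 3-point signals are thereby treated as noise).
#'
#' @inheritParams condMutualInfo
#' @param z third variable (distinct from x, y, and not in cond).
#' @return An \linkS4class{InfoResult}; \code{info} holds the raw 3-point
#'   value, \code{shifted} its complexity-shrunk version.
#' @export
threePointInfo <- function(data, x, y, z, cond = character(0), mode = c("nml", "bic")) {
  stopifnot(is(data, "CategoricalData"))
  if (anyDuplicated(c(x, y, z))) stop("x, y, z must be distinct")
  if (z %in% cond) stop("z must not be in cond")
  mode <- match.arg(mode)
  # both terms on the same complete-case basis: restrict to the full tuple
  sub <- .completeSubset(data, c(x, y, z, cond))
  a <- .condInfoCore(sub, x, y, cond, mode)
  b <- .condInfoCore(sub, x, y, c(cond, z), mode)
  i3 <- a$info - b$info
  dk <- max(0, b$cplx - a$cplx)
  shrunk <- if (i3 > 0) max(0, i3 - dk / b$nUsed) else min(0, i3 + dk / b$nUsed)
  new("InfoResult", info = i3, complexity = dk, shifted = shrunk,
      nUsed = as.integer(b$nUsed))
}

# restrict a CategoricalData to rows complete in `vars` (keeps all columns of
# vars only; preserves nEff)
.completeSubset <- function(data, vars) {
  cd <- data@codes[, unique(vars), drop = FALSE]
  ok <- stats::complete.cases(cd)
  new("CategoricalData", codes = cd[ok, , drop = FALSE],
      levels = data@levels[unique(vars)], nEff = data@nEff)
}

setMethod("show", "InfoResult", function(object) {
  cat(sprintf("InfoResult: info = %.6g nats, complexity = %.6g, shifted = %.6g (n = %d)\n",
              object@info, object@complexity, object@shifted, object@nUsed))
})

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable over (%s): %s cells, N_a = %d\n",
              paste(object@vars, collapse = ", "),
              paste(dim(object@counts), collapse = " x "), object@nAvailable))
})

#' Convert nats to bits
#'
#' All information quantities in the package are in natural log units; this
#' helper rescales to bits for reporting.
#' @param x numeric in nats.
#' @export
natsToBits <- function(x) x / log(2)
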