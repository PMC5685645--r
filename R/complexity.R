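# Multinomial parametric (NML) complexity and the per-test complexity terms.

# memo cache for log C(K, n); keyed "K.n"
.logCcache <- new.env(parent = emptyenv())

#' Log multinomial parametric complexity
#'
#' Log of the normalized-maximum-likelihood parametric complexity C(K, n) of
#' a K-level multinomial over n samples: C(K, n) =
#' sum over counts (h1..hK) summing to n of the multinomial coefficient times
#' prod (h_j / n)^h_j. Computed via C(1, n) = 1, the binary case by exact
#' summation (n <= 1000) or an asymptotic expansion (relative accuracy better
#' than 1e-6), and the linear recurrence
#' C(K, n) = C(K-1, n) + (n / (K-2)) C(K-2, n) for K >= 3, all in log space
#' with memoization.
#'
#' @param K number of levels (>= 1).
#' @param n sample count (>= 0); log C(K, 0) = 0.
#' @return log C(K, n) in nats.
#' @examples
#' logMultinomialComplexity(2, 1)  # log(2)
#' logMultinomialComplexity(2, 2)  # log(2.5)
#' @export
logMultinomialComplexity <- function(K, n) {
  K <- as.integer(K); n <- as.integer(n)
  stopifnot(K >= 1L, n >= 0L)
  if (K == 1L || n == 0L) return(0)
  key <- paste0(K, ".", n)
  hit <- .logCcache[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (K == 2L) .logC2(n) else {
    # linear recurrence in K, log-space
    la <- logMultinomialComplexity(K - 1L, n)
    lb <- log(n / (K - 2)) + logMultinomialComplexity(K - 2L, n)
    m <- max(la, lb)
    m + log(exp(la - m) + exp(lb - m))
  }
  assign(key, val, envir = .logCcache)
  val
}

.logC2 <- function(n) {
  if (n <= 1000L) {
    h <- 0:n
    lt <- lchoose(n, h) +
      ifelse(h == 0L, 0, h * log(h / n)) +
      ifelse(h == n, 0, (n - h) * log((n - h) / n))
    m <- max(lt)
    m + log(sum(exp(lt - m)))
  } else {
    # Szpankowski-type expansion; relative error < 1e-6 for n > 1000
    log(sqrt(n * pi / 2) + 2 / 3 + sqrt(pi / 2) / (12 * sqrt(n)))
  }
}

# vectorized over stratum counts: zero strata contribute 0, repeated counts
# are computed once (logMultinomialComplexity memoizes across calls too)
.logCsum <- function(K, ns) {
  ns <- ns[ns > 0]
  if (!length(ns)) return(0)
  u <- unique(ns)
  lv <- vapply(u, function(n) logMultinomialComplexity(K, n), 0)
  sum(lv[match(ns, u)])
}

# Complexity core shared with .condInfoCore.
#  rx, ry: full level counts of X and Y; nStrataA: full cardinality of the
#  conditioning level space; nA / cXA / cYA: non-empty stratum counts of
#  {A}, (X, A) and (Y, A); n: N_a; nUsed: n or nEff.
# BIC: 0.5 (rx-1)(ry-1) prod(rA) log(nUsed).
# NML (decomposable, symmetrized): k = 0.5 (kX + kY) with
#  kX = sum over (Y x A) strata of log C(rx, n_u) - sum over A strata of
#       log C(rx, n_v), and symmetrically kY; floored at 0.
.complexityCore <- function(rx, ry, nStrataA, nA, cXA, cYA, n, nUsed, mode) {
  if (mode == "bic") {
    if (nUsed < 1L) return(0)
    return(0.5 * (rx - 1) * (ry - 1) * nStrataA * log(max(nUsed, 2L)))
  }
  # nml: when an effective sample size overrides N_a, stratum counts are
  # rescaled (and rounded) so the regret reflects the effective count
  scale <- if (nUsed != n) nUsed / n else 1
  nYA <- cYA; nXA <- cXA; nAv <- nA
  if (scale != 1) {
    nYA <- round(nYA * scale); nXA <- round(nXA * scale); nAv <- round(nAv * scale)
  }
  kX <- .logCsum(rx, nYA) - .logCsum(rx, nAv)
  kY <- .logCsum(ry, nXA) - .logCsum(ry, nAv)
  max(0, 0.5 * (kX + kY))
}

#' Complexity term of a conditional-independence test
#'
#' The finite-size penalty k attached to I(X;Y|{A}): either the BIC/MDL
#' penalty 0.5 (r_X - 1)(r_Y - 1) prod_i r_Ai log(n), or the decomposable
#' NML regret built from multinomial complexities over conditioning strata,
#' symmetrized over X and Y. Strata with no samples contribute 0.
#'
#' @inheritParams condMutualInfo
#' @return penalty k >= 0 in nats.
#' @export
complexityTerm <- function(data, x, y, cond = character(0), mode = c("nml", "bic")) {
  mode <- match.arg(mode)
  .condInfoCore(data, x, y, cond, mode)$cplx
}
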