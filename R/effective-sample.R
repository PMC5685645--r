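# Effective number of independent samples for autocorrelated series (e.g.
# consecutive Monte Carlo configurations).

#' Average sample autocorrelation of a categorical table
#'
#' Each variable is integer-coded (level rank in sorted label order, the
#' same coding used for partial-correlation signs)
#' and centered; the lag-n autocovariance is pooled over variables with
#' lag-0-variance weights and normalized by the pooled lag-0 value:
#' c(n) = sum_i cov_i(n) / sum_i cov_i(0). Constant variables are excluded.
#'
#' @param data a \linkS4class{CategoricalData} object (rows in sampling
#'   order; no missing values expected for meaningful lags).
#' @param maxLag largest lag to evaluate (1 <= maxLag < N).
#' @return list with \code{c0} (pooled variance), \code{c} (normalized
#'   autocorrelation, index = lag), and \code{n} (series length).
#' @export
autocorrelation <- function(data, maxLag = 50L) {
  stopifnot(is(data, "CategoricalData"))
  N <- nSamples(data)
  maxLag <- as.integer(maxLag)
  if (maxLag < 1L || maxLag >= N) stop("need N > maxLag >= 1")
  M <- .numericCodes(data)
  keep <- apply(M, 2, function(v) stats::var(v, na.rm = TRUE) > 0)
  if (!any(keep)) stop("all series are constant")
  M <- M[, keep, drop = FALSE]
  M <- sweep(M, 2, colMeans(M, na.rm = TRUE))
  c0 <- sum(colMeans(M^2, na.rm = TRUE))
  cn <- vapply(seq_len(maxLag), function(lag) {
    a <- M[seq_len(N - lag), , drop = FALSE]
    b <- M[(lag + 1):N, , drop = FALSE]
    sum(colMeans(a * b, na.rm = TRUE)) / c0
  }, 0)
  list(c0 = c0, c = cn, n = N)
}

#' Fit an exponential decay to an autocorrelation function
#'
#' Assumes c(n) ~ c(0) alpha^n (first-order Markov decay) and estimates
#' alpha by a least-squares line through log c(n), using only lags where
#' c(n) exceeds a floor (default 0.05, below which log-scale noise
#' dominates), capped at the first \code{maxLags} lags. The fitted alpha is
#' clipped to [0, 1 - 1e-6]; if fewer than two usable lags remain (e.g. an
#' i.i.d. series, or all-negative autocorrelations) alpha = 0.
#'
#' @param ac result of \code{\link{autocorrelation}}.
#' @param floor minimum autocorrelation entering the log-scale fit.
#' @param maxLags cap on the number of lags used.
#' @return An \linkS4class{AutocorrFit} with alpha, the decay length
#'   R = -1/log(alpha), and nEff = round(N (1-alpha)/(1+alpha)).
#' @export
fitAlpha <- function(ac, floor = 0.05, maxLags = 50L) {
  cn <- ac$c
  usable <- which(cn > floor)
  usable <- usable[usable <= maxLags]
  alpha <- if (length(usable) < 2L) 0 else {
    lag <- usable
    fit <- stats::lm.fit(cbind(1, lag), log(cn[usable]))
    a <- exp(fit$coefficients[[2L]])
    min(max(a, 0), 1 - 1e-6)
  }
  new("AutocorrFit", c0 = ac$c0, c = cn, alpha = alpha,
      decayLength = if (alpha > 0) -1 / log(alpha) else 0,
      nEff = effectiveN(ac$n, alpha), n = as.integer(ac$n))
}

#' Effective number of independent samples
#'
#' For an exponentially decaying autocorrelation with per-step factor alpha,
#' the variance of the sample mean over N correlated samples is inflated by
#' (1 + alpha) / (1 - alpha), so the equivalent number of independent
#' samples is N_eff = round(N (1 - alpha) / (1 + alpha)): N at alpha = 0,
#' shrinking toward 0 as alpha -> 1.
#'
#' @param N nominal sample count.
#' @param alpha per-step autocorrelation decay, 0 <= alpha < 1.
#' @return integer effective sample size (at least 1).
#' @examples
#' effectiveN(1e5, 0.872) / 1e5  # ~0.068
#' @export
effectiveN <- function(N, alpha) {
  if (alpha < 0 || alpha >= 1) stop("alpha must satisfy 0 <= alpha < 1")
  max(1L, as.integer(round(N * (1 - alpha) / (1 + alpha))))
}

#' One-call effective-sample-size estimate
#'
#' Runs \code{\link{autocorrelation}} and \code{\link{fitAlpha}} on a table
#' of consecutive samples.
#'
#' @inheritParams autocorrelation
#' @inheritParams fitAlpha
#' @return An \linkS4class{AutocorrFit}.
#' @export
estimateEffectiveSamples <- function(data, maxLag = 50L, floor = 0.05) {
  fitAlpha(autocorrelation(data, maxLag), floor = floor, maxLags = maxLag)
}

setMethod("show", "AutocorrFit", function(object) {
  cat(sprintf("AutocorrFit: alpha = %.4f, decay length R = %.3f, N = %d, nEff = %d (%.3f N)\n",
              object@alpha, object@decayLength, object@n, object@nEff,
              object@nEff / object@n))
})
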