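#' Construct a CategoricalData object
#'
#' Builds the package's core data container from a data.frame or character
#' matrix. Every column is treated as categorical whatever it looks like
#' (numeric-looking columns are never discretized or coerced silently);
#' levels are recorded in first-appearance order, which also fixes the
#' integer coding used for partial correlations and autocorrelations.
#'
#' @param x data.frame or matrix; rows are samples, columns variables.
#' @param naTokens character values to interpret as missing (in addition to
#'   real \code{NA}s).
#' @param nEff optional integer; effective number of independent samples
#'   overriding N in all finite-size corrections.
#' @return A \linkS4class{CategoricalData} object.
#' @examples
#' d <- categoricalData(data.frame(X = c("a", "b", "a"), Y = c("u", "u", "v")))
#' nSamples(d)
#' @export
categoricalData <- function(x, naTokens = c("NA", ""), nEff = NA_integer_) {
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x) || ncol(x) < 1L) stop("x must be a data.frame with >= 1 column")
  if (anyDuplicated(names(x))) stop("duplicate column names")
  lv <- vector("list", ncol(x))
  names(lv) <- names(x)
  codes <- matrix(NA_integer_, nrow(x), ncol(x), dimnames = list(NULL, names(x)))
  for (j in seq_along(x)) {
    v <- as.character(x[[j]])
    v[v %in% naTokens] <- NA_character_
    obs <- unique(v[!is.na(v)])
    if (!length(obs)) stop(sprintf("column '%s' has no observed values", names(x)[j]))
    lv[[j]] <- obs
    codes[, j] <- match(v, obs)
  }
  new("CategoricalData", codes = codes, levels = lv, nEff = as.integer(nEff))
}

#' Read a delimited table of categorical samples
#'
#' Reads an N x P rectangular text file with a header row of variable names.
#' All columns are read as character and kept categorical; the delimiter is
#' never guessed.
#'
#' @param path file path.
#' @param delimiter single character column separator (default tab).
#' @param naTokens tokens interpreted as missing values.
#' @param nEff optional effective sample size override.
#' @return A \linkS4class{CategoricalData} object.
#' @export
readCategoricalTable <- function(path, delimiter = "\t", naTokens = c("NA", ""),
                                 nEff = NA_integer_) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "",
                          comment.char = "", fill = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L) stop("empty table")
  categoricalData(df, naTokens = naTokens, nEff = nEff)
}

#' @rdname categoricalData
#' @param object,x a CategoricalData object.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname categoricalData
#' @export
setMethod("nSamples", "CategoricalData", function(object) nrow(object@codes))

#' @rdname categoricalData
#' @export
setGeneric("nVariables", function(object) standardGeneric("nVariables"))

#' @rdname categoricalData
#' @export
setMethod("nVariables", "CategoricalData", function(object) ncol(object@codes))

#' @rdname categoricalData
#' @export
setGeneric("varNames", function(object) standardGeneric("varNames"))

#' @rdname categoricalData
#' @export
setMethod("varNames", "CategoricalData", function(object) colnames(object@codes))

#' @rdname categoricalData
#' @export
setGeneric("varLevels", function(object) standardGeneric("varLevels"))

#' @rdname categoricalData
#' @export
setMethod("varLevels", "CategoricalData", function(object) object@levels)

#' @rdname categoricalData
#' @export
setGeneric("dataCodes", function(object) standardGeneric("dataCodes"))

#' @rdname categoricalData
#' @export
setMethod("dataCodes", "CategoricalData", function(object) object@codes)

#' @rdname categoricalData
#' @export
setGeneric("effectiveSamples", function(object) standardGeneric("effectiveSamples"))

#' @rdname categoricalData
#' @export
setMethod("effectiveSamples", "CategoricalData", function(object) object@nEff)

#' @rdname categoricalData
#' @param value integer effective sample size (NA to clear).
#' @export
setGeneric("effectiveSamples<-", function(object, value) standardGeneric("effectiveSamples<-"))

#' @rdname categoricalData
#' @export
setReplaceMethod("effectiveSamples", "CategoricalData", function(object, value) {
  object@nEff <- as.integer(value)
  validObject(object)
  object
})

setMethod("show", "CategoricalData", function(object) {
  cat(sprintf("CategoricalData: %d samples x %d variables\n",
              nrow(object@codes), ncol(object@codes)))
  nm <- sum(is.na(object@codes))
  if (nm) cat(sprintf("  missing values: %d (%.1f%%)\n", nm, 100 * nm / length(object@codes)))
  if (!is.na(object@nEff)) cat(sprintf("  effective sample size: %d\n", object@nEff))
  k <- lengths(object@levels)
  cat(sprintf("  levels per variable: %d-%d\n", min(k), max(k)))
})

# number of levels per variable for a subset of variables
.nLevels <- function(data, vars) {
  vapply(data@levels[vars], length, 1L)
}

# sample count entering finite-size terms: nEff override, else complete cases
.nUsed <- function(data, nAvailable) {
  if (!is.na(data@nEff)) data@nEff else as.integer(nAvailable)
}

# numeric matrix of level codes re-ranked into sorted label order (the
# coding used wherever categories enter a correlation)
.numericCodes <- function(data, vars = varNames(data), cd = data@codes[, vars, drop = FALSE]) {
  M <- matrix(NA_real_, nrow(cd), ncol(cd))
  for (j in seq_along(vars)) {
    lab <- data@levels[[vars[j]]]
    rk <- match(lab, sort(lab))
    M[, j] <- rk[cd[, j]]
  }
  M
}
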