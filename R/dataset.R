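#' Validated laboratory dataset
#'
#' Builds the container every other function in the package operates on: a
#' vector of strictly positive laboratory results rounded to a fixed decimal
#' precision, together with its distinct-value histogram (sorted unique
#' rounded values and their multiplicities).  The histogram representation is
#' what keeps the truncation-interval search tractable: the objective only
#' ever needs to be evaluated at distinct values, and run time scales with
#' the number of distinct values rather than the number of samples.
#'
#' Non-positive values are a hard error rather than being shifted or dropped:
#' the Box-Cox transform requires positive input, and silently shifting the
#' data would change the estimand.  If an offset is appropriate for an
#' analyte, apply it explicitly (and document it) before calling this.
#'
#' @param values numeric vector of strictly positive test results, one per
#'   sample, in analyte units.
#' @param decimals non-negative integer: number of decimal digits the values
#'   are rounded to before histogramming.  `NULL` (default) infers the
#'   precision as the maximum number of decimal digits among the first 1000
#'   values, capped at 4.
#' @return An object of class `lab_dataset`: a list with elements `values`
#'   (rounded input values, original order), `decimals`, `distinct` (sorted
#'   unique rounded values), `counts` (multiplicity per distinct value) and
#'   `n` (total sample count).
#' @examples
#' d <- lab_dataset(c(14.05, 14.04, 12.0), decimals = 1)
#' d$distinct  # 12.0, 14.0
#' d$counts    # 1, 2
#' @export
lab_dataset <- function(values, decimals = NULL) {
  if (length(values) == 0L)
    stop("empty input: at least one value is required")
  if (!is.numeric(values))
    stop("values must be numeric")
  bad <- which(!is.finite(values))
  if (length(bad) > 0L)
    stop("non-finite value at row ", bad[1L])
  bad <- which(values <= 0)
  if (length(bad) > 0L)
    stop("nonpositive value at row ", bad[1L],
         " (", format(values[bad[1L]]), "); the Box-Cox transform requires ",
         "strictly positive input -- apply and document an offset if needed")
  if (is.null(decimals)) {
    decimals <- infer_decimals(values)
  } else {
    decimals <- as.integer(decimals)
    if (length(decimals) != 1L || is.na(decimals) || decimals < 0L)
      stop("decimals must be a single non-negative integer")
  }
  rounded <- round_dec(values, decimals)
  bad <- which(rounded <= 0)
  if (length(bad) > 0L)
    stop("nonpositive value at row ", bad[1L], " after rounding to ",
         decimals, " decimals; increase `decimals` or rescale the analyte")
  distinct <- sort(unique(rounded))
  counts <- tabulate(match(rounded, distinct), nbins = length(distinct))
  structure(
    list(values = rounded, decimals = decimals, distinct = distinct,
         counts = counts, n = length(rounded)),
    class = "lab_dataset")
}

# Decimal-aware round-half-to-even: values that are an exact half step in
# decimal notation (e.g. 14.05 at one decimal) go to the even neighbour,
# regardless of which side of the half their binary representation falls on.
round_dec <- function(x, d) {
  s <- x * 10^d
  f <- s - floor(s)
  half <- abs(f - 0.5) < 1e-9 * pmax(1, abs(s))
  r <- round(s)
  if (any(half)) {
    lo <- floor(s[half])
    r[half] <- lo + (lo %% 2)
  }
  r / 10^d
}

# max decimal digits among the first 1000 values, capped at 4
infer_decimals <- function(values) {
  head_vals <- values[seq_len(min(1000L, length(values)))]
  for (d in 0:3) {
    if (all(abs(head_vals - round(head_vals, d)) <=
              1e-8 * pmax(1, abs(head_vals))))
      return(d)
  }
  4L
}

#' @export
print.lab_dataset <- function(x, ...) {
  cat("Laboratory dataset: ", x$n, " values (",
      length(x$distinct), " distinct at ", x$decimals, " decimals), range ",
      format(min(x$distinct)), "-", format(max(x$distinct)), "\n", sep = "")
  invisible(x)
}

is_lab_dataset <- function(x) inherits(x, "lab_dataset")

#' Box-Cox power transform
#'
#' `boxcox()` maps positive values through `(x^lambda - 1) / lambda`
#' (natural log at `lambda = 0`, where the power expression has its
#' continuous limit); `inv_boxcox()` is its inverse.  `lambda` is restricted
#' to `[0, 1]`, spanning the log-normal (`lambda = 0`) to Gaussian
#' (`lambda = 1`) family of right-skewed shapes the estimator searches over.
#' The log branch is taken explicitly rather than via a limit expression for
#' numerical stability near `lambda = 0`.
#'
#' @param x strictly positive numeric vector.
#' @param y numeric vector in transformed space.
#' @param lambda single number in `[0, 1]`.
#' @return `boxcox()`: transformed values.  `inv_boxcox()`: values on the
#'   original scale; an error is raised when `lambda * y + 1 <= 0`, where the
#'   transform is not invertible.
#' @examples
#' boxcox(4, 0.5)       # 2
#' inv_boxcox(2, 0.5)   # 4
#' boxcox(exp(1), 0)    # 1
#' @export
boxcox <- function(x, lambda) {
  check_lambda(lambda)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("boxcox requires strictly positive finite input")
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' @rdname boxcox
#' @export
inv_boxcox <- function(y, lambda) {
  check_lambda(lambda)
  if (lambda == 0) return(exp(y))
  arg <- lambda * y + 1
  if (any(arg <= 0))
    stop("limit not invertible: lambda * y + 1 <= 0 (lambda = ",
         format(lambda), ", y = ", format(y[which(arg <= 0)[1L]]), ")")
  arg^(1 / lambda)
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  invisible(lambda)
}

#' Empirical CDF of a dataset in Box-Cox space
#'
#' Right-continuous cumulative histogram of the rounded values after
#' transformation: `D(x)` is the fraction of samples whose transformed
#' rounded value is `<= x`.  Ties are aggregated at the rounded value.
#'
#' @param dataset a [lab_dataset()].
#' @param x numeric vector of evaluation points in transformed space.
#' @param lambda Box-Cox parameter in `[0, 1]` applied to the dataset.
#' @return Fractions in `[0, 1]`, one per element of `x`.
#' @examples
#' d <- lab_dataset(c(1, 2, 3), decimals = 0)
#' ecdf_at(d, boxcox(2, 1), lambda = 1)  # 2/3
#' @export
ecdf_at <- function(dataset, x, lambda) {
  stopifnot(is_lab_dataset(dataset))
  xt <- boxcox(dataset$distinct, lambda)
  cum <- cumsum(dataset$counts)
  i <- findInterval(x, xt)
  ifelse(i == 0L, 0, cum[pmax(i, 1L)]) / dataset$n
}
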