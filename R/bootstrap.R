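#' Bootstrap confidence intervals for estimated reference limits
#'
#' Percentile bootstrap: each replicate resamples the full dataset with
#' replacement (on the value multiset, not the histogram bins) and re-runs
#' the complete estimator, including re-optimization of `lambda`.  The
#' confidence bounds are the `((1 - level)/2, (1 + level)/2)` empirical
#' percentiles (inverse-ECDF convention, i.e. `quantile(type = 1)`) of the
#' replicate limits.
#'
#' Each replicate draws from its own RNG stream keyed by `(seed, replicate)`,
#' so the result is bit-identical for any `threads` value and any replicate
#' execution order.  Replicates whose estimation fails are excluded and
#' counted; more than 20% failures is an error.
#'
#' @param dataset a [lab_dataset()].
#' @param config a [search_config()] used for every replicate fit.
#' @param replicates number of bootstrap resamples (>= 2).
#' @param level confidence level in (0, 1).
#' @param seed integer seed for the replicate resampling streams.
#' @param threads number of worker processes for replicate fits.
#' @return An object of class `ri_boot`: list with `level`, `replicates`,
#'   `n_success`, `lower_limit_ci`, `upper_limit_ci` (each a length-2
#'   vector) and `replicate_estimates` (data frame with columns `replicate`,
#'   `lower`, `upper`).
#' @export
bootstrap_ri <- function(dataset, config = search_config(), replicates = 100L,
                         level = 0.90, seed = 1L, threads = 1L) {
  stopifnot(is_lab_dataset(dataset))
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("replicates must be >= 2")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")

  reps <- stream_lapply(replicates, seed, threads, function(r) {
    vals <- dataset$values[sample.int(dataset$n, dataset$n, replace = TRUE)]
    fit <- tryCatch(
      estimate_ri(lab_dataset(vals, decimals = dataset$decimals), config),
      error = function(e) e)
    if (inherits(fit, "error")) list(ok = FALSE, msg = conditionMessage(fit))
    else list(ok = TRUE, lower = fit$lower_limit, upper = fit$upper_limit)
  })

  ok <- vapply(reps, function(r) isTRUE(r$ok), logical(1))
  n_fail <- sum(!ok)
  if (n_fail > 0L) {
    message("bootstrap: ", n_fail, " of ", replicates,
            " replicate estimations failed and were excluded")
  }
  if (n_fail > 0.20 * replicates)
    stop(sprintf("bootstrap failed: %.0f%% of replicates (%d/%d) could not be estimated",
                 100 * n_fail / replicates, n_fail, replicates))

  lower <- vapply(reps[ok], `[[`, numeric(1), "lower")
  upper <- vapply(reps[ok], `[[`, numeric(1), "upper")
  probs <- c((1 - level) / 2, (1 + level) / 2)
  structure(
    list(level = level, replicates = replicates, n_success = sum(ok),
         lower_limit_ci = unname(stats::quantile(lower, probs, type = 1)),
         upper_limit_ci = unname(stats::quantile(upper, probs, type = 1)),
         replicate_estimates = data.frame(replicate = which(ok),
                                          lower = lower, upper = upper)),
    class = "ri_boot")
}

#' @export
print.ri_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap reference-limit confidence intervals (",
      format(100 * x$level), "%, ", x$n_success, "/", x$replicates,
      " replicates)\n", sep = "")
  cat("  lower limit: [", format(x$lower_limit_ci[1], digits = digits), ", ",
      format(x$lower_limit_ci[2], digits = digits), "]\n", sep = "")
  cat("  upper limit: [", format(x$upper_limit_ci[1], digits = digits), ", ",
      format(x$upper_limit_ci[2], digits = digits), "]\n", sep = "")
  invisible(x)
}
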