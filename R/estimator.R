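#' Search configuration for the reference-interval estimator
#'
#' Collects every tunable of the optimization.  Defaults follow the
#' estimator's standard setup: truncation limits searched between the 5th
#' and 30th percentile (lower) and the 70th and 95th percentile (upper) of
#' the input data, a coarse/fine Box-Cox grid with steps 0.1 and 0.01, and
#' central 95% reference limits (z = 1.959964).
#'
#' @param t1_percentile_range length-2 fractions: percentile-rank window the
#'   lower truncation limit is searched in.
#' @param t2_percentile_range length-2 fractions: window for the upper
#'   truncation limit.
#' @param lambda_coarse_step,lambda_fine_step grid steps for the Box-Cox
#'   parameter search.
#' @param max_candidates_per_side cap on the number of candidate truncation
#'   limits per side; larger candidate sets are thinned to evenly spaced
#'   quantile ranks.  Bounds run time, which grows with the product of the
#'   two candidate counts.
#' @param nm_tolerance absolute convergence tolerance on the objective for
#'   the Nelder-Mead (mu, sigma) fit.
#' @param nm_max_iter Nelder-Mead iteration cap.
#' @param min_n_inside minimum number of samples a truncation interval must
#'   contain to be considered.
#' @param reference_z z-quantile defining the central reference interval;
#'   the default corresponds to the 2.5th/97.5th percentiles.
#' @return An object of class `ks_search_config` (a named list).
#' @export
search_config <- function(t1_percentile_range = c(0.05, 0.30),
                          t2_percentile_range = c(0.70, 0.95),
                          lambda_coarse_step = 0.1,
                          lambda_fine_step = 0.01,
                          max_candidates_per_side = 40L,
                          nm_tolerance = 1e-7,
                          nm_max_iter = 500L,
                          min_n_inside = 50,
                          reference_z = 1.959964) {
  cfg <- list(t1_percentile_range = as.numeric(t1_percentile_range),
              t2_percentile_range = as.numeric(t2_percentile_range),
              lambda_coarse_step = lambda_coarse_step,
              lambda_fine_step = lambda_fine_step,
              max_candidates_per_side = as.integer(max_candidates_per_side),
              nm_tolerance = nm_tolerance,
              nm_max_iter = as.integer(nm_max_iter),
              min_n_inside = min_n_inside,
              reference_z = reference_z)
  r1 <- cfg$t1_percentile_range
  r2 <- cfg$t2_percentile_range
  if (length(r1) != 2L || length(r2) != 2L ||
      !(0 < r1[1] && r1[1] <= r1[2] && r1[2] < r2[1] &&
          r2[1] <= r2[2] && r2[2] < 1))
    stop("percentile ranges must satisfy 0 < t1 range < t2 range < 1")
  if (cfg$lambda_coarse_step <= 0 || cfg$lambda_fine_step <= 0)
    stop("lambda grid steps must be positive")
  if (cfg$max_candidates_per_side < 1L)
    stop("max_candidates_per_side must be >= 1")
  if (cfg$min_n_inside < 2)
    stop("min_n_inside must be >= 2")
  class(cfg) <- "ks_search_config"
  cfg
}

# distinct-value indices whose percentile rank (fraction of samples <= value)
# falls in each side's window; thinned to evenly spaced positions when a side
# exceeds the cap.  Ranks are invariant under the monotone Box-Cox map, so
# the same index sets serve every lambda.
candidate_indices <- function(dataset, config) {
  ranks <- cumsum(dataset$counts) / dataset$n
  i1 <- which(ranks >= config$t1_percentile_range[1] &
                ranks <= config$t1_percentile_range[2])
  i2 <- which(ranks >= config$t2_percentile_range[1] &
                ranks <= config$t2_percentile_range[2])
  thin <- function(idx, cap) {
    if (length(idx) <= cap) return(idx)
    idx[unique(round(seq(1, length(idx), length.out = cap)))]
  }
  list(i1 = thin(i1, config$max_candidates_per_side),
       i2 = thin(i2, config$max_candidates_per_side))
}

#' Candidate truncation intervals
#'
#' Enumerates the truncation intervals the brute-force search examines:
#' every pair of a candidate lower limit (a distinct value whose percentile
#' rank lies in `t1_percentile_range`) and a candidate upper limit (rank in
#' `t2_percentile_range`), excluding pairs containing fewer than
#' `min_n_inside` samples.  Because candidate membership is defined by
#' percentile rank, the same sample subsets are examined at every `lambda`
#' and objective values are comparable across the `lambda` grid.
#'
#' @param dataset a [lab_dataset()].
#' @param lambda Box-Cox parameter; the returned limits are in transformed
#'   space.
#' @param config a [search_config()].
#' @return A data frame with columns `t1`, `t2` (transformed space),
#'   `n_inside` and the distinct-value indices `i1`, `i2`.
#' @export
truncation_candidates <- function(dataset, lambda, config = search_config()) {
  stopifnot(is_lab_dataset(dataset))
  idx <- candidate_indices(dataset, config)
  cum <- cumsum(dataset$counts)
  pairs <- expand.grid(i1 = idx$i1, i2 = idx$i2, KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$i2 > pairs$i1, , drop = FALSE]
  if (nrow(pairs) > 0L) {
    below <- ifelse(pairs$i1 > 1L, cum[pmax(pairs$i1 - 1L, 1L)], 0)
    below[pairs$i1 == 1L] <- 0
    pairs$n_inside <- cum[pairs$i2] - below
    pairs <- pairs[pairs$n_inside >= config$min_n_inside, , drop = FALSE]
  }
  if (nrow(pairs) == 0L)
    stop("no valid truncation interval: dataset too small or too discrete")
  xt <- boxcox(dataset$distinct, lambda)
  out <- data.frame(t1 = xt[pairs$i1], t2 = xt[pairs$i2],
                    n_inside = pairs$n_inside,
                    i1 = pairs$i1, i2 = pairs$i2)
  rownames(out) <- NULL
  out[order(out$i1, out$i2), , drop = FALSE]
}

# Transformed value and bin-edge grids.  The distinct values are centers of
# bins of width 10^-decimals; the empirical CDF steps at the upper edges, so
# the model CDF is evaluated there, and truncation intervals are anchored at
# outer bin edges.  Edges are transformed with the same lambda (monotone, so
# edge order is preserved).
transformed_grid <- function(dataset, lambda) {
  h <- 10^(-dataset$decimals) / 2
  list(xt = boxcox(dataset$distinct, lambda),
       ue = boxcox(dataset$distinct + h, lambda),
       le = boxcox(dataset$distinct - h, lambda),
       cum = as.numeric(cumsum(dataset$counts)))
}

# map truncation limits in transformed space back to distinct-value indices
trunc_to_indices <- function(dataset, lambda, t1, t2) {
  if (!(t1 < t2)) stop("truncation interval requires t1 < t2")
  xt <- boxcox(dataset$distinct, lambda)
  tol <- 1e-9 * max(1, abs(t1), abs(t2))
  lo <- which(xt >= t1 - tol)
  hi <- which(xt <= t2 + tol)
  if (length(lo) == 0L || length(hi) == 0L || max(hi) < lo[1L])
    stop("truncation interval contains no data")
  c(i1 = lo[1L], i2 = max(hi))
}

#' Penalized Kolmogorov-Smirnov objective
#'
#' Evaluates the minimization target for one candidate fit: the supremum
#' distance between the conditional empirical CDF inside the truncation
#' interval and the conditional Gaussian CDF, divided by the square root of
#' the number of samples inside, plus two one-sided penalties (`p1` below,
#' `p2` above) that punish fits implying more physiological mass outside the
#' truncation interval than was observed.  Negative penalty excursions are
#' ignored, so abnormal mass in either tail is penalty-free.
#'
#' @param dataset a [lab_dataset()].
#' @param lambda Box-Cox parameter in `[0, 1]`.
#' @param mu,sigma Gaussian location and scale in transformed space.
#' @param t1,t2 truncation limits in transformed space; they are snapped to
#'   the nearest enclosed distinct values.
#' @return An object of class `ks_objective`: list with `ks_main`, `p1`,
#'   `p2`, `total` (their sum) and `n_inside`.  `total` is `Inf` for
#'   degenerate configurations (`sigma <= 0`, or model mass inside the
#'   interval below 1e-6).
#' @export
ks_objective <- function(dataset, lambda, mu, sigma, t1, t2) {
  stopifnot(is_lab_dataset(dataset))
  check_lambda(lambda)
  ii <- trunc_to_indices(dataset, lambda, t1, t2)
  g <- transformed_grid(dataset, lambda)
  o <- ks_objective_cpp(g$ue, g$le, g$cum, dataset$n,
                        ii[["i1"]] - 1L, ii[["i2"]] - 1L, mu, sigma)
  nin <- g$cum[ii[["i2"]]] - if (ii[["i1"]] > 1L) g$cum[ii[["i1"]] - 1L] else 0
  structure(list(ks_main = o[["ks_main"]], p1 = o[["p1"]], p2 = o[["p2"]],
                 total = o[["total"]], n_inside = nin),
            class = "ks_objective")
}

#' Fit the truncated Gaussian for one truncation interval
#'
#' Nelder-Mead minimization of [ks_objective()] over `(mu, sigma)` at fixed
#' `lambda` and truncation interval.  The fit starts from the robust pair
#' (median, IQR/1.349) of the transformed values inside the interval and is
#' restarted once from (mean, SD) if the first run exhausts the iteration
#' budget.
#'
#' @inheritParams ks_objective
#' @param config a [search_config()] supplying `nm_tolerance` and
#'   `nm_max_iter`.
#' @return List with `mu`, `sigma` and `objective` (a `ks_objective`).
#' @export
fit_truncated_gaussian <- function(dataset, lambda, t1, t2,
                                   config = search_config()) {
  stopifnot(is_lab_dataset(dataset))
  check_lambda(lambda)
  ii <- trunc_to_indices(dataset, lambda, t1, t2)
  g <- transformed_grid(dataset, lambda)
  f <- ks_fit_pair_cpp(g$xt, g$ue, g$le, g$cum, dataset$n,
                       ii[["i1"]] - 1L, ii[["i2"]] - 1L,
                       config$nm_tolerance, config$nm_max_iter)
  if (!is.finite(f$total))
    stop("optimizer failure: degenerate objective for the requested ",
         "truncation interval")
  nin <- g$cum[ii[["i2"]]] - if (ii[["i1"]] > 1L) g$cum[ii[["i1"]] - 1L] else 0
  list(mu = f$mu, sigma = f$sigma,
       objective = structure(list(ks_main = f$ks_main, p1 = f$p1, p2 = f$p2,
                                  total = f$total, n_inside = nin),
                             class = "ks_objective"))
}

# best fit over all candidate truncation pairs at one lambda (or NULL if no
# pair yields a finite objective)
best_fit_at_lambda <- function(grid, n_total, idx, config) {
  r <- ks_best_fit_cpp(grid$xt, grid$ue, grid$le, grid$cum, n_total,
                       as.integer(idx$i1 - 1L), as.integer(idx$i2 - 1L),
                       config$min_n_inside, config$nm_tolerance,
                       config$nm_max_iter)
  if (!isTRUE(r$ok)) return(NULL)
  r
}

#' Estimate a reference interval from mixed laboratory data
#'
#' The full estimator: for every Box-Cox `lambda` on the coarse grid
#' `0, 0.1, ..., 1`, every candidate truncation interval is examined by brute
#' force and a Gaussian is fitted to the truncated, transformed data by
#' Nelder-Mead minimization of the penalized Kolmogorov-Smirnov objective.
#' The search is then repeated on a fine grid (step 0.01) around the winning
#' coarse `lambda`.  The globally best `(lambda, mu, sigma, T)` defines the
#' estimated physiological distribution, and the reference limits are its
#' 2.5th and 97.5th percentiles back-transformed to analyte units:
#' `inv_boxcox(mu -/+ z * sigma, lambda)`.
#'
#' Ties on the objective (within 1e-12) prefer the wider truncation interval,
#' then the smaller `lambda`.  The result is deterministic for a fixed
#' dataset and configuration and invariant under permutations of the input
#' rows.
#'
#' @param dataset a [lab_dataset()], or a numeric vector which is passed to
#'   [lab_dataset()] first.
#' @param config a [search_config()].
#' @return An object of class `ri_fit`: list with `lower_limit`,
#'   `upper_limit` (analyte units), `lambda`, `mu`, `sigma`, `t1`, `t2`
#'   (transformed space), `t1_value`, `t2_value` (analyte units),
#'   `n_inside`, `objective` (a `ks_objective`), `n` and `config`.
#' @examples
#' \donttest{
#' set.seed(7)
#' d <- lab_dataset(round(rnorm(4000, 14, 0.98), 2))
#' fit <- estimate_ri(d, search_config(max_candidates_per_side = 15))
#' fit$lower_limit  # close to 12.08 = 14 - 1.96 * 0.98
#' }
#' @export
estimate_ri <- function(dataset, config = search_config()) {
  if (!is_lab_dataset(dataset)) dataset <- lab_dataset(dataset)
  idx <- candidate_indices(dataset, config)
  if (length(idx$i1) == 0L || length(idx$i2) == 0L)
    stop("no valid truncation interval: dataset too small or too discrete")

  results <- new.env(parent = emptyenv())
  eval_lambda <- function(lam) {
    key <- sprintf("%.2f", lam)
    if (!is.null(results[[key]])) return(results[[key]])
    r <- best_fit_at_lambda(transformed_grid(dataset, lam), dataset$n,
                            idx, config)
    if (!is.null(r)) r$lambda <- lam
    results[[key]] <- if (is.null(r)) list(ok = FALSE, lambda = lam) else r
    results[[key]]
  }

  pick_best <- function(fits) {
    fits <- Filter(function(f) isTRUE(f$ok), fits)
    if (length(fits) == 0L) return(NULL)
    totals <- vapply(fits, `[[`, numeric(1), "total")
    tied <- which(totals <= min(totals) + 1e-12)
    if (length(tied) > 1L) {
      nin <- vapply(fits[tied], `[[`, numeric(1), "n_inside")
      tied <- tied[nin == max(nin)]
      if (length(tied) > 1L) {
        lam <- vapply(fits[tied], `[[`, numeric(1), "lambda")
        tied <- tied[which.min(lam)]
      }
    }
    fits[[tied[1L]]]
  }

  coarse_grid <- seq(0, 1, by = config$lambda_coarse_step)
  coarse <- lapply(coarse_grid, eval_lambda)
  best_coarse <- pick_best(coarse)
  if (is.null(best_coarse))
    stop("estimation failed: every candidate configuration was degenerate")

  fine_grid <- seq(best_coarse$lambda - 9 * config$lambda_fine_step,
                   best_coarse$lambda + 9 * config$lambda_fine_step,
                   by = config$lambda_fine_step)
  fine_grid <- round(fine_grid[fine_grid >= 0 & fine_grid <= 1], 10)
  fine <- lapply(fine_grid, eval_lambda)

  best <- pick_best(c(coarse, fine))
  lam <- best$lambda
  z <- config$reference_z
  lower <- inv_boxcox(best$mu - z * best$sigma, lam)
  upper <- inv_boxcox(best$mu + z * best$sigma, lam)

  xt <- boxcox(dataset$distinct, lam)
  i1 <- best$i1 + 1L
  i2 <- best$i2 + 1L
  structure(
    list(lower_limit = lower, upper_limit = upper,
         lambda = lam, mu = best$mu, sigma = best$sigma,
         t1 = xt[i1], t2 = xt[i2],
         t1_value = dataset$distinct[i1], t2_value = dataset$distinct[i2],
         n_inside = best$n_inside,
         objective = structure(list(ks_main = best$ks_main, p1 = best$p1,
                                    p2 = best$p2, total = best$total,
                                    n_inside = best$n_inside),
                               class = "ks_objective"),
         n = dataset$n, config = config),
    class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, digits = 4, ...) {
  cat("Indirect reference interval estimate\n")
  cat("  reference interval: ", format(x$lower_limit, digits = digits), " - ",
      format(x$upper_limit, digits = digits), "\n", sep = "")
  cat("  lambda = ", format(x$lambda),
      ", mu = ", format(x$mu, digits = digits),
      ", sigma = ", format(x$sigma, digits = digits), "\n", sep = "")
  cat("  truncation interval: [", format(x$t1_value, digits = digits), ", ",
      format(x$t2_value, digits = digits), "] containing ", x$n_inside,
      " of ", x$n, " samples\n", sep = "")
  cat("  objective: total = ", format(x$objective$total, digits = digits),
      " (ks = ", format(x$objective$ks_main, digits = digits),
      ", p1 = ", format(x$objective$p1, digits = digits),
      ", p2 = ", format(x$objective$p2, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' @export
print.ks_objective <- function(x, digits = 6, ...) {
  cat("KS objective: total = ", format(x$total, digits = digits),
      " (ks_main = ", format(x$ks_main, digits = digits),
      ", p1 = ", format(x$p1, digits = digits),
      ", p2 = ", format(x$p2, digits = digits),
      "), n_inside = ", x$n_inside, "\n", sep = "")
  invisible(x)
}
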