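#' Distribution specification for simulated analytes
#'
#' Describes one component (physiological or abnormal) of a simulated
#' dataset as either a Gaussian or a log-normal distribution.  The
#' distribution can be given by its natural parameters (`mu`, `sigma`;
#' meanlog/sdlog for the log-normal) or by its 2.5th/97.5th percentiles, in
#' which case `mu = (p2_5 + p97_5) / 2` and
#' `sigma = (p97_5 - p2_5) / (2 * 1.959964)` (applied to logs for the
#' log-normal).  When both are supplied, the explicit parameters take
#' precedence and the percentiles are recomputed from them.
#'
#' @param family `"gaussian"` or `"lognormal"`.
#' @param p2_5,p97_5 2.5th and 97.5th percentiles in analyte units.
#' @param mu,sigma location and scale (log scale for `"lognormal"`).
#' @return An object of class `distribution_spec`: list with `family`,
#'   `mu`, `sigma`, `p2_5`, `p97_5`.
#' @examples
#' distribution_from_interval("gaussian", 12, 16)    # mu 14, sigma ~1.02
#' distribution_from_interval("lognormal", 0.25, 4)  # meanlog 0, sdlog ~0.707
#' @export
distribution_spec <- function(family = c("gaussian", "lognormal"),
                              p2_5 = NULL, p97_5 = NULL,
                              mu = NULL, sigma = NULL) {
  family <- match.arg(family)
  z <- 1.959964
  if (!is.null(mu) && !is.null(sigma)) {
    if (sigma <= 0) stop("sigma must be positive")
  } else if (!is.null(p2_5) && !is.null(p97_5)) {
    if (!(p2_5 < p97_5)) stop("p2_5 must be smaller than p97_5")
    if (family == "lognormal" && p2_5 <= 0)
      stop("lognormal percentiles must be positive")
    if (family == "gaussian") {
      mu <- (p2_5 + p97_5) / 2
      sigma <- (p97_5 - p2_5) / (2 * z)
    } else {
      mu <- (log(p2_5) + log(p97_5)) / 2
      sigma <- (log(p97_5) - log(p2_5)) / (2 * z)
    }
  } else {
    stop("supply either (mu, sigma) or (p2_5, p97_5)")
  }
  if (family == "gaussian") {
    p2_5 <- mu - z * sigma
    p97_5 <- mu + z * sigma
  } else {
    p2_5 <- exp(mu - z * sigma)
    p97_5 <- exp(mu + z * sigma)
  }
  structure(list(family = family, mu = mu, sigma = sigma,
                 p2_5 = p2_5, p97_5 = p97_5),
            class = "distribution_spec")
}

#' @rdname distribution_spec
#' @export
distribution_from_interval <- function(family, p2_5, p97_5) {
  distribution_spec(family, p2_5 = p2_5, p97_5 = p97_5)
}

#' Contamination scenario specification
#'
#' One cell of the simulation study: a physiological distribution
#' contaminated with a fixed fraction of draws from an abnormal
#' distribution, at fixed total sample size.  The abnormal count is
#' `round(abnormal_fraction * n_total)`; the total is held constant
#' regardless of the fraction.
#'
#' @param physiological a [distribution_spec()] for the physiological
#'   component.
#' @param abnormal a [distribution_spec()] for the abnormal component, or
#'   `NULL` when `abnormal_fraction = 0`.
#' @param abnormal_fraction fraction of abnormal samples in `[0, 0.30]`
#'   (the range covered by the simulation study; larger values are refused).
#' @param n_total total dataset size per cycle.
#' @param cycles number of independent simulation cycles.
#' @param seed integer seed; cycle `k` draws from an RNG stream keyed by
#'   `(seed, k)`.
#' @param decimals rounding precision of the simulated results (2 is typical
#'   for hemoglobin in g/dL, 3 for TSH in mU/L, 0 for gamma-GT in U/L).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(physiological, abnormal = NULL,
                          abnormal_fraction = 0, n_total = 10000L,
                          cycles = 100L, seed = 1L, decimals = 2L) {
  stopifnot(inherits(physiological, "distribution_spec"))
  if (!(abnormal_fraction >= 0 && abnormal_fraction <= 0.30))
    stop("abnormal_fraction must be in [0, 0.30]")
  if (abnormal_fraction > 0 && is.null(abnormal))
    stop("an abnormal distribution_spec is required when abnormal_fraction > 0")
  if (!is.null(abnormal)) stopifnot(inherits(abnormal, "distribution_spec"))
  n_total <- as.integer(n_total)
  if (n_total < 1L) stop("n_total must be positive")
  structure(list(physiological = physiological, abnormal = abnormal,
                 abnormal_fraction = abnormal_fraction, n_total = n_total,
                 n_abnormal = as.integer(round(abnormal_fraction * n_total)),
                 cycles = as.integer(cycles), seed = as.integer(seed),
                 decimals = as.integer(decimals)),
            class = "scenario_spec")
}

# positive draws from a distribution_spec; nonpositive draws are resampled
# (clipping would distort the shape near zero), capped at 1000 attempts per
# requested draw
draw_positive <- function(spec, n) {
  if (n == 0L) return(numeric(0))
  draw <- function(k) {
    if (spec$family == "gaussian") stats::rnorm(k, spec$mu, spec$sigma)
    else stats::rlnorm(k, spec$mu, spec$sigma)
  }
  out <- draw(n)
  attempts <- 1L
  while (any(out <= 0)) {
    attempts <- attempts + 1L
    if (attempts > 1000L)
      stop("resampling cap exceeded: the distribution places essentially ",
           "all of its mass at nonpositive values")
    bad <- which(out <= 0)
    out[bad] <- draw(length(bad))
  }
  out
}

#' Generate one simulated dataset
#'
#' Draws `n_total - n_abnormal` physiological and `n_abnormal` abnormal
#' results for one cycle of a scenario, under the RNG stream keyed by
#' `(seed, cycle)`, resampling any nonpositive draw.  The same
#' `(seed, cycle)` always yields an identical dataset.
#'
#' @param scenario a [scenario_spec()].
#' @param cycle cycle index in `1..cycles`.
#' @return A [lab_dataset()] rounded at the scenario's `decimals`.
#' @export
generate_dataset <- function(scenario, cycle = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"))
  cycle <- as.integer(cycle)
  if (cycle < 1L || cycle > scenario$cycles)
    stop("cycle must be in 1..cycles")
  stream <- rng_streams(scenario$seed, cycle)[[cycle]]
  vals <- with_rng_stream(stream, {
    phys <- draw_positive(scenario$physiological,
                          scenario$n_total - scenario$n_abnormal)
    abn <- if (scenario$n_abnormal > 0L)
      draw_positive(scenario$abnormal, scenario$n_abnormal)
    else numeric(0)
    c(phys, abn)
  })
  lab_dataset(vals, decimals = scenario$decimals)
}

#' Run a full contamination scenario
#'
#' Generates and estimates every cycle of a scenario and summarizes the
#' per-cycle reference limits: medians, the 5th-95th percentile range of the
#' per-cycle estimates (the cross-cycle 90% interval), and optionally the
#' fraction of cycles whose limit falls inside a stated margin.
#'
#' @param scenario a [scenario_spec()].
#' @param config a [search_config()] for the per-cycle fits.
#' @param margins optional list with elements `lower` and `upper`, each a
#'   length-2 numeric margin in analyte units, e.g.
#'   `list(lower = c(11.8, 12.2), upper = c(15.8, 16.2))`.
#' @param threads worker processes for the per-cycle fits (results are
#'   independent of this value).
#' @return An object of class `scenario_summary`: list with `median_lower`,
#'   `median_upper`, `lower_ci90`, `upper_ci90`, `within_margin_lower`,
#'   `within_margin_upper`, `n_cycles`, `n_failed` and `estimates` (data
#'   frame of per-cycle limits).
#' @export
run_scenario <- function(scenario, config = search_config(), margins = NULL,
                         threads = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"))
  fits <- stream_lapply(scenario$cycles, scenario$seed, threads, function(k) {
    vals <- {
      phys <- draw_positive(scenario$physiological,
                            scenario$n_total - scenario$n_abnormal)
      abn <- if (scenario$n_abnormal > 0L)
        draw_positive(scenario$abnormal, scenario$n_abnormal)
      else numeric(0)
      c(phys, abn)
    }
    fit <- tryCatch(
      estimate_ri(lab_dataset(vals, decimals = scenario$decimals), config),
      error = function(e) e)
    if (inherits(fit, "error")) list(ok = FALSE, msg = conditionMessage(fit))
    else list(ok = TRUE, lower = fit$lower_limit, upper = fit$upper_limit)
  })

  ok <- vapply(fits, function(f) isTRUE(f$ok), logical(1))
  n_fail <- sum(!ok)
  if (n_fail > 0.20 * scenario$cycles)
    stop(sprintf("scenario failed: %d/%d cycle estimations failed",
                 n_fail, scenario$cycles))
  lower <- vapply(fits[ok], `[[`, numeric(1), "lower")
  upper <- vapply(fits[ok], `[[`, numeric(1), "upper")

  within <- function(x, margin) {
    if (is.null(margin)) NA_real_
    else mean(x >= margin[1] & x <= margin[2])
  }
  structure(
    list(median_lower = stats::median(lower),
         median_upper = stats::median(upper),
         lower_ci90 = unname(stats::quantile(lower, c(0.05, 0.95), type = 1)),
         upper_ci90 = unname(stats::quantile(upper, c(0.05, 0.95), type = 1)),
         within_margin_lower = within(lower, margins$lower),
         within_margin_upper = within(upper, margins$upper),
         n_cycles = scenario$cycles, n_failed = n_fail,
         estimates = data.frame(cycle = which(ok), lower = lower,
                                upper = upper)),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, digits = 4, ...) {
  cat("Scenario summary over ", x$n_cycles - x$n_failed, " cycles",
      if (x$n_failed > 0) paste0(" (", x$n_failed, " failed)"), "\n", sep = "")
  cat("  median limits: ", format(x$median_lower, digits = digits), " / ",
      format(x$median_upper, digits = digits), "\n", sep = "")
  cat("  90% ranges: lower [", format(x$lower_ci90[1], digits = digits), ", ",
      format(x$lower_ci90[2], digits = digits), "], upper [",
      format(x$upper_ci90[1], digits = digits), ", ",
      format(x$upper_ci90[2], digits = digits), "]\n", sep = "")
  if (!is.na(x$within_margin_lower))
    cat("  within margins: lower ", format(x$within_margin_lower),
        ", upper ", format(x$within_margin_upper), "\n", sep = "")
  invisible(x)
}

#' Preset analyte scenarios
#'
#' Convenience constructors for the three simulated analytes used to
#' validate the estimator: `"hemoglobin"` (Gaussian, mu 14.0, sigma 0.98,
#' n 10,000, 2 decimals), `"tsh"` (log-normal with 2.5th/97.5th percentiles
#' 0.25-4.0 mU/L, n 50,000, 3 decimals) and `"ggt"` (log-normal, 10-50 U/L,
#' n 25,000, 0 decimals).  The default abnormal component for hemoglobin is
#' the abnormal-low Gaussian with 95% interval 8.0-12.0 g/dL.
#'
#' @param analyte one of `"hemoglobin"`, `"tsh"`, `"ggt"`.
#' @param abnormal_fraction contamination fraction in `[0, 0.30]`.
#' @param abnormal optional [distribution_spec()] overriding the default
#'   abnormal component.
#' @param cycles,seed,n_total passed to [scenario_spec()]; `n_total = NULL`
#'   uses the analyte's standard size.
#' @return A [scenario_spec()].
#' @export
preset_scenario <- function(analyte = c("hemoglobin", "tsh", "ggt"),
                            abnormal_fraction = 0, abnormal = NULL,
                            cycles = 100L, seed = 1L, n_total = NULL) {
  analyte <- match.arg(analyte)
  p <- switch(analyte,
    hemoglobin = list(
      phys = distribution_spec("gaussian", mu = 14.0, sigma = 0.98),
      abn = distribution_from_interval("gaussian", 8.0, 12.0),
      n = 10000L, decimals = 2L),
    tsh = list(
      phys = distribution_from_interval("lognormal", 0.25, 4.0),
      abn = distribution_from_interval("gaussian", 4.5, 12.0),
      n = 50000L, decimals = 3L),
    ggt = list(
      phys = distribution_from_interval("lognormal", 10, 50),
      abn = distribution_from_interval("lognormal", 40, 300),
      n = 25000L, decimals = 0L))
  if (is.null(abnormal)) abnormal <- p$abn
  if (is.null(n_total)) n_total <- p$n
  scenario_spec(p$phys, abnormal = abnormal,
                abnormal_fraction = abnormal_fraction, n_total = n_total,
                cycles = cycles, seed = seed, decimals = p$decimals)
}
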