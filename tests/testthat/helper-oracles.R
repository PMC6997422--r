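# Independent oracles used across the suite.  These deliberately share no
# code with the package internals: plain loops over the distinct values,
# stats::pnorm for the Gaussian CDF.

# Brute-force penalized KS objective.  `dataset` is a lab_dataset, the
# truncation interval spans the distinct values with indices i1..i2
# (1-based).  Distinct values are bin centers of width 10^-decimals; the
# empirical CDF steps at upper bin edges and the truncation interval runs
# between outer bin edges.
oracle_objective <- function(dataset, lambda, mu, sigma, i1, i2) {
  h <- 10^(-dataset$decimals) / 2
  ue <- boxcox(dataset$distinct + h, lambda)
  le <- boxcox(dataset$distinct - h, lambda)
  cum <- cumsum(dataset$counts)
  n <- dataset$n
  m <- length(dataset$distinct)

  below <- if (i1 > 1) cum[i1 - 1] else 0
  nin <- cum[i2] - below
  P1 <- stats::pnorm(le[i1], mu, sigma)
  P2 <- stats::pnorm(ue[i2], mu, sigma)
  q <- P2 - P1
  if (sigma <= 0 || q < 1e-6)
    return(list(ks_main = 0, p1 = 0, p2 = 0, total = Inf))
  cc <- (nin / n) / q

  # at each upper edge the step CDF is checked on both sides of its jump
  ks <- 0
  for (i in i1:i2) {
    Ft <- (stats::pnorm(ue[i], mu, sigma) - P1) / q
    Dt <- (cum[i] - below) / nin
    Dt_pre <- if (i > i1) (cum[i - 1] - below) / nin else 0
    ks <- max(ks, abs(Dt - Ft), abs(Dt_pre - Ft))
  }
  # scaled model CDF vs observed CDF at every distinct value below T
  p1 <- 0
  if (i1 > 1) {
    for (i in 1:(i1 - 1)) {
      p1 <- max(p1, cc * stats::pnorm(ue[i], mu, sigma) - cum[i] / n)
    }
  }
  # scaled model survival vs observed survival above T
  p2 <- 0
  if (i2 < m) {
    for (i in (i2 + 1):m) {
      p2 <- max(p2, cum[i] / n - (1 - cc * (1 - stats::pnorm(ue[i], mu, sigma))))
    }
  }
  ks <- ks / sqrt(nin)
  p1 <- max(0, p1) / sqrt(nin)
  p2 <- max(0, p2) / sqrt(nin)
  list(ks_main = ks, p1 = p1, p2 = p2, total = ks + p1 + p2)
}

# random small positive dataset for oracle comparisons
random_small_dataset <- function(n = NULL, decimals = 1) {
  if (is.null(n)) n <- sample(8:50, 1)
  vals <- round(exp(stats::rnorm(n, mean = 1, sd = 0.5)), decimals)
  vals[vals <= 0] <- 10^(-decimals)
  lab_dataset(vals, decimals = decimals)
}

# economical search configuration for fast end-to-end tests
fast_config <- function(...) {
  search_config(max_candidates_per_side = 10L, min_n_inside = 30, ...)
}

# simulated hemoglobin-like sample: Gaussian(14, 0.98) rounded to 2 decimals
rhemoglobin <- function(n = 4000) round(stats::rnorm(n, 14, 0.98), 2)
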