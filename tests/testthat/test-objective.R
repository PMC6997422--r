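test_that("objective matches the brute-force oracle on random small datasets", {
  set.seed(101)
  for (rep in 1:120) {
    d <- random_small_dataset()
    m <- length(d$distinct)
    if (m < 4) next
    i1 <- sample(1:(m - 2), 1)
    i2 <- sample((i1 + 1):m, 1)
    lam <- round(runif(1), 2)
    xt <- boxcox(d$distinct, lam)
    mu <- runif(1, min(xt), max(xt))
    sigma <- runif(1, 0.05, 2) * max(diff(range(xt)), 0.1)
    got <- ks_objective(d, lam, mu, sigma, t1 = xt[i1], t2 = xt[i2])
    want <- oracle_objective(d, lam, mu, sigma, i1, i2)
    expect_equal(got$ks_main, want$ks_main, tolerance = 1e-12)
    expect_equal(got$p1, want$p1, tolerance = 1e-12)
    expect_equal(got$p2, want$p2, tolerance = 1e-12)
    expect_equal(got$total, want$total, tolerance = 1e-12)
  }
})

test_that("objective components are nonnegative and sum to the total", {
  set.seed(111)
  for (rep in 1:25) {
    d <- random_small_dataset()
    m <- length(d$distinct)
    if (m < 4) next
    xt <- boxcox(d$distinct, 0.5)
    o <- ks_objective(d, 0.5, mean(xt), sd(xt) + 0.1,
                      t1 = xt[2], t2 = xt[m - 1])
    expect_gte(o$ks_main, 0)
    expect_gte(o$p1, 0)
    expect_gte(o$p2, 0)
    expect_equal(o$total, o$ks_main + o$p1 + o$p2)
  }
})

test_that("a well-specified Gaussian on a quantile grid fits almost exactly", {
  # 2.5th..97.5th percent quantile grid of N(0,1), shifted positive; with the
  # matching model and the full grid as truncation interval the conditional
  # CDFs agree up to discretization, and no tail penalties can arise
  n <- 200
  shift <- 10
  grid <- shift + qnorm(seq(0.025, 0.975, length.out = n))
  d <- lab_dataset(grid, decimals = 4)
  xt <- boxcox(d$distinct, 1)
  o <- ks_objective(d, 1, mu = shift - 1, sigma = 1,
                    t1 = min(xt), t2 = max(xt))
  expect_lte(o$ks_main, 0.02 / sqrt(n))
  expect_equal(o$p1, 0)
  expect_equal(o$p2, 0)
})

test_that("penalties do not activate when the model implies less mass than observed", {
  # all abnormal mass far below the truncation interval: the model CDF there
  # is tiny, far under the observed cumulative mass, so p1 stays 0
  set.seed(121)
  phys <- round(rnorm(800, 14, 1), 1)
  low <- round(rnorm(200, 5, 0.3), 1)
  d <- lab_dataset(c(phys, low), decimals = 1)
  xt <- boxcox(d$distinct, 1)
  i1 <- which(d$distinct == 13.0)
  i2 <- which(d$distinct == 15.0)
  o <- ks_objective(d, 1, mu = boxcox(14, 1), sigma = 1,
                    t1 = xt[i1], t2 = xt[i2])
  expect_equal(o$p1, 0)

  # mirrored: abnormal mass far above leaves p2 at 0
  high <- round(rnorm(200, 30, 0.3), 1)
  d2 <- lab_dataset(c(phys, high), decimals = 1)
  xt2 <- boxcox(d2$distinct, 1)
  o2 <- ks_objective(d2, 1, mu = boxcox(14, 1), sigma = 1,
                     t1 = xt2[which(d2$distinct == 13.0)],
                     t2 = xt2[which(d2$distinct == 15.0)])
  expect_equal(o2$p2, 0)
})

test_that("penalties activate when the model implies impossible tail mass", {
  # model centered on the data but with a huge sigma implies far more mass
  # below the truncation interval than observed
  set.seed(131)
  d <- lab_dataset(round(rnorm(1000, 14, 1), 1), decimals = 1)
  xt <- boxcox(d$distinct, 1)
  m <- length(d$distinct)
  o <- ks_objective(d, 1, mu = boxcox(14, 1), sigma = 10,
                    t1 = xt[max(2, m %/% 4)], t2 = xt[m - m %/% 4])
  expect_gt(o$p1, 0)
  expect_gt(o$p2, 0)
})

test_that("objective is invariant under joint affine rescaling at lambda 1", {
  set.seed(141)
  vals <- round(rnorm(400, 50, 4), 1)
  d <- lab_dataset(vals, decimals = 1)
  # x -> 10x + 30 scales the one-decimal grid onto the integer grid, so the
  # bins (and their edges) map exactly
  d2 <- lab_dataset(10 * d$values + 30, decimals = 0)
  expect_equal(length(d$distinct), length(d2$distinct))
  xt <- boxcox(d$distinct, 1)
  m <- length(d$distinct)
  i1 <- m %/% 5
  i2 <- m - m %/% 5
  # mu is a transformed-space location: boxcox(., 1) shifts by -1
  o1 <- ks_objective(d, 1, mu = boxcox(50, 1), sigma = 4,
                     t1 = xt[i1], t2 = xt[i2])
  xt2 <- boxcox(d2$distinct, 1)
  o2 <- ks_objective(d2, 1, mu = boxcox(10 * 50 + 30, 1), sigma = 40,
                     t1 = xt2[i1], t2 = xt2[i2])
  expect_equal(o1$total, o2$total, tolerance = 1e-10)
  expect_equal(o1$ks_main, o2$ks_main, tolerance = 1e-10)
})

test_that("degenerate configurations give an infinite objective", {
  d <- lab_dataset(round(rnorm(200, 14, 1), 1), decimals = 1)
  xt <- boxcox(d$distinct, 1)
  m <- length(d$distinct)
  o <- ks_objective(d, 1, mu = boxcox(14, 1), sigma = -1,
                    t1 = xt[2], t2 = xt[m - 1])
  expect_equal(o$total, Inf)
  # model mass inside T essentially zero
  o2 <- ks_objective(d, 1, mu = 1000, sigma = 0.5, t1 = xt[2], t2 = xt[m - 1])
  expect_equal(o2$total, Inf)
})
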