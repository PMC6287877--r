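# Discrete Gamma, discrete GPD, and the spliced model built from them.

test_that("discrete Gamma pmf and cdf match closed forms and normalize", {
  # alpha = 1 reduces to a discretized exponential
  expect_equal(ddiscgamma(0, shape = 1, rate = 0.5), 1 - exp(-0.5))
  expect_equal(ddiscgamma(3, shape = 1, rate = 0.5),
               exp(-1.5) - exp(-2))
  expect_equal(sum(ddiscgamma(0:10000, shape = 3, rate = 0.15)), 1,
               tolerance = 1e-8)
  # cdf at x equals the continuous Gamma cdf at x + 1
  expect_equal(pdiscgamma(0, 1, 0.5), 1 - exp(-0.5))
  expect_equal(pdiscgamma(5, 3, 0.15), pgamma(6, 3, rate = 0.15))
  expect_equal(pdiscgamma(1e6, 3, 0.15), 1)
  expect_error(ddiscgamma(-1, 3, 0.15), "nonnegative integer")
  expect_error(ddiscgamma(2.5, 3, 0.15), "nonnegative integer")
  expect_error(ddiscgamma(2, -3, 0.15), "positive")
})

test_that("discrete Gamma pmf equals the law of floored continuous draws", {
  # floor(Gamma(3, 0.15)) has exactly this pmf; Monte-Carlo oracle
  set.seed(101)
  draws <- floor(rgamma(1e7, shape = 3, rate = 0.15))
  for (x in c(2, 10, 30)) {
    p_emp <- mean(draws == x)
    p_ana <- ddiscgamma(x, 3, 0.15)
    se <- sqrt(p_ana * (1 - p_ana) / 1e7)
    expect_lt(abs(p_emp - p_ana), 5 * se)
  }
})

test_that("discrete Gamma pmf is stable far above the mean", {
  # lower-tail differencing would cancel to 0 out here
  p <- ddiscgamma(3000, shape = 1.3, rate = 0.011)
  expect_gt(p, 0)
  expect_equal(p, exp(ddiscgamma(3000, 1.3, 0.011, log = TRUE)))
})

test_that("discrete GPD pmf matches closed forms and normalizes", {
  # xi = 1: survival is 1 / (1 + z), pmf 1/(1+z) - 1/(2+z)
  expect_equal(ddiscgpd(0, u = 0, sigma = 1, xi = 1), 0.5)
  expect_equal(ddiscgpd(4, u = 0, sigma = 1, xi = 1), 1 / 5 - 1 / 6)
  # exponential limit branch
  expect_equal(ddiscgpd(3, u = 0, sigma = 2, xi = 1e-12),
               exp(-1.5) - exp(-2))
  # normalization over the (truncated) support; the omitted tail mass is
  # 1e-10, well inside the 1e-8 assertion (and the enumeration stays small:
  # heavy tails put the 1e-13 point beyond 1e7)
  xmax <- qdiscgpd(1 - 1e-10, u = 5, sigma = 4, xi = 0.5)
  expect_equal(sum(ddiscgpd(5:xmax, u = 5, sigma = 4, xi = 0.5)), 1,
               tolerance = 1e-8)
  # bounded support for xi < 0
  sup <- discgpd_support(u = 10, sigma = 5, xi = -1)
  expect_identical(sup, c(10, 15))
  expect_equal(sum(ddiscgpd(10:15, 10, 5, -1)), 1, tolerance = 1e-12)
  expect_equal(pdiscgpd(sup[2], 10, 5, -1), 1)
  expect_equal(ddiscgpd(16, 10, 5, -1), 0)   # outside support, not an error
  expect_equal(ddiscgpd(9, 10, 5, -1), 0)
})

test_that("discrete GPD pmf is continuous across the xi = 0 branch switch", {
  for (x in c(0, 3, 10)) {
    lim <- exp(-x / 2) - exp(-(x + 1) / 2)
    expect_equal(ddiscgpd(x, 0, 2, 1e-9), lim, tolerance = 1e-8)
    expect_equal(ddiscgpd(x, 0, 2, -1e-9), lim, tolerance = 1e-8)
  }
})

test_that("discrete GPD quantile is the Galois inverse of the cdf", {
  u <- 5; sigma <- 4; xi <- 0.5
  expect_identical(qdiscgpd(0, u, sigma, xi), 5)
  # linear-scan oracle
  xs <- 5:5000
  cdf <- cumsum(ddiscgpd(xs, u, sigma, xi))
  for (p in c(0.1, 0.5, 0.9, 0.99, 0.999)) {
    expect_identical(qdiscgpd(p, u, sigma, xi),
                     as.numeric(xs[which(cdf >= p)[1]]))
  }
  # Galois: quantile(cdf(x)) <= x < quantile(cdf(x) + eps)
  for (x in c(5, 8, 20, 100)) {
    Fx <- pdiscgpd(x, u, sigma, xi)
    expect_lte(qdiscgpd(Fx, u, sigma, xi), x)
    expect_gt(qdiscgpd(min(Fx + 1e-12, 1 - 1e-15), u, sigma, xi), x - 1)
  }
  expect_error(qdiscgpd(1, u, sigma, xi), "unbounded")
  # sigma / |xi| integral: the nominal top support point 15 carries zero
  # mass, so the smallest x with cdf 1 is 14
  expect_identical(qdiscgpd(1, 10, 5, -1), 14)
  expect_identical(qdiscgpd(1, 10, 5.5, -1), 15)
})

test_that("discrete GPD threshold stability: excess over u is GPD(0, sigma + xi, xi)", {
  grid <- expand.grid(u = c(0, 5, 20), sigma = c(1, 4, 20),
                      xi = c(-0.4, -0.1, 0, 0.25, 0.5, 1.1))
  for (i in seq_len(nrow(grid))) {
    u <- grid$u[i]; sigma <- grid$sigma[i]; xi <- grid$xi[i]
    if (sigma + xi <= 0) next
    xs <- 0:30
    if (xi < 0) xs <- xs[xs <= floor(-(sigma + xi) / xi)]
    Fu <- pdiscgpd(u, u, sigma, xi)
    lhs <- (pdiscgpd(xs + u + 1, u, sigma, xi) - Fu) / (1 - Fu)
    rhs <- pdiscgpd(xs, 0, sigma + xi, xi)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("continuous GPD at (u, u/a, 1/a) is the type-I Pareto cdf", {
  for (u in c(5, 10, 50)) {
    for (a in c(0.9, 1.5, 3)) {
      xs <- u * c(1, 1.01, 1.5, 2, 10, 100, 1e4)
      expect_lt(max(abs(pgpd(xs, u, u / a, 1 / a) - (1 - (u / xs)^a))), 1e-10)
    }
  }
})

test_that("spliced pmf composes bulk and tail with the stated normalizers", {
  m <- toy_model()
  # hand-composed oracle at bulk, boundary, and tail points
  xs <- c(1, 3, 10, 19, 20, 25, 100)
  expect_equal(dspliced(xs, m),
               compose_spliced_pmf(xs, 3, 0.15, 20, 20, 0.5, 0.15),
               tolerance = 1e-12)
  # bulk mass is exactly 1 - phi; F(u - 1) = 1 - phi
  expect_equal(sum(dspliced(1:19, m)), 1 - m$phi, tolerance = 1e-8)
  expect_equal(pspliced(19, m), 1 - m$phi)
  expect_equal(pspliced(1e7, m), 1, tolerance = 1e-8)
  # total mass 1 after tail truncation
  xmax <- clonetail:::spliced_upper_quantile(m, 1e-10)
  expect_equal(sum(dspliced(1:xmax, m)), 1, tolerance = 1e-8)
  # cdf is a nondecreasing cumulative sum of the pmf
  expect_equal(pspliced(1:50, m), cumsum(dspliced(1:50, m)), tolerance = 1e-12)
  # degenerate phi = 1: pure discrete GPD
  m1 <- spliced_model(3, 0.15, 20, 20, 0.5, phi = 1)
  expect_equal(dspliced(20:40, m1), ddiscgpd(20:40, 20, 20, 0.5))
  # literal normalizer variant allocates mass at zero
  m0 <- spliced_model(3, 0.15, 20, 20, 0.5, 0.15, bulk_includes_zero = TRUE)
  expect_equal(sum(dspliced(0:19, m0)), 1 - m0$phi, tolerance = 1e-8)
  expect_lt(sum(dspliced(1:19, m0)), 1 - m0$phi)
})

test_that("spliced log-likelihood sums log pmf and flags zero-mass data", {
  m <- toy_model()
  # single clone at the threshold
  expect_equal(spliced_loglik(20, m), log(m$phi * ddiscgpd(20, 20, 20, 0.5)))
  # toy sample against independently composed pmf values
  toy <- c(1, 1, 2, 20, 35)
  expect_equal(spliced_loglik(toy, m),
               sum(log(compose_spliced_pmf(toy, 3, 0.15, 20, 20, 0.5, 0.15))))
  expect_error(spliced_loglik(numeric(0), m), "empty")
  # observation beyond a xi < 0 upper bound has zero mass
  mneg <- spliced_model(3, 0.15, 10, 5, -1, 0.15)
  expect_identical(spliced_loglik(c(2, 3, 30), mneg), -Inf)
  # likelihood principle: truth beats a perturbed shape on model draws
  s <- generate_repertoire(m, 20000, seed = 31)
  for (dxi in c(-0.3, 0.3)) {
    mp <- toy_model(xi = 0.5 + dxi)
    expect_gt(spliced_loglik(s$counts, m), spliced_loglik(s$counts, mp))
  }
})

test_that("sampling agrees with the analytic pmf (goodness of fit)", {
  m <- toy_model()
  counts <- withr::with_seed(77, rspliced(1e6, m))
  # pool sizes with small expectation into one tail bin
  cut <- qdiscgpd(1 - 2e-4 / m$phi, m$u, m$sigma, m$xi)
  probs <- dspliced(1:cut, m)
  obs <- c(tabulate(pmin(counts, cut + 1), nbins = cut + 1))
  probs <- c(probs, 1 - sum(probs))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})
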