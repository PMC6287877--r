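# Jensen-Shannon divergence, distance matrices, clustering, and MDS.

test_that("discrete JSD is zero at identity, symmetric, bounded, and ln 2
           on disjoint supports", {
  P <- toy_model(xi = 0.4)
  Q <- toy_model(xi = 0.9)
  expect_equal(jsd_spliced(P, P), 0)
  expect_equal(jsd_spliced(P, Q), jsd_spliced(Q, P))
  expect_gt(jsd_spliced(P, Q), 0)
  expect_lte(jsd_spliced(P, Q), log(2))
  # bounded-support models with disjoint ranges achieve the maximum
  A <- spliced_model(3, 0.15, 10, 5, -1, phi = 1)   # support {10..15}
  B <- spliced_model(3, 0.15, 20, 5, -1, phi = 1)   # support {20..25}
  expect_equal(jsd_spliced(A, B), log(2))
  expect_equal(jsd_spliced(A, B, sqrt = TRUE), sqrt(log(2)))
})

test_that("discrete JSD matches direct summation at higher truncation
           precision and is robust to the truncation tolerance", {
  P <- toy_model(xi = 0.3, phi = 0.15)
  Q <- toy_model(xi = 0.35, phi = 0.2)   # shapes kept moderate so the
  # finer-truncation oracle support stays enumerable
  # oracle: plain enumeration of both pmfs at much finer truncation
  xmax <- max(clonetail:::spliced_upper_quantile(P, 1e-13),
              clonetail:::spliced_upper_quantile(Q, 1e-13))
  p <- dspliced(1:xmax, P); p <- p / sum(p)
  q <- dspliced(1:xmax, Q); q <- q / sum(q)
  m <- (p + q) / 2
  oracle <- 0.5 * (sum(p[p > 0] * log(p[p > 0] / m[p > 0])) +
                   sum(q[q > 0] * log(q[q > 0] / m[q > 0])))
  expect_equal(jsd_spliced(P, Q), oracle, tolerance = 1e-6)
  expect_lt(abs(jsd_spliced(P, Q, tol = 1e-10) -
                jsd_spliced(P, Q, tol = 5e-11)), 1e-6)
  # the geometric-bin remainder path agrees with enumeration where both
  # are feasible
  expect_equal(jsd_spliced(P, Q, exact_limit = 2e4), jsd_spliced(P, Q),
               tolerance = 1e-6)
})

test_that("continuous JSD between Pareto fits matches a fixed-grid oracle", {
  P <- list(u = 10, alpha_d = 1.5)
  Q <- list(u = 10, alpha_d = 3.0)
  expect_equal(jsd_desponds(P, P), 0)
  expect_equal(jsd_desponds(P, Q), jsd_desponds(Q, P))
  # high-resolution log-grid trapezoid oracle
  xs <- exp(seq(log(10), log(1e8), length.out = 2e6))
  fp <- 1.5 * 10^1.5 / xs^2.5
  fq <- 3.0 * 10^3 / xs^4
  m <- (fp + fq) / 2
  integrand <- 0.5 * (fp * log(fp / m) + fq * log(fq / m))
  oracle <- sum(diff(xs) * (integrand[-1] + integrand[-length(xs)]) / 2)
  expect_equal(jsd_desponds(P, Q), oracle, tolerance = 1e-5)
  # differing thresholds: the disjoint stretch contributes ln(2)/2 mass
  R <- list(u = 20, alpha_d = 1.5)
  expect_gt(jsd_desponds(P, R), 0.5 * log(2) * (1 - (10 / 20)^1.5) * 0.99)
})

test_that("pairwise distances form a symmetric zero-diagonal matrix and
           respect monotone orderings", {
  fits <- list(a = toy_model(xi = 0.3), b = toy_model(xi = 0.6),
               c = toy_model(xi = 1.0))
  D <- pairwise_distances(fits, method = "spliced")
  expect_identical(D$labels, c("a", "b", "c"))
  expect_equal(D$values, t(D$values))
  expect_true(all(diag(D$values) == 0))
  expect_true(all(D$values >= 0))
  # monotone family: the extremes are farthest apart
  expect_gte(D$values["a", "c"],
             max(D$values["a", "b"], D$values["b", "c"]))
  # identical fits give a zero matrix
  D0 <- pairwise_distances(list(x = toy_model(), y = toy_model()),
                           method = "spliced")
  expect_equal(max(D0$values), 0)
  # mixed fit types are rejected
  dfit <- structure(list(u = 10, alpha_d = 2, label = "d"),
                    class = "desponds_fit")
  expect_error(pairwise_distances(list(toy_model(), dfit), method = "spliced"),
               "mixed|class")
  # estimator mode: plain Euclidean distance on statistic rows
  st <- rbind(a = c(0, 0), b = c(3, 4))
  De <- pairwise_distances(method = "estimator", stats = st)
  expect_equal(De$values["a", "b"], 5)
})

test_that("Ward clustering separates well-separated shape groups and merges
           duplicates first", {
  cohort <- two_group_cohort(seed = 601, n_clones = 8000)
  fits <- lapply(cohort, fit_spliced)
  D <- pairwise_distances(fits, method = "spliced")
  hc <- cluster_samples(D)
  grp <- cutree(hc, k = 2)
  expect_identical(unname(grp[1:3] == grp[1]), rep(TRUE, 3))
  expect_identical(unname(grp[4:6] == grp[4]), rep(TRUE, 3))
  expect_false(grp[1] == grp[4])
  # duplicated samples sit at distance zero and merge first
  v <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  Dm <- structure(list(labels = letters[1:3], values = v), class = "dist_matrix")
  hc2 <- cluster_samples(Dm)
  expect_identical(sort(hc2$merge[1, ]), c(-2L, -1L))
  expect_equal(hc2$height[1], 0)
})

test_that("non-metric MDS embeds an equilateral triangle equilaterally", {
  v <- matrix(1, 3, 3) - diag(3)
  dimnames(v) <- list(c("a", "b", "c"), c("a", "b", "c"))
  D <- structure(list(labels = c("a", "b", "c"), values = v),
                 class = "dist_matrix")
  mds <- embed_mds(D, k = 2, seed = 3)
  pd <- dist(mds$points)
  expect_lt(max(pd) - min(pd), 1e-4 * max(pd))
  expect_true(is.finite(mds$stress))
  # too few samples is an error
  v2 <- v[1:2, 1:2]
  D2 <- structure(list(labels = c("a", "b"), values = v2),
                  class = "dist_matrix")
  expect_error(embed_mds(D2), "at least 3")
})
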