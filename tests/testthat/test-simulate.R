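# Generative sampling, the factorial design, and read downsampling.

test_that("repertoire generation respects the mixture construction", {
  m <- toy_model()
  s <- generate_repertoire(m, 20000, seed = 71)
  frac <- mean(s$counts >= m$u)
  se <- sqrt(m$phi * (1 - m$phi) / 20000)
  expect_lt(abs(frac - m$phi), 3 * se)
  expect_true(all(s$counts >= 1))
  # phi = 0: no clone reaches the threshold
  m0 <- spliced_model(3, 0.15, 20, 20, 0.5, phi = 0)
  s0 <- generate_repertoire(m0, 5000, seed = 72)
  expect_true(all(s0$counts < 20))
  # reproducibility under the seed
  expect_identical(generate_repertoire(m, 1000, seed = 73)$counts,
                   generate_repertoire(m, 1000, seed = 73)$counts)
})

test_that("generated clone sizes follow the spliced pmf (goodness of fit)", {
  m <- toy_model()
  s <- generate_repertoire(m, 1e6, seed = 74)
  cut <- qdiscgpd(1 - 2e-4 / m$phi, m$u, m$sigma, m$xi)
  probs <- dspliced(1:cut, m)
  obs <- tabulate(pmin(s$counts, cut + 1), nbins = cut + 1)
  gof <- suppressWarnings(stats::chisq.test(obs, p = c(probs, 1 - sum(probs))))
  expect_gt(gof$p.value, 0.01)
})

test_that("the factorial design expands to the reference 48-cell grid with
           derived thresholds and scales", {
  d <- simulation_design(seed = 5)
  expect_identical(nrow(d$cells), 48L)
  expect_identical(sort(unique(d$cells$alpha)), c(3, 5, 10))
  expect_identical(sort(unique(d$cells$xi)), c(0.25, 0.5, 0.75, 1.1))
  expect_identical(sort(unique(d$cells$phi)), c(0.1, 0.15, 0.2, 0.25))
  expect_true(all(d$cells$beta == 0.15))
  expect_equal(d$cells$sigma, d$cells$alpha / 0.15)
  expect_equal(d$cells$u,
               floor(qgamma(1 - d$cells$phi, d$cells$alpha, rate = 0.15)))
  expect_identical(anyDuplicated(d$cells$label), 0L)
  # the alternative reading of the scale rule is available but not default
  dp <- simulation_design(seed = 5, sigma_rule = "product")
  expect_equal(dp$cells$sigma, d$cells$alpha * 0.15)
  # a degenerate cell is refused by name
  expect_error(simulation_design(alpha_grid = 1, beta = 5,
                                 phi_grid = 0.9, seed = 1),
               "u < 2.*alpha1")
})

test_that("cohort materialization is reproducible and labeled", {
  d <- simulation_design(n_clones = 500, seed = 6)
  c1 <- build_design_cohort(d)
  c2 <- build_design_cohort(d)
  expect_identical(length(c1), 48L)
  expect_identical(names(c1), d$cells$label)
  expect_identical(lapply(c1, `[[`, "counts"), lapply(c2, `[[`, "counts"))
  expect_identical(attr(c1, "manifest")$xi, d$cells$xi)
  expect_true(all(vapply(c1, function(s) s$n, numeric(1)) == 500))
})

test_that("read downsampling is an exact without-replacement subsample", {
  s <- clone_sample(c(10), "one")
  expect_identical(downsample_reads(s, 4, seed = 1)$counts, 4)
  # identity at full depth
  s2 <- clone_sample(c(5, 3, 2), "b")
  expect_identical(downsample_reads(s2, 10, seed = 1)$counts, s2$counts)
  expect_error(downsample_reads(s2, 11, seed = 1), "total_reads")
  # hypergeometric moment oracle: E[count_i] = count_i * target / total;
  # fewer reads are removed than the smallest clone holds, so every clone
  # survives and positions stay aligned across replicates
  counts <- c(30, 20, 10)
  reps <- vapply(1:1000, function(r) {
    downsample_reads(clone_sample(counts, "m"), 51, seed = 900 + r)$counts
  }, numeric(3))
  emp <- rowMeans(reps)
  expected <- counts * 51 / 60
  se <- apply(reps, 1, sd) / sqrt(1000)
  expect_true(all(abs(emp - expected) < 3.5 * se))
  # totals are hit exactly and zero-count clones are dropped
  big <- generate_repertoire(toy_model(), 5000, seed = 77)
  ds <- downsample_reads(big, 10000, seed = 78)
  expect_identical(ds$total_reads, 10000)
  expect_true(all(ds$counts >= 1))
})

test_that("depth equalization brings every sample to the cohort minimum", {
  cohort <- list(clone_sample(c(50, 30), "a"), clone_sample(c(10, 5, 5), "b"),
                 clone_sample(rep(4, 5), "c"))
  eq <- equalize_depth(cohort, seed = 9)
  totals <- vapply(eq, function(s) s$total_reads, numeric(1))
  expect_true(all(totals == 20))
  expect_identical(attr(eq, "depth"), 20)
  # an already-equal cohort passes through unchanged
  eq2 <- equalize_depth(eq, seed = 10)
  expect_identical(lapply(eq2, `[[`, "counts"), lapply(eq, `[[`, "counts"))
})
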