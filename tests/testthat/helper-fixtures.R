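# shared fixtures: a reference parameterization used across tests and the
# small cohorts the comparison tests cluster

derive_seed_for_test <- function(seed, index = 97) {
  clonetail:::derive_seed(seed, index)
}

toy_model <- function(xi = 0.5, phi = 0.15, alpha = 3, beta = 0.15, u = 20,
                      sigma = 20) {
  spliced_model(alpha, beta, u, sigma, xi, phi)
}

# independent composition of the spliced pmf from its ingredients, used as
# the oracle against dspliced()
compose_spliced_pmf <- function(x, alpha, beta, u, sigma, xi, phi) {
  z_bulk <- pgamma(u, alpha, rate = beta) - pgamma(1, alpha, rate = beta)
  h <- pgamma(x + 1, alpha, rate = beta) - pgamma(x, alpha, rate = beta)
  surv <- function(z) (1 + xi * z / sigma)^(-1 / xi)
  g <- surv(x - u) - surv(x + 1 - u)
  ifelse(x <= u - 1, (1 - phi) * h / z_bulk, phi * g)
}

# cohort of six repertoires with a grid-derived threshold, three per tail
# shape group; used by the clustering and downsampling tests
two_group_cohort <- function(xis = c(0.3, 0.3, 0.3, 0.9, 0.9, 0.9),
                             n_clones = 20000, seed = 401,
                             alpha = 3, beta = 0.15, phi = 0.15) {
  u <- floor(qgamma(1 - phi, alpha, rate = beta))
  cohort <- lapply(seq_along(xis), function(i) {
    m <- spliced_model(alpha, beta, u, alpha / beta, xis[i], phi)
    generate_repertoire(m, n_clones, seed = seed + i,
                        label = sprintf("s%d_xi%g", i, xis[i]))
  })
  names(cohort) <- vapply(cohort, function(s) s$label, character(1))
  attr(cohort, "xi") <- xis
  cohort
}
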