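#' Type-I Pareto tail shape estimator
#'
#' Closed-form maximum-likelihood shape estimate for a type-I Pareto tail:
#' `alpha_d = n_u / sum(log(x_j / u))` over the `n_u` tail counts at or
#' above the threshold `u`.
#'
#' @param tail_counts counts at or above `u`.
#' @param u positive threshold.
#' @return the shape estimate `alpha_d`; `Inf` (with a warning) when every
#'   tail count equals `u`.
#' @examples
#' desponds_shape(c(2, 4, 8), u = 2)   # 1 / log(2)
#' @export
desponds_shape <- function(tail_counts, u) {
  if (!is.numeric(u) || length(u) != 1L || u <= 0) {
    stop_domain("'u' must be a single positive number")
  }
  if (any(tail_counts < u)) stop_domain("all tail counts must be >= u")
  if (sum(tail_counts > u) < 2) {
    stop_domain("need at least 2 counts strictly above u")
  }
  s <- sum(log(tail_counts / u))
  if (s == 0) {
    warning("all tail counts equal the threshold; shape estimate is infinite")
    return(Inf)
  }
  length(tail_counts) / s
}

# two-sided KS statistic between the empirical cdf of tail counts and the
# continuous Pareto cdf, with ties handled by evaluating both one-sided gaps
# at each unique value
pareto_ks <- function(tail_counts, u, alpha_d) {
  x <- sort(tail_counts)
  n <- length(x)
  xs <- unique(x)
  Fx <- 1 - (u / xs)^alpha_d
  # ecdf just below and at each unique value
  at <- cumsum(tabulate(match(x, xs))) / n
  below <- c(0, at[-length(at)])
  max(pmax(abs(at - Fx), abs(below - Fx)))
}

#' Fit the type-I Pareto comparator with KS threshold selection
#'
#' Comparator tail-only model: for each unique observed clone size taken as
#' a candidate threshold `u_i`, estimates the Pareto shape by
#' [desponds_shape()] and scores the fit by the Kolmogorov-Smirnov statistic
#' between the empirical distribution of counts at or above `u_i` and the
#' continuous Pareto distribution function `1 - (u_i / x)^alpha_d`. The
#' threshold minimizing the KS statistic is returned.
#'
#' @inheritParams candidate_thresholds
#' @param min_tail minimum clones required at or above a candidate.
#' @return an object of class `desponds_fit`: `u`, `alpha_d`, `ks`,
#'   `n_tail`, the per-candidate `trace` (data frame `u`, `alpha_d`, `ks`,
#'   `n_tail`), and the sample's `label`, `n`, `total_reads`.
#' @export
fit_desponds <- function(sample, min_tail = 10) {
  sample <- as_clone_sample(sample)
  counts <- sample$counts
  cand <- sort(unique(counts))
  keep <- vapply(cand, function(u) {
    sum(counts >= u) >= min_tail && sum(counts > u) >= 2
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0L) {
    stop_domain("fewer than 'min_tail' clones above every candidate threshold")
  }
  trace <- do.call(rbind, lapply(cand, function(u) {
    tc <- counts[counts >= u]
    ad <- desponds_shape(tc, u)
    data.frame(u = u, alpha_d = ad, ks = pareto_ks(tc, u, ad),
               n_tail = length(tc))
  }))
  best <- which.min(trace$ks)
  structure(
    list(u = trace$u[best], alpha_d = trace$alpha_d[best],
         ks = trace$ks[best], n_tail = trace$n_tail[best], trace = trace,
         label = sample$label, n = sample$n, total_reads = sample$total_reads),
    class = "desponds_fit"
  )
}

#' @export
print.desponds_fit <- function(x, ...) {
  cat(sprintf("Type-I Pareto tail fit for '%s'\n", x$label))
  cat(sprintf("  u = %g  alpha_d = %.4g  KS = %.5g  (n_tail = %d of %d clones)\n",
              x$u, x$alpha_d, x$ks, x$n_tail, x$n))
  invisible(x)
}
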