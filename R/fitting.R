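#' Candidate thresholds for the spliced model
#'
#' Builds the threshold grid for the profile-likelihood search: every unique
#' observed clone size at or above the empirical `quantile`-quantile of the
#' sample, keeping only candidates that leave at least `min_tail` clones at
#' or above the threshold and at least `min_bulk` clones below it (both
#' component likelihoods need data to be maximized).
#'
#' @param sample a [clone_sample()] or a vector of positive integer counts.
#' @param quantile lower quantile of the search grid (default 0.75).
#' @param min_tail,min_bulk minimum clones required in each component.
#' @return increasing integer vector of candidate thresholds.
#' @export
candidate_thresholds <- function(sample, quantile = 0.75,
                                 min_tail = 10, min_bulk = 10) {
  sample <- as_clone_sample(sample)
  if (quantile <= 0 || quantile >= 1) stop_domain("'quantile' must be in (0, 1)")
  counts <- sample$counts
  if (length(unique(counts)) == 1L) {
    stop_domain("all clone sizes are identical; no spliced structure to fit")
  }
  qv <- stats::quantile(counts, quantile, names = FALSE)
  cand <- sort(unique(counts[counts >= qv]))
  cand <- cand[cand >= 2]
  keep <- vapply(cand, function(u) {
    sum(counts >= u) >= min_tail && sum(counts <= u - 1) >= min_bulk
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0L) {
    stop_domain("no admissible threshold candidates (sample too small or ",
                "too concentrated)")
  }
  cand
}

sample_table <- function(counts) {
  xu <- sort(unique(counts))
  fr <- as.numeric(tabulate(match(counts, xu)))
  list(xu = as.numeric(xu), fr = fr)
}

#' Fit the spliced model at a fixed threshold
#'
#' Maximizes the complete-data likelihood with the threshold held at `u`:
#' `phi` is the plug-in fraction of clones at or above `u`; the bulk
#' (truncated discrete Gamma) and tail (discrete GPD) parameters are then
#' maximized independently, since the likelihood factorizes given `u` and
#' `phi`. Optimization is Nelder-Mead on `(log alpha, log beta)` and
#' `(log sigma, xi)` from deterministic starts: a method-of-moments Gamma
#' start for the bulk, a Hill-type estimate mapped through the Pareto-GPD
#' identity for the tail, and one fixed fallback each.
#'
#' @inheritParams candidate_thresholds
#' @param u integer threshold.
#' @param bulk_includes_zero passed to [spliced_model()].
#' @return a list with elements `model` (a [spliced_model()]), `loglik`, and
#'   `converged`.
#' @export
fit_given_threshold <- function(sample, u, min_tail = 10, min_bulk = 10,
                                bulk_includes_zero = FALSE) {
  sample <- as_clone_sample(sample)
  counts <- sample$counts
  if (!is_wholenumber(u) || u < 2) stop_domain("'u' must be an integer >= 2")
  if (sum(counts >= u) < min_tail || sum(counts <= u - 1) < min_bulk) {
    stop_domain("threshold leaves fewer than min_tail/min_bulk clones in a component")
  }
  tab <- sample_table(counts)
  r <- fit_threshold_cpp(tab$xu, tab$fr, as.numeric(u), bulk_includes_zero,
                         rep(NA_real_, 4), TRUE)
  if (!r$converged) warning("component optimization did not converge at u = ", u)
  model <- spliced_model(r$alpha, r$beta, u, r$sigma, r$xi, r$phi,
                         bulk_includes_zero = bulk_includes_zero)
  list(model = model, loglik = r$loglik, converged = r$converged)
}

#' Fit the discrete spliced threshold model by profile likelihood
#'
#' The workhorse fit: evaluates the profile log-likelihood `L_p(u)` (the
#' likelihood maximized over all distribution parameters with `u` held
#' fixed) at every candidate threshold from [candidate_thresholds()] and
#' returns the model at the maximizing threshold `u-hat`, together with the
#' full profile trace. Ties in the profile are broken toward the smallest
#' threshold (the larger tail). Fits with `xi < 0` whose implied upper
#' support bound falls below the observed maximum have zero likelihood and
#' are never selected. The fit is deterministic and permutation invariant.
#'
#' @inheritParams candidate_thresholds
#' @param bulk_includes_zero passed to [spliced_model()].
#' @return an object of class `spliced_fit`: a list with `model`
#'   ([spliced_model()]), `loglik`, `profile` (data frame with one row per
#'   candidate: `u`, `loglik`, `converged`), `n_u`, plus the sample's
#'   `label`, `n`, and `total_reads`.
#' @examples
#' m <- spliced_model(3, 0.15, u = 20, sigma = 20, xi = 0.5, phi = 0.15)
#' s <- generate_repertoire(m, n_clones = 3000, seed = 7)
#' f <- fit_spliced(s)
#' f$model$xi
#' @export
fit_spliced <- function(sample, quantile = 0.75, min_tail = 10, min_bulk = 10,
                        bulk_includes_zero = FALSE) {
  sample <- as_clone_sample(sample)
  cand <- candidate_thresholds(sample, quantile, min_tail, min_bulk)
  tab <- sample_table(sample$counts)
  prof <- profile_spliced_cpp(tab$xu, tab$fr, as.numeric(cand),
                              bulk_includes_zero)
  ll <- prof[, "loglik"]
  conv <- prof[, "converged"] == 1
  ok <- conv & is.finite(ll)
  if (!any(ok)) {
    stop_domain("no candidate threshold produced a converged fit; profile: ",
                paste(sprintf("u=%g(ll=%.3g)", prof[, "u"], ll), collapse = ", "))
  }
  if (any(!ok)) {
    warning(sum(!ok), " candidate threshold(s) skipped (non-convergence)")
  }
  llv <- ifelse(ok, ll, -Inf)
  best <- which.max(llv)   # first maximum = smallest u on exact ties
  # polish the selected threshold with the full deterministic start set
  rb <- fit_threshold_cpp(tab$xu, tab$fr, prof[best, "u"], bulk_includes_zero,
                          rep(NA_real_, 4), TRUE)
  if (rb$converged && rb$loglik >= ll[best]) {
    model <- spliced_model(rb$alpha, rb$beta, prof[best, "u"], rb$sigma,
                           rb$xi, rb$phi,
                           bulk_includes_zero = bulk_includes_zero)
    ll[best] <- rb$loglik
  } else {
    model <- spliced_model(prof[best, "alpha"], prof[best, "beta"],
                           prof[best, "u"], prof[best, "sigma"],
                           prof[best, "xi"], prof[best, "phi"],
                           bulk_includes_zero = bulk_includes_zero)
  }
  structure(
    list(model = model,
         loglik = ll[best],
         profile = data.frame(u = prof[, "u"], loglik = ll, converged = conv),
         n_u = as.integer(round(prof[best, "phi"] * sample$n)),
         label = sample$label, n = sample$n, total_reads = sample$total_reads),
    class = "spliced_fit"
  )
}

#' @export
print.spliced_fit <- function(x, ...) {
  cat(sprintf("Spliced threshold model fit for '%s' (%d clonotypes, %s reads)\n",
              x$label, x$n, format(x$total_reads, big.mark = ",")))
  m <- x$model
  cat(sprintf("  u = %d  alpha = %.4g  beta = %.4g  sigma = %.4g  xi = %.4g  phi = %.5g\n",
              as.integer(m$u), m$alpha, m$beta, m$sigma, m$xi, m$phi))
  cat(sprintf("  log-likelihood = %.4f over %d candidate thresholds\n",
              x$loglik, nrow(x$profile)))
  invisible(x)
}
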