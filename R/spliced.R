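#' Construct a discrete spliced bulk-tail model
#'
#' Builds the discrete spliced threshold model for clone sizes: below the
#' threshold `u` clone sizes follow a right-truncated discrete Gamma "bulk"
#' (shape `alpha`, rate `beta`); at and above `u` they follow a discrete GPD
#' "tail" (scale `sigma`, shape `xi`); `phi` is the probability mass assigned
#' to the tail. The censoring interval is fixed at `d = 1` (integer read
#' counts).
#'
#' With `bulk_includes_zero = FALSE` (default) the bulk support is
#' `{1, ..., u - 1}` and the bulk normalizer is `H(u - 1) - h(0)`: no
#' clonotype can be observed with zero reads, so no mass is allocated there.
#' Setting `bulk_includes_zero = TRUE` uses the literal normalizer
#' `H(u - 1)` with bulk support `{0, ..., u - 1}`.
#'
#' @param alpha,beta bulk Gamma shape and rate, both > 0.
#' @param u integer threshold; must be at least 2 (so the bulk support is
#'   non-empty) unless `phi = 1`.
#' @param sigma,xi tail GPD scale (> 0) and shape.
#' @param phi tail mass fraction in `[0, 1]`.
#' @param bulk_includes_zero logical; see Details.
#' @return an object of class `spliced_model`.
#' @examples
#' m <- spliced_model(alpha = 3, beta = 0.15, u = 20, sigma = 20,
#'                    xi = 0.5, phi = 0.15)
#' sum(dspliced(1:19, m))   # bulk mass = 1 - phi
#' @export
spliced_model <- function(alpha, beta, u, sigma, xi, phi,
                          bulk_includes_zero = FALSE) {
  check_gamma_params(alpha, beta)
  check_gpd_params(u, sigma, xi)
  if (!is_wholenumber(u) || (u < 2 && phi < 1)) {
    stop_domain("'u' must be an integer >= 2 (bulk support must be non-empty)")
  }
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) ||
      phi < 0 || phi > 1) {
    stop_domain("'phi' must lie in [0, 1]")
  }
  structure(
    list(alpha = unname(alpha), beta = unname(beta), u = as.numeric(round(u)),
         sigma = unname(sigma), xi = unname(xi), phi = unname(phi), d = 1L,
         bulk_includes_zero = isTRUE(bulk_includes_zero)),
    class = "spliced_model"
  )
}

#' @export
print.spliced_model <- function(x, ...) {
  cat("Discrete Gamma-GPD spliced model\n")
  cat(sprintf("  bulk : discrete Gamma(alpha = %.4g, rate = %.4g) on {%d, ..., %d}\n",
              x$alpha, x$beta, if (x$bulk_includes_zero) 0L else 1L,
              as.integer(x$u) - 1L))
  up <- discgpd_support(x$u, x$sigma, x$xi)[2]
  cat(sprintf("  tail : discrete GPD(u = %d, sigma = %.4g, xi = %.4g) on {%d, ..., %s}\n",
              as.integer(x$u), x$sigma, x$xi, as.integer(x$u),
              if (is.finite(up)) format(up) else "Inf"))
  cat(sprintf("  phi  : %.4g (tail mass fraction)\n", x$phi))
  invisible(x)
}

bulk_normalizer <- function(model) {
  z <- pgamma(model$u, shape = model$alpha, rate = model$beta)
  if (!model$bulk_includes_zero) {
    z <- z - pgamma(1, shape = model$alpha, rate = model$beta)
  }
  z
}

bulk_lower <- function(model) if (model$bulk_includes_zero) 0 else 1

#' Spliced model pmf, cdf, log-likelihood, and sampling
#'
#' `dspliced` evaluates the spliced pmf `f(x)`: for `x <= u - 1`,
#' `(1 - phi) * h(x) / Z_bulk`; for `x >= u`, `phi * g(x)`, with `h` the
#' discrete Gamma pmf, `g` the discrete GPD pmf, and `Z_bulk` the bulk
#' normalizer. `pspliced` is the corresponding distribution function, which
#' equals `1 - phi` exactly at `x = u - 1`. `spliced_loglik` sums the log
#' pmf over a sample of clone sizes (the complete-data log-likelihood), and
#' `rspliced` draws clone sizes by inverse-cdf sampling from the mixture.
#'
#' @param x,q integer clone sizes (quantiles floored in `pspliced`).
#' @param model a [spliced_model()].
#' @param counts positive integer clone sizes.
#' @param n number of draws.
#' @param log logical; return log pmf?
#' @return pmf/cdf values, a scalar log-likelihood (`-Inf` if any
#'   observation has zero mass), or integer draws.
#' @export
dspliced <- function(x, model, log = FALSE) {
  stopifnot(inherits(model, "spliced_model"))
  u <- model$u
  lo <- bulk_lower(model)
  out <- numeric(length(x))
  bulk <- is_wholenumber(x) & x >= lo & x <= u - 1
  tailp <- is_wholenumber(x) & x >= u
  if (any(bulk)) {
    h <- ddiscgamma(x[bulk], model$alpha, model$beta)
    out[bulk] <- (1 - model$phi) * h / bulk_normalizer(model)
  }
  if (any(tailp)) {
    out[tailp] <- model$phi * ddiscgpd(x[tailp], u, model$sigma, model$xi)
  }
  if (log) base::log(out) else out
}

#' @rdname dspliced
#' @export
pspliced <- function(q, model) {
  stopifnot(inherits(model, "spliced_model"))
  q <- floor(q)
  u <- model$u
  lo <- bulk_lower(model)
  out <- numeric(length(q))
  bulk <- q >= lo & q <= u - 1
  tailp <- q >= u
  if (any(bulk)) {
    num <- pgamma(q[bulk] + 1, shape = model$alpha, rate = model$beta) -
      pgamma(lo, shape = model$alpha, rate = model$beta)
    out[bulk] <- (1 - model$phi) * num / bulk_normalizer(model)
  }
  if (any(tailp)) {
    out[tailp] <- (1 - model$phi) +
      model$phi * pdiscgpd(q[tailp], u, model$sigma, model$xi)
  }
  out
}

#' @rdname dspliced
#' @export
spliced_loglik <- function(counts, model) {
  stopifnot(inherits(model, "spliced_model"))
  if (length(counts) == 0L) stop_domain("empty sample")
  if (inherits(counts, "clone_sample")) counts <- counts$counts
  if (any(counts < bulk_lower(model))) {
    stop_domain("clone sizes below the model support")
  }
  ll <- sum(dspliced(counts, model, log = TRUE))
  if (is.nan(ll)) ll <- -Inf
  ll
}

#' @rdname dspliced
#' @export
rspliced <- function(n, model) {
  stopifnot(inherits(model, "spliced_model"))
  u <- model$u
  k_tail <- rbinom(1, n, model$phi)
  out <- numeric(n)
  if (n - k_tail > 0) {
    lo <- bulk_lower(model)
    xs <- lo:(u - 1)
    pr <- ddiscgamma(xs, model$alpha, model$beta)
    cum <- cumsum(pr) / sum(pr)
    out[seq_len(n - k_tail)] <- xs[findInterval(runif(n - k_tail), cum) + 1L]
  }
  if (k_tail > 0) {
    out[(n - k_tail + 1):n] <- rdiscgpd(k_tail, u, model$sigma, model$xi)
  }
  sample(out)
}

# smallest integer x with total remaining mass 1 - F(x) < tol
spliced_upper_quantile <- function(model, tol = 1e-10) {
  u <- model$u; phi <- model$phi; sigma <- model$sigma; xi <- model$xi
  if (phi <= tol) return(u)
  if (xi < 0) return(discgpd_support(u, sigma, xi)[2])
  # solve phi * S(x + 1 - u) < tol
  s <- tol / phi
  if (abs(xi) < 1e-8) z <- -sigma * base::log(s) else z <- sigma / xi * expm1(-xi * base::log(s))
  max(u, ceiling(u - 1 + z))
}
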