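#' Discrete Gamma distribution
#'
#' Probability mass, distribution, and random generation for the discrete
#' Gamma distribution obtained by quantizing a continuous Gamma(shape, rate)
#' at unit intervals: `Pr(X = x) = Psi(x + 1) - Psi(x)` where `Psi` is the
#' continuous Gamma distribution function. Equivalently, `X = floor(Y)` with
#' `Y ~ Gamma(shape, rate)`. The support is the nonnegative integers.
#'
#' The pmf can be written in terms of the lower incomplete gamma function
#' `gamma(a, s)` as `[gamma(shape, rate * (x + 1)) - gamma(shape, rate * x)] /
#' Gamma(shape)`; [stats::pgamma()] supplies the regularized incomplete gamma.
#'
#' @param x vector of nonnegative integers (clone sizes).
#' @param q vector of quantiles; non-integers are floored.
#' @param n number of draws.
#' @param shape,rate Gamma shape `alpha > 0` and rate `beta > 0`.
#' @param log logical; return log pmf?
#' @return `ddiscgamma` the pmf, `pdiscgamma` the cdf (`P(X <= q)`),
#'   `rdiscgamma` integer draws.
#' @examples
#' ddiscgamma(0, shape = 1, rate = 0.5)   # 1 - exp(-0.5)
#' sum(ddiscgamma(0:500, shape = 3, rate = 0.15))
#' @export
ddiscgamma <- function(x, shape, rate, log = FALSE) {
  check_gamma_params(shape, rate)
  if (any(!is_wholenumber(x)) || any(x < 0)) {
    stop_domain("'x' must contain nonnegative integers")
  }
  # take the difference on whichever Gamma tail is small: far above the mean
  # the lower-tail difference cancels catastrophically
  upper <- x >= shape / rate
  p <- numeric(length(x))
  p[!upper] <- pgamma(x[!upper] + 1, shape = shape, rate = rate) -
    pgamma(x[!upper], shape = shape, rate = rate)
  p[upper] <- pgamma(x[upper], shape = shape, rate = rate, lower.tail = FALSE) -
    pgamma(x[upper] + 1, shape = shape, rate = rate, lower.tail = FALSE)
  p <- pmax(p, 0)
  if (log) base::log(p) else p
}

#' @rdname ddiscgamma
#' @export
pdiscgamma <- function(q, shape, rate) {
  check_gamma_params(shape, rate)
  if (any(!is.finite(q) & !is.infinite(q))) stop_domain("'q' must be numeric")
  q <- floor(q)
  out <- numeric(length(q))
  ok <- q >= 0
  out[ok] <- pgamma(q[ok] + 1, shape = shape, rate = rate)
  out
}

#' @rdname ddiscgamma
#' @export
rdiscgamma <- function(n, shape, rate) {
  check_gamma_params(shape, rate)
  floor(stats::rgamma(n, shape = shape, rate = rate))
}

check_gamma_params <- function(shape, rate) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0) {
    stop_domain("'shape' must be a single positive number")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop_domain("'rate' must be a single positive number")
  }
  invisible(TRUE)
}

# log survival function of the continuous GPD at excess z = x - u, i.e.
# log[(1 + xi * z / sigma)^(-1/xi)], with the exponential limit for |xi| small
# and -Inf beyond the upper bound when xi < 0.  Vectorized over z.
lsurv_gpd <- function(z, sigma, xi) {
  z <- pmax(z, 0)
  if (abs(xi) < 1e-8) return(-z / sigma)
  t <- xi * z / sigma
  out <- rep(-Inf, length(z))
  ok <- (1 + t) > 0
  out[ok] <- -log1p(t[ok]) / xi
  out
}

check_gpd_params <- function(u, sigma, xi) {
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u)) {
    stop_domain("'u' must be a single finite number")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop_domain("'sigma' must be a single positive number")
  }
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi)) {
    stop_domain("'xi' must be a single finite number")
  }
  invisible(TRUE)
}

#' Discrete generalized Pareto distribution
#'
#' Probability mass, distribution, quantile, and random generation for the
#' discrete GPD with threshold `u`, scale `sigma > 0`, and shape `xi`,
#' obtained by quantizing the continuous GPD at unit intervals:
#' `Pr(X = x) = S(x) - S(x + 1)` with survival
#' `S(x) = (1 + xi * (x - u) / sigma)^(-1/xi)`. The support is the integers
#' `x >= u` when `xi >= 0` and `u <= x <= floor(u - sigma / xi)` when
#' `xi < 0`. For `|xi| < 1e-8` the exponential limit
#' `S(x) = exp(-(x - u) / sigma)` is used.
#'
#' @param x integer quantiles; values outside the support have mass 0.
#' @param q quantiles; non-integers are floored.
#' @param p probabilities in `[0, 1)`; `p = 1` is admitted only when
#'   `xi < 0` (bounded support).
#' @param n number of draws.
#' @param u,sigma,xi threshold, scale (> 0), and shape.
#' @param log logical; return log pmf?
#' @return pmf values, cdf values, integer quantiles (the smallest support
#'   point with cdf at or above `p`), or integer draws.
#' @examples
#' ddiscgpd(0, u = 0, sigma = 1, xi = 1)       # 1/1 - 1/2
#' qdiscgpd(0, u = 5, sigma = 4, xi = 0.5)     # the threshold itself
#' @export
ddiscgpd <- function(x, u, sigma, xi, log = FALSE) {
  check_gpd_params(u, sigma, xi)
  out <- rep(if (log) -Inf else 0, length(x))
  sup <- discgpd_support(u, sigma, xi)
  ok <- is_wholenumber(x) & x >= sup[1] & x <= sup[2]
  if (any(ok)) {
    l1 <- lsurv_gpd(x[ok] - u, sigma, xi)
    l2 <- lsurv_gpd(x[ok] + 1 - u, sigma, xi)
    lg <- ifelse(is.infinite(l2), l1, l1 + base::log(-expm1(pmin(l2 - l1, -1e-300))))
    out[ok] <- if (log) lg else exp(lg)
  }
  out
}

#' @rdname ddiscgpd
#' @export
pdiscgpd <- function(q, u, sigma, xi) {
  check_gpd_params(u, sigma, xi)
  q <- floor(q)
  out <- numeric(length(q))
  ok <- q >= u
  out[ok] <- -expm1(lsurv_gpd(q[ok] + 1 - u, sigma, xi))
  out
}

#' @rdname ddiscgpd
#' @export
qdiscgpd <- function(p, u, sigma, xi) {
  check_gpd_params(u, sigma, xi)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_domain("'p' must lie in [0, 1]")
  }
  if (xi >= 0 && any(p == 1)) {
    stop_domain("p = 1 requested but the support is unbounded (xi >= 0)")
  }
  # continuous excess quantile z(p): S(z) = 1 - p
  if (abs(xi) < 1e-8) {
    z <- -sigma * log1p(-p)
  } else {
    z <- sigma / xi * expm1(-xi * log1p(-p))
  }
  out <- pmax(ceiling(u + z - 1), u)
  sup <- discgpd_support(u, sigma, xi)
  pmin(out, sup[2])
}

#' @rdname ddiscgpd
#' @export
rdiscgpd <- function(n, u, sigma, xi) {
  qdiscgpd(runif(n), u, sigma, xi)
}

#' Support of the discrete GPD
#'
#' @inheritParams ddiscgpd
#' @return integer vector `c(lower, upper)`; `upper` is `Inf` when `xi >= 0`.
#' @export
discgpd_support <- function(u, sigma, xi) {
  check_gpd_params(u, sigma, xi)
  if (xi >= 0) c(u, Inf) else c(u, floor(u - sigma / xi))
}

#' Continuous GPD distribution function
#'
#' `F(y) = 1 - (1 + xi * (y - u) / sigma)^(-1/xi)` for `y >= u` (0 below).
#' At `sigma = u / alpha_d`, `xi = 1 / alpha_d` this coincides with the
#' type-I Pareto distribution function `1 - (u / y)^alpha_d`, the identity
#' that links the GPD tail shape to the Pareto shape parameter.
#'
#' @param q quantiles.
#' @inheritParams ddiscgpd
#' @return cdf values.
#' @export
pgpd <- function(q, u, sigma, xi) {
  check_gpd_params(u, sigma, xi)
  out <- numeric(length(q))
  ok <- q >= u
  out[ok] <- -expm1(lsurv_gpd(q[ok] - u, sigma, xi))
  out
}

#' Continuous GPD density
#'
#' @inheritParams pgpd
#' @return density values (0 outside the support).
#' @export
dgpd <- function(q, u, sigma, xi) {
  check_gpd_params(u, sigma, xi)
  out <- numeric(length(q))
  z <- q - u
  if (abs(xi) < 1e-8) {
    ok <- z >= 0
    out[ok] <- exp(-z[ok] / sigma) / sigma
  } else {
    t <- xi * z / sigma
    ok <- z >= 0 & (1 + t) > 0
    out[ok] <- exp(-(1 / xi + 1) * log1p(t[ok])) / sigma
  }
  out
}
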