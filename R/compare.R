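#' Jensen-Shannon divergence between fitted spliced models
#'
#' Evaluates both pmfs over the integer support, renormalizes, and returns
#' `0.5 * [sum P log(P/M) + sum Q log(Q/M)]` with `M = (P + Q) / 2` and
#' `0 log 0 = 0` (natural log, so the value lies in `[0, log 2]`).
#'
#' The support is truncated where both models' remaining tail mass drops
#' below `tol`. Clone sizes up to `exact_limit` are enumerated exactly; for
#' very heavy tails (`xi` near 1) the truncation point can exceed 1e10, so
#' the remainder is accumulated over a fine geometric binning (edge ratio
#' `bin_ratio`) with bin masses taken from the closed-form distribution
#' functions. The binned remainder carries a negligible share of the mass,
#' so the additional error is far below `tol`-level effects.
#'
#' @param P,Q [spliced_model()] objects (or `spliced_fit` objects, whose
#'   models are used).
#' @param tol remaining tail mass at which the support is truncated.
#' @param exact_limit largest clone size enumerated exactly.
#' @param bin_ratio geometric ratio of bin edges beyond `exact_limit`.
#' @param sqrt logical; return the square root (the metric form)?
#' @return the divergence in nats (or its square root).
#' @export
jsd_spliced <- function(P, Q, tol = 1e-10, exact_limit = 1e6,
                        bin_ratio = 1.0005, sqrt = FALSE) {
  if (inherits(P, "spliced_fit")) P <- P$model
  if (inherits(Q, "spliced_fit")) Q <- Q$model
  stopifnot(inherits(P, "spliced_model"), inherits(Q, "spliced_model"))
  lo <- min(bulk_lower(P), bulk_lower(Q))
  xmax <- max(spliced_upper_quantile(P, tol), spliced_upper_quantile(Q, tol),
              P$u + 1, Q$u + 1)
  x1 <- min(xmax, exact_limit)
  xs <- lo:x1
  p <- dspliced(xs, P)
  q <- dspliced(xs, Q)
  if (xmax > x1) {
    k <- ceiling(log(xmax / x1) / log(bin_ratio))
    edges <- unique(c(x1, ceiling(x1 * bin_ratio^seq_len(k))))
    edges[length(edges)] <- max(edges[length(edges)], xmax)
    p <- c(p, diff(pspliced(edges, P)))
    q <- c(q, diff(pspliced(edges, Q)))
  }
  p <- pmax(p, 0); q <- pmax(q, 0)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  js <- 0.5 * (sum(p[p > 0] * log(p[p > 0] / m[p > 0])) +
               sum(q[q > 0] * log(q[q > 0] / m[q > 0])))
  js <- min(max(js, 0), log(2))
  if (sqrt) base::sqrt(js) else js
}

#' Jensen-Shannon divergence between type-I Pareto tail fits
#'
#' Continuous generalization of the Jensen-Shannon divergence, trading the
#' summation for an integral of the same integrand over the union support.
#' Each density is treated as 0 below its own threshold, so on
#' `[min(u), max(u))` only one density is positive and the contribution
#' reduces to `log(2) / 2` times that model's mass there; the remainder is
#' evaluated by adaptive quadrature ([stats::integrate()]).
#'
#' @param P,Q `desponds_fit` objects (see [fit_desponds()]) or lists with
#'   elements `u` and `alpha_d`.
#' @param rel.tol relative tolerance of the quadrature.
#' @param sqrt logical; return the square root?
#' @return the divergence in nats.
#' @export
jsd_desponds <- function(P, Q, rel.tol = 1e-8, sqrt = FALSE) {
  stopifnot(is.numeric(P$u), is.numeric(P$alpha_d),
            is.numeric(Q$u), is.numeric(Q$alpha_d))
  dpareto <- function(x, u, a) ifelse(x >= u, a * u^a / x^(a + 1), 0)
  ppareto <- function(x, u, a) ifelse(x >= u, 1 - (u / x)^a, 0)
  ulo <- min(P$u, Q$u); uhi <- max(P$u, Q$u)
  js <- 0
  if (uhi > ulo) {
    lowmass <- if (P$u < Q$u) ppareto(uhi, P$u, P$alpha_d)
               else ppareto(uhi, Q$u, Q$alpha_d)
    js <- js + 0.5 * log(2) * lowmass
  }
  integrand <- function(x) {
    fp <- dpareto(x, P$u, P$alpha_d)
    fq <- dpareto(x, Q$u, Q$alpha_d)
    m <- (fp + fq) / 2
    tp <- ifelse(fp > 0, fp * log(fp / m), 0)
    tq <- ifelse(fq > 0, fq * log(fq / m), 0)
    0.5 * (tp + tq)
  }
  js <- js + integrate(integrand, uhi, Inf, rel.tol = rel.tol,
                       subdivisions = 1000L)$value
  js <- min(max(js, 0), log(2))
  if (sqrt) base::sqrt(js) else js
}

#' Pairwise distance matrix over a cohort of fits
#'
#' Fills a symmetric distance matrix across a labeled collection of fitted
#' models: Jensen-Shannon divergence between spliced model pmfs
#' (`method = "spliced"`), continuous Jensen-Shannon divergence between
#' Pareto comparator fits (`method = "desponds"`), or Euclidean distance
#' between per-sample statistic vectors (`method = "estimator"`, e.g. rows
#' of centered and scaled diversity estimates).
#'
#' @param fits a list of `spliced_fit` or `desponds_fit` objects (ignored
#'   for `method = "estimator"`); mixed types are an error.
#' @param method distance flavour.
#' @param stats numeric matrix or data frame (samples in rows) for
#'   `method = "estimator"`.
#' @param labels optional character labels; defaults to fit labels or
#'   `stats` row names.
#' @param sqrt logical; use the square-root (metric) form of the divergence?
#' @param ... passed to [jsd_spliced()] or [jsd_desponds()].
#' @return an object of class `dist_matrix`: a list with `labels` and the
#'   symmetric `values` matrix (zero diagonal).
#' @export
pairwise_distances <- function(fits = NULL,
                               method = c("spliced", "desponds", "estimator"),
                               stats = NULL, labels = NULL, sqrt = FALSE, ...) {
  method <- match.arg(method)
  if (method == "estimator") {
    if (is.null(stats)) stop_domain("'stats' is required for method = 'estimator'")
    m <- as.matrix(stats)
    labels <- labels %||% rownames(m) %||% paste0("sample", seq_len(nrow(m)))
    d <- as.matrix(stats::dist(m))
    dimnames(d) <- list(labels, labels)
    return(structure(list(labels = labels, values = d), class = "dist_matrix"))
  }
  if (length(fits) < 2L) stop_domain("need at least 2 fits")
  cls <- if (method == "spliced") "spliced_fit" else "desponds_fit"
  okcls <- vapply(fits, function(f) {
    inherits(f, cls) || (method == "spliced" && inherits(f, "spliced_model"))
  }, logical(1))
  if (!all(okcls)) {
    stop_domain("all fits must be of class '", cls, "' for method = '",
                method, "' (mixed fit types are not comparable)")
  }
  labels <- labels %||% names(fits) %||%
    vapply(seq_along(fits), function(i) fits[[i]]$label %||% paste0("sample", i),
           character(1))
  n <- length(fits)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  fun <- if (method == "spliced") jsd_spliced else jsd_desponds
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- fun(fits[[i]], fits[[j]], sqrt = sqrt, ...)
    }
  }
  structure(list(labels = labels, values = d), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Pairwise distance matrix over %d samples\n", length(x$labels)))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Hierarchical clustering and ordination of a cohort
#'
#' `cluster_samples` runs Ward agglomerative clustering (the squared-update
#' "ward.D2" convention) on a [pairwise_distances()] matrix. `embed_mds`
#' computes a non-metric multidimensional scaling embedding
#' ([MASS::isoMDS()], initialized from classical scaling) and reports the
#' stress.
#'
#' @param D a `dist_matrix`.
#' @param method linkage passed to [stats::hclust()].
#' @param k embedding dimension (default 2).
#' @param seed RNG seed fixed around the embedding for reproducibility.
#' @return `cluster_samples`: an [stats::hclust()] tree. `embed_mds`: a list
#'   with `points` (labeled coordinate matrix) and `stress` (Kruskal
#'   stress-1, percent).
#' @export
cluster_samples <- function(D, method = "ward.D2") {
  stopifnot(inherits(D, "dist_matrix"))
  hclust(stats::as.dist(D$values), method = method)
}

#' @rdname cluster_samples
#' @export
embed_mds <- function(D, k = 2, seed = 1) {
  stopifnot(inherits(D, "dist_matrix"))
  n <- length(D$labels)
  if (n < 3) stop_domain("non-metric MDS needs at least 3 samples")
  v <- D$values
  # isoMDS rejects zero off-diagonal dissimilarities; nudge exact duplicates
  off <- v[upper.tri(v)]
  if (any(off <= 0)) {
    eps <- max(min(off[off > 0], na.rm = TRUE) * 1e-6, 1e-12)
    v[v <= 0] <- eps
    diag(v) <- 0
  }
  d <- stats::as.dist(v)
  fit <- withr::with_seed(seed, MASS::isoMDS(d, k = k, trace = FALSE))
  rownames(fit$points) <- D$labels
  list(points = fit$points, stress = fit$stress)
}
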