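#' Ecological diversity statistics for a repertoire
#'
#' `richness` counts unique clonotypes; `shannon` is the Shannon entropy
#' `H = -sum(p_i * log(p_i))` of the clone frequency distribution
#' `p_i = count_i / total_reads` (in nats by default); `clonality` is one
#' minus Pielou's evenness, `C = 1 - H / log(S)`, which is 0 for a perfectly
#' even repertoire and approaches 1 for a repertoire dominated by a single
#' clone. A single-clonotype sample has `H = 0` and, by convention,
#' `C = 1` (the fully clonal limit; the ratio is otherwise 0/0).
#'
#' @param sample a [clone_sample()] or a vector of positive integer counts.
#' @param base logarithm base for `shannon` (default `exp(1)`, nats).
#' @return a scalar statistic.
#' @examples
#' clonality(c(1, 1, 2))
#' shannon(rep(5, 10))  # log(10): maximum entropy
#' @export
richness <- function(sample) {
  sample <- as_clone_sample(sample)
  length(sample$counts)
}

#' @rdname richness
#' @export
shannon <- function(sample, base = exp(1)) {
  sample <- as_clone_sample(sample)
  p <- sample$counts / sample$total_reads
  -sum(p * log(p, base = base))
}

#' @rdname richness
#' @export
clonality <- function(sample) {
  sample <- as_clone_sample(sample)
  s <- length(sample$counts)
  if (s == 1L) return(1)
  1 - shannon(sample) / log(s)
}

#' Proportion of highly stimulated clones
#'
#' Reads carried by clones at or above a size threshold, as a fraction of
#' all reads in the repertoire. With the threshold from a spliced model fit,
#' this measures the share of the repertoire attributable to clones in the
#' power-law (actively stimulated) regime.
#'
#' @inheritParams richness
#' @param u size threshold (e.g. the fitted `u` of a [fit_spliced()] model).
#' @return a fraction in `[0, 1]`, nonincreasing in `u`.
#' @export
proportion_stimulated <- function(sample, u) {
  sample <- as_clone_sample(sample)
  if (!is.numeric(u) || length(u) != 1L || u < 1) {
    stop_domain("'u' must be a single threshold >= 1")
  }
  sum(sample$counts[sample$counts >= u]) / sample$total_reads
}

#' Diversity summary table for a cohort
#'
#' @param samples a list of [clone_sample()] objects (a cohort).
#' @param thresholds optional numeric vector (one per sample) of size
#'   thresholds; when supplied, `prop_stimulated` is included.
#' @return a data frame with one row per sample: `label`, `richness`,
#'   `shannon`, `clonality`, and optionally `prop_stimulated`.
#' @export
diversity_table <- function(samples, thresholds = NULL) {
  samples <- lapply(samples, as_clone_sample)
  out <- data.frame(
    label = vapply(samples, function(s) s$label, character(1)),
    richness = vapply(samples, richness, numeric(1)),
    shannon = vapply(samples, shannon, numeric(1)),
    clonality = vapply(samples, clonality, numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == length(samples))
    out$prop_stimulated <- mapply(proportion_stimulated, samples, thresholds)
  }
  rownames(out) <- NULL
  out
}
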