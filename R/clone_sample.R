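#' A sample repertoire of clone sizes
#'
#' A `clone_sample` holds one sample's clone size distribution: one positive
#' integer read count per clonotype. The order of counts carries no meaning;
#' all downstream fits are permutation invariant.
#'
#' @param counts vector of positive integers (reads per clonotype).
#' @param label sample identifier.
#' @return an object of class `clone_sample` with elements `counts`,
#'   `label`, `n` (number of clonotypes), and `total_reads`.
#' @examples
#' s <- clone_sample(c(1, 1, 2, 5, 40), label = "toy")
#' s$n
#' s$total_reads
#' @export
clone_sample <- function(counts, label = "sample") {
  if (length(counts) < 1L) stop_domain("a sample needs at least one clonotype")
  if (any(!is_wholenumber(counts)) || any(counts < 1)) {
    stop_domain("clone sizes must be positive integers")
  }
  counts <- as.numeric(round(counts))
  structure(
    list(counts = counts, label = as.character(label)[1],
         n = length(counts), total_reads = sum(counts)),
    class = "clone_sample"
  )
}

#' @export
print.clone_sample <- function(x, ...) {
  cat(sprintf("clone_sample '%s': %d clonotypes, %s reads, max clone %s\n",
              x$label, x$n, format(x$total_reads, big.mark = ","),
              format(max(x$counts))))
  invisible(x)
}

as_clone_sample <- function(x, label = "sample") {
  if (inherits(x, "clone_sample")) x else clone_sample(x, label)
}
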