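#' Draw a repertoire from a spliced model
#'
#' Each clone size is drawn independently: with probability `1 - phi` from
#' the truncated discrete Gamma bulk (inverse-cdf on a tabulated bulk pmf),
#' otherwise from the discrete GPD tail (closed-form quantile on uniforms).
#'
#' @param model a [spliced_model()].
#' @param n_clones number of clonotypes to draw.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param label sample label.
#' @return a [clone_sample()].
#' @export
generate_repertoire <- function(model, n_clones, seed, label = "sim") {
  stopifnot(inherits(model, "spliced_model"), n_clones >= 1)
  counts <- withr::with_seed(as.integer(seed), rspliced(n_clones, model))
  if (model$bulk_includes_zero) counts <- counts[counts >= 1]
  clone_sample(counts, label = label)
}

#' Factorial simulation design for the clonality-shape study
#'
#' Describes a full-factorial cohort over the bulk shape `alpha`, tail shape
#' `xi`, and tail fraction `phi`, at fixed bulk rate `beta`. For each cell
#' the threshold is `u = floor(Q_{alpha,beta}(1 - phi))` (the Gamma quantile
#' function) and the tail scale follows `sigma_rule`: `"mean"` sets
#' `sigma = alpha / beta` (the bulk Gamma mean, the default) while
#' `"product"` sets `sigma = alpha * beta`. The default grids give the
#' 48-sample reference design (3 x 4 x 4) with `n = 20,000` clonotypes per
#' sample.
#'
#' @param alpha_grid,xi_grid,phi_grid parameter grids.
#' @param beta fixed bulk rate.
#' @param n_clones clonotypes per sample.
#' @param seed master seed; per-cell seeds are derived deterministically.
#' @param sigma_rule how the tail scale derives from `(alpha, beta)`.
#' @return an object of class `simulation_design` with the grid expanded
#'   into a `cells` data frame (one row per sample with all generating
#'   parameters and the derived `u`, `sigma`, and per-cell seed).
#' @export
simulation_design <- function(alpha_grid = c(3, 5, 10),
                              xi_grid = c(0.25, 0.5, 0.75, 1.1),
                              phi_grid = c(0.1, 0.15, 0.2, 0.25),
                              beta = 0.15, n_clones = 20000, seed = 1,
                              sigma_rule = c("mean", "product")) {
  sigma_rule <- match.arg(sigma_rule)
  grid <- expand.grid(phi = phi_grid, xi = xi_grid, alpha = alpha_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("alpha", "xi", "phi")]
  grid$beta <- beta
  grid$sigma <- if (sigma_rule == "mean") grid$alpha / beta else grid$alpha * beta
  grid$u <- floor(qgamma(1 - grid$phi, shape = grid$alpha, rate = beta))
  grid$seed <- vapply(seq_len(nrow(grid)), function(i) derive_seed(seed, i),
                      integer(1))
  grid$label <- sprintf("alpha%g_xi%g_phi%g", grid$alpha, grid$xi, grid$phi)
  bad <- grid$u < 2
  if (any(bad)) {
    stop_domain("design cell(s) yield threshold u < 2: ",
                paste(grid$label[bad], collapse = ", "))
  }
  structure(list(cells = grid, n_clones = n_clones, seed = as.integer(seed),
                 sigma_rule = sigma_rule),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("Simulation design: %d cells x %d clonotypes (master seed %d, sigma_rule '%s')\n",
              nrow(x$cells), x$n_clones, x$seed, x$sigma_rule))
  invisible(x)
}

#' Materialize a simulation design into a cohort
#'
#' Draws one [clone_sample()] per design cell with that cell's derived
#' threshold, scale, and seed. Regenerating from the same design reproduces
#' identical counts.
#'
#' @param design a [simulation_design()].
#' @return a named list of [clone_sample()] objects with the design's
#'   `cells` data frame attached as attribute `"manifest"`.
#' @export
build_design_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  cells <- design$cells
  cohort <- lapply(seq_len(nrow(cells)), function(i) {
    ci <- cells[i, ]
    model <- spliced_model(ci$alpha, ci$beta, ci$u, ci$sigma, ci$xi, ci$phi)
    generate_repertoire(model, design$n_clones, seed = ci$seed,
                        label = ci$label)
  })
  names(cohort) <- cells$label
  attr(cohort, "manifest") <- cells
  cohort
}

#' Downsample reads without replacement
#'
#' Draws `target_reads` reads from the sample's read pool without
#' replacement (multivariate hypergeometric across clonotypes), emulating a
#' shallower sequencing run. Clonotypes whose count reaches zero are
#' dropped (they would be unobservable).
#'
#' @param sample a [clone_sample()].
#' @param target_reads number of reads to keep; must not exceed the
#'   sample's total.
#' @param seed integer seed.
#' @return a [clone_sample()] with exactly `target_reads` total reads.
#' @export
downsample_reads <- function(sample, target_reads, seed) {
  sample <- as_clone_sample(sample)
  total <- sample$total_reads
  if (!is_wholenumber(target_reads) || target_reads < 1 || target_reads > total) {
    stop_domain("'target_reads' must be an integer in [1, total_reads]")
  }
  if (target_reads == total) return(sample)
  counts <- sample$counts
  new_counts <- withr::with_seed(as.integer(seed), {
    if (total <= 5e7) {
      pool <- rep.int(seq_along(counts), counts)
      kept <- pool[sample.int(total, target_reads)]
      tabulate(kept, nbins = length(counts))
    } else {
      # sequential conditional hypergeometric draws (exact, memory-light)
      out <- integer(length(counts))
      remaining <- total
      left <- target_reads
      for (i in seq_along(counts)) {
        if (left == 0L) break
        out[i] <- stats::rhyper(1, counts[i], remaining - counts[i], left)
        left <- left - out[i]
        remaining <- remaining - counts[i]
      }
      out
    }
  })
  clone_sample(new_counts[new_counts > 0], label = sample$label)
}

#' Equalize sequencing depth across a cohort
#'
#' Downsamples every sample to a common number of reads (the cohort minimum
#' by default) so that depth-sensitive statistics such as clonality are
#' comparable across samples.
#'
#' @param cohort a list of [clone_sample()] objects.
#' @param depth common depth; defaults to the minimum total reads in the
#'   cohort. Must not exceed any sample's total.
#' @param seed integer seed; per-sample seeds are derived deterministically.
#' @return a list of downsampled samples with attribute `"depth"`.
#' @export
equalize_depth <- function(cohort, depth = NULL, seed = 1) {
  manifest <- attr(cohort, "manifest")
  cohort <- lapply(cohort, as_clone_sample)
  totals <- vapply(cohort, function(s) s$total_reads, numeric(1))
  depth <- depth %||% min(totals)
  if (any(totals < depth)) stop_domain("'depth' exceeds a sample's total reads")
  out <- lapply(seq_along(cohort), function(i) {
    downsample_reads(cohort[[i]], depth, seed = derive_seed(seed, i))
  })
  names(out) <- names(cohort)
  attr(out, "manifest") <- manifest
  attr(out, "depth") <- depth
  out
}
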