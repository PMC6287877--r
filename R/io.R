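#' Read clone-count data
#'
#' Reads a sample repertoire from disk. `format = "two_column_tsv"` expects
#' two tab-separated columns, clonotype key and read count (a header line
#' is detected and skipped if the second field is not numeric).
#' `format = "airr_tsv"` expects an AIRR-style rearrangement table with a
#' header, and aggregates the duplicate-count column per clonotype key.
#' Duplicate keys are summed with a warning; zero or negative counts are
#' rejected with the offending row number.
#'
#' @param path file path.
#' @param format input dialect.
#' @param label sample label; defaults to the file name without extension.
#' @param key_col,count_col column names for the AIRR dialect (clonotype
#'   key and duplicate count).
#' @return a [clone_sample()] with the per-clonotype counts as attribute
#'   `"clonotypes"` (named integer vector).
#' @export
read_clone_table <- function(path, format = c("two_column_tsv", "airr_tsv"),
                             label = NULL,
                             key_col = "junction_aa",
                             count_col = "duplicate_count") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_domain("file not found: ", path)
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "two_column_tsv") {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character", blank.lines.skip = TRUE)
    if (nrow(raw) == 0L || ncol(raw) < 2L) {
      stop_domain("expected a two-column TSV with clonotype and count: ", path)
    }
    offset <- 0L
    if (suppressWarnings(is.na(as.numeric(raw[1, 2])))) {
      raw <- raw[-1, , drop = FALSE]   # header line
      offset <- 1L
      if (nrow(raw) == 0L) stop_domain("no data rows in ", path)
    }
    keys <- raw[[1]]
    cnt <- suppressWarnings(as.numeric(raw[[2]]))
  } else {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) stop_domain("no data rows in ", path)
    missing <- setdiff(c(key_col, count_col), names(tab))
    if (length(missing)) {
      stop_domain("missing column(s) in AIRR table: ",
                  paste(missing, collapse = ", "))
    }
    keys <- as.character(tab[[key_col]])
    cnt <- suppressWarnings(as.numeric(tab[[count_col]]))
    offset <- 1L
  }
  bad <- which(is.na(cnt) | cnt < 1 | abs(cnt - round(cnt)) > 1e-8)
  if (length(bad)) {
    stop_domain("row ", bad[1] + offset, " of ", basename(path),
                " has a non-positive or non-integer count")
  }
  agg <- tapply(cnt, keys, sum)
  if (length(agg) < length(keys)) {
    warning(length(keys) - length(agg),
            " duplicate clonotype key(s) aggregated by summing counts")
  }
  out <- clone_sample(as.numeric(agg), label = label)
  attr(out, "clonotypes") <- setNames(as.integer(agg), names(agg))
  out
}

#' @rdname read_clone_table
#' @param sample a [clone_sample()] to write.
#' @export
write_clone_table <- function(sample, path) {
  sample <- as_clone_sample(sample)
  keys <- names(attr(sample, "clonotypes")) %||%
    sprintf("clone%06d", seq_along(sample$counts))
  utils::write.table(
    data.frame(clonotype = keys, count = as.integer(sample$counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize and restore fit records
#'
#' Fits are written as flat JSON records holding the sample description,
#' all parameters, and the per-candidate profile/trace table. Numbers are
#' serialized at full precision, so a write/read round trip reproduces
#' every parameter bit-exactly.
#'
#' @param fit a `spliced_fit` or `desponds_fit`.
#' @param path output path.
#' @return `write_fit` the path, invisibly; `read_fit` the restored fit.
#' @export
write_fit <- function(fit, path) {
  if (inherits(fit, "spliced_fit")) {
    m <- fit$model
    # JSON has no -Inf; failed candidates are stored as missing
    fit$profile$loglik[!is.finite(fit$profile$loglik)] <- NA_real_
    rec <- list(type = "spliced", label = fit$label, n = fit$n,
                total_reads = fit$total_reads, u = m$u, alpha = m$alpha,
                beta = m$beta, sigma = m$sigma, xi = m$xi, phi = m$phi,
                bulk_includes_zero = m$bulk_includes_zero,
                loglik = fit$loglik, n_u = fit$n_u, profile = fit$profile)
  } else if (inherits(fit, "desponds_fit")) {
    rec <- list(type = "desponds", label = fit$label, n = fit$n,
                total_reads = fit$total_reads, u = fit$u,
                alpha_d = fit$alpha_d, ks = fit$ks, n_tail = fit$n_tail,
                trace = fit$trace)
  } else stop_domain("unsupported fit object")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- as.numeric   # JSON integers parse as integer; fits store doubles
  if (identical(rec$type, "spliced")) {
    model <- spliced_model(num(rec$alpha), num(rec$beta), num(rec$u),
                           num(rec$sigma), num(rec$xi), num(rec$phi),
                           bulk_includes_zero = isTRUE(rec$bulk_includes_zero))
    profile <- as.data.frame(rec$profile)
    profile$u <- num(profile$u)
    profile$loglik <- num(profile$loglik)
    structure(list(model = model, loglik = num(rec$loglik),
                   profile = profile,
                   n_u = as.integer(rec$n_u), label = rec$label,
                   n = as.integer(rec$n), total_reads = num(rec$total_reads)),
              class = "spliced_fit")
  } else if (identical(rec$type, "desponds")) {
    trace <- as.data.frame(rec$trace)
    trace$u <- num(trace$u)
    trace$alpha_d <- num(trace$alpha_d)
    trace$ks <- num(trace$ks)
    structure(list(u = num(rec$u), alpha_d = num(rec$alpha_d),
                   ks = num(rec$ks), n_tail = as.integer(rec$n_tail),
                   trace = trace, label = rec$label,
                   n = as.integer(rec$n), total_reads = num(rec$total_reads)),
              class = "desponds_fit")
  } else stop_domain("unrecognized fit record: ", path)
}

#' Write cohort comparison artifacts
#'
#' `write_distance_matrix` writes a labeled square TSV;
#' `read_distance_matrix` restores it. `write_dendrogram_newick` converts an
#' [stats::hclust()] tree to Newick text (via [ape::as.phylo()]).
#' `write_mds_coords` writes non-metric MDS coordinates as TSV.
#'
#' @param D a `dist_matrix`.
#' @param hc an `hclust` tree.
#' @param mds result of [embed_mds()].
#' @param path output path.
#' @export
write_distance_matrix <- function(D, path) {
  stopifnot(inherits(D, "dist_matrix"))
  utils::write.table(D$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  colnames(m) <- rownames(m)
  structure(list(labels = rownames(m), values = m), class = "dist_matrix")
}

#' @rdname write_distance_matrix
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
write_mds_coords <- function(mds, path) {
  pts <- as.data.frame(mds$points)
  names(pts) <- paste0("dim", seq_len(ncol(pts)))
  utils::write.table(cbind(label = rownames(pts), pts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write or read a simulated cohort
#'
#' A cohort is a directory of per-sample two-column TSVs plus a
#' `manifest.tsv` recording label, file, and generating parameters.
#'
#' @param cohort a list of [clone_sample()] objects (optionally with a
#'   `"manifest"` attribute from [build_design_cohort()]).
#' @param dir directory (created if needed).
#' @return `write_cohort` the directory; `read_cohort` the cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(cohort) %||%
    vapply(cohort, function(s) s$label, character(1))
  files <- paste0(gsub("[^A-Za-z0-9._-]", "_", labels), ".tsv")
  for (i in seq_along(cohort)) {
    write_clone_table(cohort[[i]], file.path(dir, files[i]))
  }
  manifest <- attr(cohort, "manifest")
  mf <- data.frame(label = labels, file = files, stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    mf <- cbind(mf, manifest[, setdiff(names(manifest), c("label", "file")),
                             drop = FALSE])
  }
  utils::write.table(mf, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf_path)) stop_domain("no manifest.tsv in ", dir)
  mf <- utils::read.delim(mf_path, stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(mf)), function(i) {
    read_clone_table(file.path(dir, mf$file[i]), "two_column_tsv",
                     label = mf$label[i])
  })
  names(cohort) <- mf$label
  attr(cohort, "manifest") <- mf
  cohort
}
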