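#' Construct a genotype matrix
#'
#' A light container for hard-called dosages: a subjects x variants integer
#' matrix of allele1 counts (0/1/2, NA for missing) plus a variant annotation
#' table. Dosages count `allele1`, i.e. a dosage of 2 means homozygous for
#' `allele1`.
#'
#' @param dosages integer matrix, subjects in rows, variants in columns;
#'   values in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `id`, `chr`, `pos`, `allele1`,
#'   `allele2`.
#' @param subject_ids character vector of row identifiers.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants, subject_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  need <- c("id", "chr", "pos", "allele1", "allele2")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("variant table rows must match dosage columns")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(dosages)))
  if (length(subject_ids) != nrow(dosages))
    stop("subject_ids must match dosage rows")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must lie in {0, 1, 2} or be NA")
  ok_allele <- function(a) all(a %in% c("A", "C", "G", "T"))
  if (!ok_allele(variants$allele1) || !ok_allele(variants$allele2))
    stop("alleles must be single bases A/C/G/T")
  dimnames(dosages) <- list(as.character(subject_ids),
                            as.character(variants$id))
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants)[need],
                 subject_ids = as.character(subject_ids)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("geno_matrix: %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i subject index (logical, integer, or character ids).
#' @param j variant index (logical, integer, or character ids).
#' @param ... unused.
#' @return a `geno_matrix` restricted to the selected subjects/variants.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  d <- x$dosages[i, j, drop = FALSE]
  geno_matrix(d, x$variants[match(colnames(d), x$variants$id), , drop = FALSE],
              rownames(d))
}

# per-variant effective allele frequency of allele1, over called genotypes
allele1_freq <- function(G) {
  colMeans(G$dosages, na.rm = TRUE) / 2
}

# minor allele frequency per variant
geno_maf <- function(G) {
  p <- allele1_freq(G)
  pmin(p, 1 - p)
}

#' Quality-control report
#'
#' Records, for one QC stage, the per-filter removal counts, the retained
#' identifiers, and the thresholds used. `removed + retained` always equals
#' the input count on the filtered axis.
#'
#' @param stage character label for the QC stage.
#' @param axis `"variant"` or `"sample"`.
#' @param n_input number of items entering the stage.
#' @param removed_by named integer vector (per-filter counts; an item removed
#'   by several filters is attributed to the first that caught it).
#' @param retained character vector of ids that survive.
#' @param params list of thresholds in force.
#' @param details optional data.frame of per-item diagnostics.
#' @return object of class `qc_report`.
#' @export
qc_report <- function(stage, axis, n_input, removed_by, retained, params,
                      details = NULL) {
  n_removed <- n_input - length(retained)
  if (sum(removed_by) != n_removed)
    stop("inconsistent qc_report: filter counts do not sum to removals")
  structure(list(stage = stage, axis = axis, n_input = n_input,
                 n_removed = n_removed, removed_by = removed_by,
                 retained = retained, params = params, details = details),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC stage '%s' (%s level): %d in, %d removed, %d retained\n",
              x$stage, x$axis, x$n_input, x$n_removed, length(x$retained)))
  for (nm in names(x$removed_by))
    cat(sprintf("  - %-28s %d\n", nm, x$removed_by[[nm]]))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param x a [qc_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(x, path) {
  stopifnot(inherits(x, "qc_report"))
  jsonlite::write_json(
    list(stage = x$stage, axis = x$axis, n_input = x$n_input,
         n_removed = x$n_removed, removed_by = as.list(x$removed_by),
         n_retained = length(x$retained), params = x$params),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
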