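#' Genus-by-sample count matrix with group metadata
#'
#' The central container of the package: a taxon-by-sample abundance matrix
#' together with a sample-to-group map and a normalization flag. Raw matrices
#' hold non-negative integer read counts; normalized matrices (`"CPM"` or
#' `"TMM"`) hold non-negative reals.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; must carry
#'   row and column names.
#' @param groups named character vector mapping every sample (column) to a
#'   group label, e.g. genotype.
#' @param normalized one of `"raw"`, `"CPM"`, `"TMM"`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups, normalized = c("raw", "CPM", "TMM")) {
  normalized <- match.arg(normalized)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in count matrix")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and complete")
  groups <- groups[colnames(counts)]
  if (any(is.na(groups)))
    stop("metadata is missing a group label for sample(s): ",
         paste(colnames(counts)[is.na(groups)], collapse = ", "))
  structure(list(counts = counts, groups = as.character(groups),
                 samples = colnames(counts), taxa = rownames(counts),
                 normalized = normalized),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts), x$normalized))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a taxon count table and sample metadata
#'
#' Expects a TSV with a header row of sample identifiers and taxon identifiers
#' in the first column, plus a metadata TSV with columns `sample` and `group`.
#' All-zero taxon rows are retained (membership analysis needs absences).
#'
#' @param path path to the count TSV.
#' @param metadata_path path to the metadata TSV.
#' @return A raw [count_matrix()].
#' @export
read_count_table <- function(path, metadata_path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in count table header")
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  taxa <- as.character(tab[[1]])
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers in count table")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in count table")
  if (any(m < 0)) stop("negative values in count table")
  dimnames(m) <- list(taxa, samples)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(meta)))
    stop("metadata must have 'sample' and 'group' columns")
  groups <- stats::setNames(as.character(meta$group), as.character(meta$sample))
  missing <- setdiff(samples, names(groups))
  if (length(missing))
    stop("metadata is missing sample(s): ", paste(missing, collapse = ", "))
  count_matrix(m, groups, "raw")
}

#' Write a count matrix (and optionally its metadata) to TSV
#'
#' @param m a [count_matrix()].
#' @param path output TSV path for the counts.
#' @param metadata_path optional output TSV path for the sample metadata.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(m, path, metadata_path = NULL) {
  df <- data.frame(taxon = m$taxa, m$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(data.frame(sample = m$samples, group = m$groups),
                       metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Drop reads left unclassified at the species level
#'
#' Long-read 16S workflows attach a lowest-common-ancestor (LCA) status flag to
#' every read: -1 for an unsuccessful species-level classification, 0 for a
#' species and genus classification, 1 for species-only. Reads flagged -1 are
#' removed before any abundance analysis.
#'
#' @param lca_scores integer vector of per-read LCA flags in \{-1, 0, 1\}.
#' @return list with elements `kept` and `removed`; `kept + removed` equals
#'   `length(lca_scores)`.
#' @export
lca_filter <- function(lca_scores) {
  if (!length(lca_scores)) stop("no LCA records supplied")
  if (!all(lca_scores %in% c(-1L, 0L, 1L)))
    stop("LCA scores must be -1, 0 or 1")
  removed <- sum(lca_scores == -1L)
  list(kept = length(lca_scores) - removed, removed = removed)
}

#' Counts-per-million normalization
#'
#' Scales every sample (column) so it sums to one million, removing raw
#' library-size differences without rarefaction.
#'
#' @param m a raw [count_matrix()].
#' @return A `count_matrix` with `normalized = "CPM"`.
#' @export
cpm_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalized != "raw") stop("cpm_normalize expects a raw count matrix")
  cs <- colSums(m$counts)
  if (any(cs == 0))
    stop("zero-depth sample(s): ", paste(m$samples[cs == 0], collapse = ", "))
  out <- sweep(m$counts, 2, cs, "/") * 1e6
  count_matrix(out, stats::setNames(m$groups, m$samples), "CPM")
}

#' Trimmed-mean-of-M-values normalization
#'
#' Between-sample normalization correcting for compositional library-size bias:
#' a reference sample is chosen by upper-quartile proximity to the mean upper
#' quartile, per-sample scaling factors are the weighted trimmed means of
#' log2 count ratios (M) after double trimming on M and average intensity (A),
#' and factors are re-centered to geometric mean 1. Normalized abundances are
#' counts scaled per million of the effective (factor-adjusted) library size.
#'
#' The computation is delegated to \code{edgeR::calcNormFactors}.
#'
#' @param m a raw [count_matrix()] with at least two samples.
#' @param trim_m fraction trimmed on M values (default 0.30).
#' @param trim_a fraction trimmed on A values (default 0.05).
#' @return list with `matrix` (a `count_matrix`, `normalized = "TMM"`) and
#'   `factors` (list: `reference_sample`, `factors`, `trim_m`, `trim_a`).
#' @export
tmm_normalize <- function(m, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalized != "raw") stop("tmm_normalize expects raw counts")
  if (ncol(m$counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(m$counts)
  f <- edgeR::calcNormFactors(m$counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  # same reference rule edgeR applies: upper quartile of the scaled counts
  # closest to the mean upper quartile
  uq <- apply(sweep(m$counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- m$samples[which.min(abs(uq - mean(uq)))]
  eff <- lib * f
  normed <- sweep(m$counts, 2, eff, "/") * 1e6
  list(matrix = count_matrix(normed, stats::setNames(m$groups, m$samples), "TMM"),
       factors = list(reference_sample = ref,
                      factors = stats::setNames(as.numeric(f), m$samples),
                      trim_m = trim_m, trim_a = trim_a))
}
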