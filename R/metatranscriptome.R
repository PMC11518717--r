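#' Read a tabular protein-alignment hit file
#'
#' Accepts the 12-column tabular alignment dialect (query, subject, identity,
#' length, mismatches, gapopen, qstart, qend, sstart, send, e-value,
#' bitscore), optionally extended with `genus`, `lineage` and `trait_path`
#' columns. Files with a header row naming at least `transcript_id` and
#' `protein_id` are read as-is. Malformed rows are skipped and counted.
#'
#' @param path path to the TSV hit file.
#' @return data.frame with columns transcript_id, protein_id, e_value,
#'   bitscore and any of genus, lineage, trait_path present; attribute
#'   `n_skipped` counts dropped malformed rows.
#' @export
read_hit_table <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if ("transcript_id" %in% first) {
    hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 12) stop("expected >= 12 tab-separated columns")
    hits <- data.frame(transcript_id = as.character(raw[[1]]),
                       protein_id = as.character(raw[[2]]),
                       e_value = suppressWarnings(as.numeric(raw[[11]])),
                       bitscore = suppressWarnings(as.numeric(raw[[12]])),
                       stringsAsFactors = FALSE)
    extras <- c(genus = 13L, lineage = 14L, trait_path = 15L)
    for (nm in names(extras)) {
      if (ncol(raw) >= extras[[nm]]) hits[[nm]] <- as.character(raw[[extras[[nm]]]])
    }
  }
  bad <- is.na(hits$e_value) | is.na(hits$bitscore) | hits$e_value < 0
  if (any(bad)) hits <- hits[!bad, , drop = FALSE]
  attr(hits, "n_skipped") <- sum(bad)
  hits
}

#' Best-hit selection from raw alignment hits
#'
#' Drops hits with e-value above `e_max`, then keeps a single row per
#' transcript: highest bitscore, ties broken by lowest e-value then
#' lexicographic protein id (the `-top 1` best-hit annotation contract).
#'
#' @param hits data.frame with at least transcript_id, protein_id, e_value,
#'   bitscore.
#' @param e_max e-value cutoff (default 0.05).
#' @return One row per annotated transcript.
#' @export
select_best_hits <- function(hits, e_max = 0.05) {
  hits <- hits[hits$e_value <= e_max, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$transcript_id, -hits$bitscore, hits$e_value,
               hits$protein_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$transcript_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

aggregate_hits <- function(hits, transcript_counts, key) {
  stopifnot(inherits(transcript_counts, "count_matrix"))
  if (!key %in% names(hits)) stop("hit table lacks a '", key, "' column")
  missing <- setdiff(hits$transcript_id, transcript_counts$taxa)
  if (length(missing))
    stop("annotated transcript(s) missing from counts: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- transcript_counts$counts[hits$transcript_id, , drop = FALSE]
  agg <- rowsum(sub, group = hits[[key]])
  count_matrix(agg, stats::setNames(transcript_counts$groups,
                                    transcript_counts$samples), "raw")
}

#' Genus abundance matrix from best hits
#'
#' Sums the read counts of all transcripts whose best hit is a protein of the
#' same genus, yielding a genus-by-sample metatranscript abundance matrix.
#'
#' @param hits best-hit table from [select_best_hits()] with a `genus` column.
#' @param transcript_counts transcript-by-sample [count_matrix()].
#' @return A raw genus-by-sample `count_matrix`.
#' @export
genus_abundance_matrix <- function(hits, transcript_counts) {
  aggregate_hits(hits, transcript_counts, "genus")
}

#' Metaprotein abundance matrix from best hits
#'
#' Sums read counts of all transcripts hitting the same protein id, merging
#' transcripts of that protein across genera (a metaprotein).
#'
#' @inheritParams genus_abundance_matrix
#' @return A raw protein-by-sample `count_matrix`.
#' @export
metaprotein_abundance_matrix <- function(hits, transcript_counts) {
  aggregate_hits(hits, transcript_counts, "protein_id")
}

#' Per-sample z-score enrichment filter with TMM normalization
#'
#' Within each sample, features are standardized on the `log1p` scale
#' (`z = (log1p(x) - mu_sample) / sigma_sample` over all features) and given
#' a one-sided upper-tail normal p-value. A feature is retained when
#' `p <= p_cutoff` in at least one sample; the retained features are then
#' TMM-normalized. Constant samples (zero sd) contribute p = 1 with a
#' warning.
#'
#' @param m raw aggregated [count_matrix()] (genus or metaprotein level).
#' @param p_cutoff retention p-value cutoff: 0.05 for genera, 0.01 for
#'   metaproteins.
#' @return list: `matrix` (TMM-normalized retained features), `retained`
#'   (feature ids), `p_values` (feature-by-sample matrix), `factors`
#'   (TMM factors, `NULL` when nothing is retained).
#' @export
zscore_filter <- function(m, p_cutoff = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  lx <- log1p(m$counts)
  p <- matrix(1, nrow(lx), ncol(lx), dimnames = dimnames(lx))
  for (s in seq_len(ncol(lx))) {
    sdev <- stats::sd(lx[, s])
    if (is.na(sdev) || sdev == 0) {
      warning("sample ", m$samples[s], " has constant counts; p-values set to 1")
      next
    }
    z <- (lx[, s] - mean(lx[, s])) / sdev
    p[, s] <- stats::pnorm(z, lower.tail = FALSE)
  }
  retained <- m$taxa[apply(p <= p_cutoff, 1, any)]
  if (!length(retained)) {
    warning("no features pass the z-score filter")
    return(list(matrix = NULL, retained = character(0), p_values = p,
                factors = NULL))
  }
  sub <- count_matrix(m$counts[retained, , drop = FALSE],
                      stats::setNames(m$groups, m$samples), "raw")
  tmm <- tmm_normalize(sub)
  list(matrix = tmm$matrix, retained = retained, p_values = p,
       factors = tmm$factors)
}

#' Read a trait-ontology table
#'
#' Expects a TSV with columns `path` (root-to-node path, levels separated by
#' `";"`) and optionally `branch` (`direct`, `indirect` or `other`). Node ids
#' are the full paths; the parent of a node is its path minus the last level.
#' Validates the single-root, acyclic reachability invariants.
#'
#' @param path TSV path.
#' @return data.frame: id, parent (`NA` for the root), label, branch, path.
#' @export
read_ontology <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"path" %in% names(tab)) stop("ontology needs a 'path' column")
  paths <- unique(tab$path)
  # close over ancestors so every prefix is a node
  all_paths <- unique(unlist(lapply(strsplit(paths, ";", fixed = TRUE),
                                    function(p) {
                                      vapply(seq_along(p), function(i)
                                        paste(p[seq_len(i)], collapse = ";"), "")
                                    })))
  parent <- vapply(all_paths, function(p) {
    parts <- strsplit(p, ";", fixed = TRUE)[[1]]
    if (length(parts) == 1) NA_character_
    else paste(parts[-length(parts)], collapse = ";")
  }, "")
  label <- vapply(strsplit(all_paths, ";", fixed = TRUE),
                  function(p) p[length(p)], "")
  roots <- all_paths[is.na(parent)]
  if (length(roots) != 1) stop("ontology must have a single root")
  branch <- rep("other", length(all_paths))
  if ("branch" %in% names(tab)) {
    b <- tab$branch[match(all_paths, tab$path)]
    branch[!is.na(b)] <- b
    # inherit branch from the second path level where unannotated
    second <- vapply(strsplit(all_paths, ";", fixed = TRUE), function(p)
      if (length(p) >= 2) paste(p[1:2], collapse = ";") else NA_character_, "")
    b2 <- tab$branch[match(second, tab$path)]
    branch[branch == "other" & !is.na(b2)] <- b2[branch == "other" & !is.na(b2)]
  }
  data.frame(id = all_paths, parent = parent, label = label,
             branch = branch, path = all_paths,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Roll transcript hits up a trait ontology
#'
#' Every mapped transcript increments its trait node and all of that node's
#' ancestors, so the root count equals the number of mapped transcripts.
#' Hits whose trait path does not resolve to an ontology node are counted
#' under an `unmapped` bucket.
#'
#' @param hits best-hit table with a `trait_path` column.
#' @param ontology data.frame from [read_ontology()].
#' @return list: `counts` (data.frame id, label, branch, count, log_size
#'   with `log_size = log10(1 + count)`), `branch_totals` (named vector of
#'   root-child branch totals), `n_mapped`, `n_unmapped`.
#' @export
pgpt_rollup <- function(hits, ontology) {
  counts <- stats::setNames(integer(nrow(ontology)), ontology$id)
  unmapped <- 0L
  tp <- hits$trait_path
  tp <- tp[!is.na(tp) & nzchar(tp)]
  resolved <- tp %in% ontology$id
  unmapped <- sum(!resolved)
  parent <- stats::setNames(ontology$parent, ontology$id)
  for (p in tp[resolved]) {
    node <- p
    while (!is.na(node)) {
      counts[node] <- counts[node] + 1L
      node <- parent[[node]]
    }
  }
  root <- ontology$id[is.na(ontology$parent)]
  kids <- ontology$id[!is.na(ontology$parent) & ontology$parent == root]
  branch_totals <- tapply(counts[kids], ontology$branch[match(kids, ontology$id)],
                          sum)
  list(counts = data.frame(id = ontology$id, label = ontology$label,
                           branch = ontology$branch,
                           count = as.integer(counts),
                           log_size = log10(1 + counts),
                           row.names = NULL),
       branch_totals = branch_totals,
       n_mapped = sum(resolved), n_unmapped = unmapped)
}
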