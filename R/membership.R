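#' Genotype-enriched taxa
#'
#' A taxon is genotype-enriched for a group when it is represented in every
#' replicate of that group by at least `min_count` reads (default 1, i.e.
#' present above background in all replicates).
#'
#' @param m a raw [count_matrix()].
#' @param group group label.
#' @param min_count minimum per-sample count (default 1).
#' @return character vector of taxon ids.
#' @export
genotype_enriched <- function(m, group, min_count = 1) {
  stopifnot(inherits(m, "count_matrix"))
  if (!group %in% m$groups) stop("unknown group: ", group)
  sub <- m$counts[, m$groups == group, drop = FALSE]
  m$taxa[rowSums(sub >= min_count) == ncol(sub)]
}

#' Ubiquitous taxa
#'
#' Taxa present (count `>= min_count`) in every sample of every group —
#' the intersection of all genotype-enriched sets.
#'
#' @inheritParams genotype_enriched
#' @return character vector of taxon ids.
#' @export
ubiquitous_set <- function(m, min_count = 1) {
  stopifnot(inherits(m, "count_matrix"))
  m$taxa[rowSums(m$counts >= min_count) == ncol(m$counts)]
}

#' Exact Venn partition of 2-4 sets
#'
#' Counts the members of every non-empty region signature (subset of set
#' labels); regions are disjoint and sum to the union size.
#'
#' @param sets named list of 2-4 character vectors.
#' @return list with `region_counts` (named by signatures like `"A&B"`) and
#'   `total_union`.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) stop("venn_partition supports 2 to 4 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  counts <- table(sig)
  list(region_counts = stats::setNames(as.integer(counts), names(counts)),
       total_union = length(universe))
}

#' Overlap percentage with half-up rounding to one decimal
#'
#' @param shared size of the intersection.
#' @param denominator_kind which denominator to use: `"union"`
#'   (`|A| + |B| - shared`), `"set_a"`, `"set_b"`, or `"total"` (an explicit
#'   universe size).
#' @param size_a,size_b,total the relevant set sizes.
#' @return percent, rounded half-up to 1 decimal.
#' @export
overlap_percent <- function(shared,
                            denominator_kind = c("union", "set_a", "set_b", "total"),
                            size_a = NULL, size_b = NULL, total = NULL) {
  denominator_kind <- match.arg(denominator_kind)
  den <- switch(denominator_kind,
                union = size_a + size_b - shared,
                set_a = size_a,
                set_b = size_b,
                total = total)
  if (is.null(den) || !length(den)) stop("required size missing")
  if (den == 0) stop("zero denominator")
  if (shared > den) stop("shared exceeds denominator")
  # round half-up (round() rounds half to even)
  floor(1000 * shared / den + 0.5) / 10
}

#' Core microbiome by prevalence at a detection threshold
#'
#' Prevalence of taxon t at detection threshold tau is the fraction of all
#' samples with abundance strictly greater than tau. The core set holds taxa
#' whose prevalence at the chosen detection limit strictly exceeds the
#' prevalence cutoff. A prevalence grid over a range of detection thresholds
#' is returned for heatmap-style inspection.
#'
#' @param m a CPM-normalized [count_matrix()].
#' @param detection_grid ascending detection thresholds (default 10 steps,
#'   100 to 1000).
#' @param prevalence_cutoff prevalence cutoff in (0, 1) (default 0.4).
#' @param detection detection limit used for the core set (default 500).
#' @return list with `grid` (taxa x thresholds prevalence matrix) and
#'   `core` (character vector of core taxon ids).
#' @export
core_microbiome <- function(m, detection_grid = seq(100, 1000, length.out = 10),
                            prevalence_cutoff = 0.4, detection = 500) {
  stopifnot(inherits(m, "count_matrix"))
  if (prevalence_cutoff <= 0 || prevalence_cutoff >= 1)
    stop("prevalence_cutoff must lie in (0, 1)")
  if (is.unsorted(detection_grid, strictly = TRUE))
    stop("detection_grid must be ascending")
  n <- ncol(m$counts)
  grid <- vapply(detection_grid,
                 function(tau) rowSums(m$counts > tau) / n,
                 numeric(nrow(m$counts)))
  dimnames(grid) <- list(m$taxa, as.character(detection_grid))
  prev <- rowSums(m$counts > detection) / n
  list(grid = grid, core = m$taxa[prev > prevalence_cutoff])
}

#' Functional core microbiome from metatranscript counts
#'
#' Genera whose metatranscript count strictly exceeds the detection limit in
#' a fraction of samples strictly greater than the prevalence cutoff.
#'
#' @param m genus-by-sample metatranscript [count_matrix()].
#' @param prevalence_cutoff prevalence cutoff (default 0.4).
#' @param detection detection limit in metatranscript counts (default 50).
#' @return character vector of genus ids.
#' @export
functional_core <- function(m, prevalence_cutoff = 0.4, detection = 50) {
  stopifnot(inherits(m, "count_matrix"))
  prev <- rowSums(m$counts > detection) / ncol(m$counts)
  m$taxa[prev > prevalence_cutoff]
}
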