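#' Kruskal-Wallis screen across taxa
#'
#' Per-taxon Kruskal-Wallis rank test (tie-corrected H, chi-square p with
#' `a - 1` degrees of freedom) across groups. Taxa constant over all samples
#' get `p = 1` by convention.
#'
#' @param m a [count_matrix()] of relative abundances (or any monotone
#'   transform; the test is rank-based).
#' @param groups optional group labels overriding `m$groups` (e.g. a subset).
#' @return named numeric vector of p-values, one per taxon.
#' @export
kruskal_wallis_screen <- function(m, groups = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(groups)) groups <- m$groups
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups")
  apply_p <- function(x) {
    if (length(unique(x)) == 1) return(1)
    stats::kruskal.test(x, g)$p.value
  }
  stats::setNames(apply(m$counts, 1, apply_p), m$taxa)
}

# Unit-norm linear-discriminant projection of the between-class mean
# difference for a single feature. MASS::lda normalizes its scaling by the
# within-class sd; renormalizing the coefficient to unit norm returns the
# projection to abundance units. Degenerate (zero within-class variance)
# fits fall back to the raw mean difference.
lda_projected_diff <- function(x, g) {
  m1 <- mean(x[g == levels(g)[1]])
  m2 <- mean(x[g == levels(g)[2]])
  raw <- abs(m1 - m2)
  w <- tryCatch({
    fit <- MASS::lda(matrix(x, ncol = 1), g)
    as.numeric(fit$scaling)
  }, error = function(e) NA_real_)
  proj <- if (is.na(w) || w == 0) raw else abs((w / abs(w)) * (m1 - m2))
  mean(c(proj, raw))
}

#' LDA effect size for one taxon (two groups)
#'
#' Seeded, bootstrap-averaged linear-discriminant effect size in the style of
#' the LEfSe procedure: over `n_boot` stratified resamples (at least half of
#' each class, classes never below 2 samples), the per-resample score is the
#' average of the unit-norm discriminant-projected and raw class-mean
#' differences of the taxon's abundance scaled to per-million; the effect
#' size is `log10(1 + mean score)`.
#'
#' @param m a [count_matrix()]; abundances are rescaled per-million per sample
#'   unless already CPM/TMM normalized.
#' @param taxon taxon id (should already have passed the KW screen).
#' @param pair character vector of the two group labels to compare.
#' @param n_boot number of bootstrap resamples (default 30).
#' @param seed integer seed.
#' @param threshold log10 effect-size threshold for `passes` (default 2).
#' @param kw_p optional pre-computed Kruskal-Wallis p-value for the record.
#' @param alpha KW significance level used for `passes` (default 0.05).
#' @return list: `taxon`, `enriched_group`, `kw_p`, `lda_log10`, `passes`.
#' @export
lda_effect_size <- function(m, taxon, pair, n_boot = 30, seed = 1,
                            threshold = 2, kw_p = NA_real_, alpha = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  if (!taxon %in% m$taxa) stop("unknown taxon: ", taxon)
  keep <- m$groups %in% pair
  if (sum(keep) < 4) stop("need >= 2 samples per group")
  counts <- m$counts[, keep, drop = FALSE]
  if (m$normalized == "raw")
    counts <- sweep(counts, 2, colSums(counts), "/") * 1e6
  x <- counts[taxon, ]
  g <- factor(m$groups[keep], levels = pair)
  if (any(table(g) < 2)) stop("need >= 2 samples per group")
  set.seed(seed)
  scores <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- NULL
    for (attempt in seq_len(100)) {
      cand <- unlist(lapply(pair, function(gr) {
        i <- which(g == gr)
        sample(i, max(2, ceiling(length(i) / 2)), replace = TRUE)
      }))
      if (all(table(g[cand])[pair] >= 2)) { idx <- cand; break }
    }
    if (is.null(idx)) stop("could not draw a stratified resample")
    scores[b] <- lda_projected_diff(x[idx], droplevels(g[idx]))
  }
  eff <- log10(1 + mean(scores))
  means <- tapply(x, g, mean)
  list(taxon = taxon,
       enriched_group = pair[which.max(means)],
       kw_p = kw_p,
       lda_log10 = eff,
       passes = isTRUE(eff >= threshold) && isTRUE(kw_p < alpha))
}

#' LEfSe-style discriminative-taxon screen for one group pair
#'
#' Kruskal-Wallis screen at `alpha`, then LDA effect size for the passing
#' taxa; a taxon is reported discriminative when both `kw_p < alpha` and
#' `lda_log10 >= threshold`. Groups with fewer than `min_replicates`
#' samples are rejected (mirroring the exclusion of a 2-replicate group
#' from pairwise comparisons).
#'
#' @inheritParams lda_effect_size
#' @param alpha KW screen level (default 0.05).
#' @param min_replicates minimum samples per compared group (default 3).
#' @return data.frame: taxon, enriched_group, kw_p, lda_log10, passes.
#' @export
lefse_pair <- function(m, pair, alpha = 0.05, threshold = 2, n_boot = 30,
                       seed = 1, min_replicates = 3) {
  stopifnot(inherits(m, "count_matrix"))
  tab <- table(m$groups)
  if (any(tab[pair] < min_replicates))
    stop("group(s) below min_replicates: ",
         paste(pair[tab[pair] < min_replicates], collapse = ", "))
  keep <- m$groups %in% pair
  sub <- count_matrix(m$counts[, keep, drop = FALSE],
                      stats::setNames(m$groups[keep], m$samples[keep]),
                      m$normalized)
  kw <- kruskal_wallis_screen(sub)
  cand <- names(kw)[kw < alpha]
  rows <- lapply(seq_along(cand), function(i) {
    lda_effect_size(sub, cand[i], pair, n_boot = n_boot, seed = seed + i,
                    threshold = threshold, kw_p = kw[[cand[i]]], alpha = alpha)
  })
  if (!length(rows))
    return(data.frame(taxon = character(0), enriched_group = character(0),
                      kw_p = numeric(0), lda_log10 = numeric(0),
                      passes = logical(0)))
  data.frame(taxon = vapply(rows, `[[`, "", "taxon"),
             enriched_group = vapply(rows, `[[`, "", "enriched_group"),
             kw_p = vapply(rows, `[[`, 0, "kw_p"),
             lda_log10 = vapply(rows, `[[`, 0, "lda_log10"),
             passes = vapply(rows, `[[`, TRUE, "passes"),
             row.names = NULL)
}
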