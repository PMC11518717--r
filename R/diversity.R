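#' Chao1 richness estimator
#'
#' Estimates total richness from observed richness plus the singleton/doubleton
#' ratio. The bias-corrected form `S_obs + f1(f1-1)/(2(f2+1))` is the default;
#' the classic form `S_obs + f1^2/(2 f2)` is undefined at `f2 = 0` and falls
#' back to the bias-corrected form there.
#'
#' @param counts non-negative integer vector of raw read counts for one sample.
#' @param bias_corrected use the bias-corrected estimator (default `TRUE`).
#' @return Estimated richness, always `>=` observed richness.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts != round(counts)) || any(counts < 0))
    stop("chao1 needs non-negative integer counts")
  if (!any(counts > 0)) stop("sample has no positive counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum p_i ln p_i` over taxa with positive counts.
#'
#' @param counts non-negative abundance vector.
#' @return H in nats, `>= 0`.
#' @export
shannon <- function(counts) {
  if (!any(counts > 0)) stop("sample has no positive counts")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Pielou's evenness
#'
#' `J = H / ln(S_obs)`; undefined (NA with a warning) for a single-taxon
#' sample.
#'
#' @param counts non-negative abundance vector.
#' @return J in `[0, 1]`, or `NA` when only one taxon is present.
#' @export
pielou <- function(counts) {
  s_obs <- sum(counts > 0)
  if (s_obs < 1) stop("sample has no positive counts")
  if (s_obs == 1) {
    warning("Pielou evenness undefined for a single-taxon sample")
    return(NA_real_)
  }
  shannon(counts) / log(s_obs)
}

#' Per-sample alpha diversity table
#'
#' @param m a raw [count_matrix()] (Chao1 needs integer singleton/doubleton
#'   counts).
#' @return data.frame with columns sample, group, chao1, shannon, pielou.
#' @export
alpha_diversity <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalized != "raw")
    stop("alpha diversity is computed on raw integer counts")
  data.frame(sample = m$samples, group = m$groups,
             chao1 = apply(m$counts, 2, chao1),
             shannon = apply(m$counts, 2, shannon),
             pielou = suppressWarnings(apply(m$counts, 2, pielou)),
             row.names = NULL)
}

#' Pairwise Wilcoxon rank-sum tests on an alpha diversity metric
#'
#' Two-sided rank-sum test for every group pair; exact null distribution when
#' both groups have `n <= 10` and no ties, normal approximation with tie
#' correction otherwise (the default switching of [stats::wilcox.test()]).
#' No multiplicity adjustment is applied.
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param metric one of `"chao1"`, `"shannon"`, `"pielou"`.
#' @return data.frame with columns group1, group2, p_value (`NA` for pairs
#'   where a group has fewer than 2 samples).
#' @export
pairwise_wilcoxon <- function(alpha, metric = c("chao1", "shannon", "pielou")) {
  metric <- match.arg(metric)
  gs <- unique(alpha$group)
  if (length(gs) < 2) stop("need at least two groups")
  pairs <- utils::combn(gs, 2)
  p <- apply(pairs, 2, function(pr) {
    x <- alpha[alpha$group == pr[1], metric]
    y <- alpha[alpha$group == pr[2], metric]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (length(unique(c(x, y))) == 1) return(1)  # fully tied groups
    suppressWarnings(stats::wilcox.test(x, y, exact = NULL)$p.value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_value = p)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_xy = sum |x_t - y_t| / sum (x_t + y_t)` over taxa; 0 for identical
#' samples, 1 for disjoint supports.
#'
#' @param m a [count_matrix()] (raw or normalized), all columns positive-sum.
#' @return symmetric matrix of class `dist_matrix` with zero diagonal and
#'   entries in `[0, 1]`, sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  cs <- colSums(m$counts)
  if (any(cs == 0))
    stop("zero-sum sample(s): ", paste(m$samples[cs == 0], collapse = ", "))
  n <- ncol(m$counts)
  d <- matrix(0, n, n, dimnames = list(m$samples, m$samples))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- m$counts[, i]; y <- m$counts[, j]
    d[i, j] <- d[j, i] <- sum(abs(x - y)) / sum(x + y)
  }
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering `B = -1/2 J D^2 J`,
#' eigendecomposition, coordinates `v_k sqrt(lambda_k)` for positive
#' eigenvalues. Negative eigenvalues are reported but their axes dropped.
#' Axis signs are fixed so the largest-magnitude loading on each axis is
#' positive.
#'
#' @param d symmetric distance matrix (a `dist_matrix` or plain matrix).
#' @return list of class `pcoa_ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 0) * 1e-12 & ev > 0)
  coords <- if (length(pos)) {
    v <- e$vectors[, pos, drop = FALSE]
    for (k in seq_len(ncol(v))) {
      if (v[which.max(abs(v[, k])), k] < 0) v[, k] <- -v[, k]
    }
    sweep(v, 2, sqrt(ev[pos]), "*")
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = if (length(pos))
                   ev[pos] / sum(ev[pos]) else numeric(0),
                 negative_eigenvectors = e$vectors[, ev < 0, drop = FALSE],
                 negative_eigenvalues = ev[ev < 0]),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$proportion_explained))
    cat("proportion explained:",
        paste(sprintf("%.3f", utils::head(x$proportion_explained, 4)),
              collapse = " "), "\n")
  invisible(x)
}

perm_result <- function(statistic, p_value, n_permutations, seed, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, seed = seed, method = method),
            class = "permtest")
}

#' @export
print.permtest <- function(x, ...) {
  cat(sprintf("%s: pseudo-F = %.4g, p = %.4g (%d permutations, seed %d)\n",
              x$method, x$statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  list(f = (ss_a / (a - 1)) / (ss_w / (n - a)),
       ss_t = ss_t, ss_w = ss_w, ss_a = ss_a)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F statistic by permuting
#' group labels. The p-value uses the "+1" convention (the observed
#' statistic counts as one permutation), so its floor is
#' `1/(n_permutations + 1)`.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (matrix order).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return A `permtest` object; `$statistic` is the pseudo-F, with the sum of
#'   squares decomposition in `$ss`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each")
  if (n_permutations < 99) stop("use at least 99 permutations")
  d2 <- d^2
  obs <- permanova_f(d2, groups)
  if (obs$ss_w == 0) {
    warning("within-group sum of squares is zero; F is infinite")
    out <- perm_result(Inf, 1 / (n_permutations + 1), n_permutations, seed,
                       "PERMANOVA")
    out$ss <- obs
    return(out)
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    fp <- permanova_f(d2, sample(groups))$f
    if (fp >= obs$f) exceed <- exceed + 1L
  }
  out <- perm_result(obs$f, (1 + exceed) / (1 + n_permutations),
                     n_permutations, seed, "PERMANOVA")
  out$ss <- obs
  out
}

# Squared distances of each sample to a group centroid in the PCoA embedding,
# with Anderson's correction: real-axis contribution minus imaginary-axis
# contribution, floored at 0.
dist_to_centroids <- function(ord, groups) {
  X <- ord$coordinates
  Yn <- ord$negative_eigenvectors
  if (ncol(Yn)) Yn <- sweep(Yn, 2, sqrt(abs(ord$negative_eigenvalues)), "*")
  z <- numeric(nrow(X))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cr <- colMeans(X[idx, , drop = FALSE])
    d2r <- rowSums((X[idx, , drop = FALSE] -
                      matrix(cr, length(idx), ncol(X), byrow = TRUE))^2)
    d2i <- 0
    if (ncol(Yn)) {
      ci <- colMeans(Yn[idx, , drop = FALSE])
      d2i <- rowSums((Yn[idx, , drop = FALSE] -
                        matrix(ci, length(idx), ncol(Yn), byrow = TRUE))^2)
    }
    z[idx] <- sqrt(pmax(0, d2r - d2i))
  }
  z
}

anova_f <- function(z, groups) {
  n <- length(z); a <- length(unique(groups))
  gm <- stats::ave(z, groups)
  ss_w <- sum((z - gm)^2)
  ss_a <- sum((gm - mean(z))^2)
  if (ss_w == 0) return(Inf)
  (ss_a / (a - 1)) / (ss_w / (n - a))
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix by PCoA (negative-eigenvalue axes enter as an
#' imaginary-part correction), computes every sample's distance to its own
#' group centroid, and tests the one-way ANOVA F on those distances by
#' permuting least-squares residuals.
#'
#' @inheritParams permanova
#' @return A `permtest` object; `$distances` holds the per-sample centroid
#'   distances.
#' @export
permdisp <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each")
  if (n_permutations < 99) stop("use at least 99 permutations")
  ord <- pcoa(d)
  z <- dist_to_centroids(ord, groups)
  f_obs <- anova_f(z, groups)
  # least-squares residuals under the null (intercept-only) model
  resid <- z - mean(z)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    zp <- mean(z) + sample(resid)
    if (anova_f(zp, groups) >= f_obs) exceed <- exceed + 1L
  }
  out <- perm_result(f_obs, (1 + exceed) / (1 + n_permutations),
                     n_permutations, seed, "PERMDISP")
  out$distances <- stats::setNames(z, rownames(d))
  out
}
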