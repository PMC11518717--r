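test_that("alpha diversity estimators match hand-derived values", {
  # chao1: S_obs = 5, f1 = 2, f2 = 1 -> 5 + 2*1/(2*2) = 5.5
  expect_equal(chao1(c(10, 4, 1, 1, 2)), 5.5, tolerance = 1e-6)
  # no singletons: estimator collapses to observed richness
  expect_equal(chao1(c(5, 3, 2)), 3)
  # two singletons, no doubletons: bias-corrected fallback 2 + 2*1/2 = 3
  expect_equal(chao1(c(1, 1)), 3)
  expect_equal(chao1(c(1, 1), bias_corrected = FALSE), 3)
  expect_error(chao1(c(1.5, 2)), "integer")

  expect_equal(shannon(c(1, 1, 1, 1)), log(4), tolerance = 1e-6)
  expect_equal(shannon(c(7)), 0)
  expect_equal(shannon(c(2, 1, 1)), 1.039721, tolerance = 1e-6)
  expect_error(shannon(c(0, 0)), "no positive")

  expect_equal(pielou(c(3, 3, 3)), 1, tolerance = 1e-12)
  expect_equal(pielou(c(2, 1, 1)), 0.946395, tolerance = 1e-6)
  expect_warning(j <- pielou(c(5, 0)), "single-taxon")
  expect_true(is.na(j))

  # chao1 >= observed richness, always
  set.seed(8)
  for (i in 1:30) {
    v <- rpois(40, 2)
    if (!any(v > 0)) next
    expect_gte(chao1(v), sum(v > 0))
  }
})

test_that("pairwise Wilcoxon uses the exact two-sided rank-sum null", {
  alpha <- data.frame(group = rep(c("A", "B"), each = 3),
                      chao1 = c(1, 2, 3, 4, 5, 6))
  out <- pairwise_wilcoxon(alpha, "chao1")
  expect_equal(out$p_value, 0.1)  # 2/choose(6,3)

  tied <- data.frame(group = rep(c("A", "B"), each = 2), chao1 = rep(5, 4))
  expect_equal(pairwise_wilcoxon(tied, "chao1")$p_value, 1)

  # 5-sigma separation at n = 10 per group
  set.seed(9)
  sep <- data.frame(group = rep(c("A", "B"), each = 10),
                    chao1 = c(rnorm(10), rnorm(10, 5)))
  expect_lt(pairwise_wilcoxon(sep, "chao1")$p_value, 0.01)

  # a singleton group is untestable, not an error
  tiny <- data.frame(group = c("A", "A", "B"), chao1 = c(1, 2, 3))
  expect_true(is.na(pairwise_wilcoxon(tiny, "chao1")$p_value))
})

test_that("Bray-Curtis distances match the definition and vegan", {
  x <- matrix(c(1, 2, 0, 0, 2, 4), 3, 2,
              dimnames = list(paste0("t", 1:3), c("a", "b")))
  m <- count_matrix(x, c(a = "g", b = "g"))
  expect_equal(bray_curtis_matrix(m)["a", "b"], 5 / 9, tolerance = 1e-12)

  same <- count_matrix(cbind(a = c(1, 2), b = c(1, 2)) |>
                         `rownames<-`(c("t1", "t2")), c(a = "g", b = "g"))
  expect_equal(bray_curtis_matrix(same)["a", "b"], 0)

  disj <- count_matrix(cbind(a = c(3, 0), b = c(0, 7)) |>
                         `rownames<-`(c("t1", "t2")), c(a = "g", b = "g"))
  expect_equal(bray_curtis_matrix(disj)["a", "b"], 1)

  # metric properties + agreement with vegan on random matrices
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:5) {
    m <- random_count_matrix(20, c(A = 4, B = 4))
    d <- bray_curtis_matrix(m)
    expect_equal(unname(diag(d)), rep(0, 8))
    expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
    expect_true(all(d >= 0 & d <= 1))
    dv <- as.matrix(vegan::vegdist(t(m$counts)))
    expect_equal(unclass(d), dv, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("PCoA embeds Euclidean-compatible distances exactly", {
  # three collinear points: d(1,2)=1, d(2,3)=1, d(1,3)=2
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  o <- pcoa(d)
  expect_equal(sum(o$eigenvalues > 1e-8), 1)
  rec <- as.matrix(dist(o$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)

  # degenerate all-zero distances
  z <- matrix(0, 3, 3, dimnames = dimnames(d))
  oz <- pcoa(z)
  expect_true(all(abs(oz$eigenvalues) < 1e-12))
  expect_equal(ncol(oz$coordinates), 0)

  # random planar configurations are reproduced by the first two axes
  set.seed(12)
  for (i in 1:5) {
    pts <- matrix(rnorm(12), 6, 2)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
    o <- pcoa(D)
    expect_lte(ncol(o$coordinates), 2)
    expect_lt(max(abs(as.matrix(dist(o$coordinates)) - D)), 1e-8)
  }

  # eigenvalues agree with classical MDS
  m <- random_count_matrix(15, c(A = 4, B = 4))
  d <- bray_curtis_matrix(m)
  cmd <- stats::cmdscale(as.dist(d), k = 4, eig = TRUE)
  o <- pcoa(d)
  expect_equal(o$eigenvalues[1:4], cmd$eig[1:4], tolerance = 1e-10)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA partitions sums of squares and matches vegan's pseudo-F", {
  # hand-worked 4-sample example: within d = 1, between d = 2
  d <- matrix(2, 4, 4)
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  r <- permanova(d, c("a", "a", "b", "b"), 99, 1)
  expect_equal(r$statistic, 7)
  expect_equal(r$ss$ss_t, 4.5)
  expect_equal(r$ss$ss_w, 1)
  expect_equal(r$ss$ss_a, 3.5)

  # exchangeable groups: no evidence of separation
  set.seed(13)
  m <- random_count_matrix(15, c(A = 5, B = 5))
  dd <- bray_curtis_matrix(m)
  expect_gt(permanova(dd, m$groups, 199, 5)$p_value, 0.05)

  # p-value floor under the "+1" convention
  expect_gte(permanova(dd, m$groups, 99, 1)$p_value, 1 / 100)

  skip_if_not_installed("vegan")
  g <- factor(m$groups)
  a2 <- vegan::adonis2(stats::as.dist(dd) ~ g, permutations = 50)
  expect_equal(permanova(dd, m$groups, 99, 1)$statistic, a2$F[1],
               tolerance = 1e-10)
})

test_that("PERMDISP measures dispersion, not location", {
  # one group coincident, the other dispersed: extreme F, minimal p
  pts <- rbind(matrix(0, 4, 2), matrix(rnorm(8, sd = 3), 4, 2))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:8), paste0("s", 1:8))
  g <- rep(c("tight", "loose"), each = 4)
  r <- permdisp(D, g, 199, 3)
  expect_gt(r$statistic, 5)
  expect_equal(r$p_value, 1 / 200)

  # mirror-image groups have identical dispersion: no signal
  set.seed(14)
  a <- matrix(rnorm(10), 5, 2)
  pts <- rbind(a, -a)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  r <- permdisp(D, rep(c("p", "q"), each = 5), 199, 4)
  expect_lt(r$statistic, 1e-10)
  expect_gt(r$p_value, 0.5)

  # statistic agrees with vegan::betadisper on Bray-Curtis input
  skip_if_not_installed("vegan")
  m <- random_count_matrix(15, c(A = 5, B = 5))
  dd <- bray_curtis_matrix(m)
  bd <- vegan::betadisper(stats::as.dist(dd), factor(m$groups),
                          type = "centroid")
  expect_equal(permdisp(dd, m$groups, 99, 1)$statistic,
               stats::anova(bd)$`F value`[1], tolerance = 1e-8)
})
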