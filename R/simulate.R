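#' Configuration for the synthetic community generator
#'
#' Defines the statistical structure of a simulated genus-by-sample count
#' matrix: group design (replicates per genotype), correlated abundance blocks
#' with optional multi-block hub taxa, planted core and genotype-enriched
#' taxa, lognormal sequencing-depth variation, and negative-binomial
#' overdispersion.
#'
#' @param n_taxa number of taxa.
#' @param group_design named integer vector, replicates per group. The default
#'   mirrors a 4/3/3/2 genotype design (Spu/Sps/F1/F2).
#' @param n_blocks number of correlated abundance blocks.
#' @param block_correlation latent correlation within a block, in `[0, 1]`.
#' @param core_fraction fraction of taxa planted as high-abundance core taxa.
#' @param enriched_fraction fraction of taxa planted as genotype-enriched
#'   (present in every replicate of one group, absent elsewhere).
#' @param effect_size log-scale abundance boost for enriched taxa in their
#'   group (natural-log units).
#' @param depth_lognormal_sigma sd of the lognormal per-sample depth factor.
#' @param dispersion negative-binomial size parameter; `Inf` switches to
#'   noise-free rounded expected counts.
#' @param n_hubs number of hub taxa loading on two blocks each.
#' @param core_log_boost baseline log-abundance boost of core taxa over
#'   background taxa (natural-log units); the default 4 makes the planted
#'   core dominate the composition, as the most prevalent genera do in real
#'   pitcher communities.
#' @param library_size expected reads per sample before depth variation.
#' @param latent_sigma sd of the latent log-abundance variation per taxon.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 60,
                       group_design = c(Spu = 4, Sps = 3, F1 = 3, F2 = 2),
                       n_blocks = 3,
                       block_correlation = 0.9,
                       core_fraction = 0.25,
                       enriched_fraction = 0.2,
                       effect_size = 2,
                       depth_lognormal_sigma = 0.3,
                       dispersion = 10,
                       n_hubs = 2,
                       core_log_boost = 4,
                       library_size = 1e5,
                       latent_sigma = 1,
                       seed = 1) {
  if (core_fraction + enriched_fraction > 1)
    stop("core_fraction + enriched_fraction must not exceed 1")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (block_correlation < 0 || block_correlation > 1)
    stop("block_correlation must lie in [0, 1]")
  if (any(group_design < 2)) stop("every group needs at least 2 replicates")
  if (sum(group_design == 2) > 1)
    stop("at most one group may have only 2 replicates")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genus-by-sample count matrix with planted ground truth
#'
#' Latent log-abundance of taxon t in sample s is
#' `baseline_t + sqrt(rho) * sigma * Z_{block(t),s} + sqrt(1-rho) * sigma * E_{ts}`,
#' with a shared Gaussian factor `Z` per block so that same-block taxa have
#' latent correlation `rho`. Hub taxa instead load equally on two block
#' factors. Enriched taxa get `effect_size` added to the latent scale inside
#' their group and are forced to zero occupancy outside it; core taxa get a
#' high baseline so they exceed typical detection thresholds in most samples.
#' Counts are drawn negative-binomially around
#' `depth_s * library_size * softmax(latent)`.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (raw [count_matrix()]) and `truth` (list:
#'   `core_taxa`, `enriched_taxa` per group, `community_blocks`, `hub_taxa`,
#'   `depth_factors`, `group_design`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  groups <- rep(names(cfg$group_design), cfg$group_design)
  samples <- paste0(groups, ".", unlist(lapply(cfg$group_design, seq_len)))
  n_s <- length(samples)
  n_t <- cfg$n_taxa
  taxa <- sprintf("g%03d", seq_len(n_t))

  n_core <- round(cfg$core_fraction * n_t)
  n_enr <- round(cfg$enriched_fraction * n_t)
  core_taxa <- taxa[seq_len(n_core)]
  enr_idx <- n_core + seq_len(n_enr)
  enr_group <- rep(names(cfg$group_design), length.out = n_enr)
  enriched_taxa <- split(taxa[enr_idx], enr_group)
  enriched_of <- stats::setNames(rep(NA_character_, n_t), taxa)
  enriched_of[enr_idx] <- enr_group

  blocks <- stats::setNames(rep(seq_len(cfg$n_blocks), length.out = n_t), taxa)
  hub_taxa <- character(0)
  hub_pair <- list()
  if (cfg$n_hubs > 0 && cfg$n_blocks >= 2) {
    # hubs are background taxa (not core, not enriched) loading on two blocks
    bg <- setdiff(seq_len(n_t), c(seq_len(n_core), enr_idx))
    hub_i <- bg[seq_len(min(cfg$n_hubs, length(bg)))]
    hub_taxa <- taxa[hub_i]
    for (k in seq_along(hub_i)) {
      b1 <- 1 + (k - 1) %% cfg$n_blocks
      b2 <- 1 + k %% cfg$n_blocks
      hub_pair[[taxa[hub_i[k]]]] <- c(b1, b2)
    }
  }

  # baselines: core taxa high so they dominate the composition
  baseline <- stats::rnorm(n_t, 0, 0.25)
  baseline[seq_len(n_core)] <- baseline[seq_len(n_core)] + cfg$core_log_boost

  rho <- cfg$block_correlation
  # core taxa fluctuate less than background (a stable dominant core, as in
  # real pitcher communities); correlation structure is scale-free so their
  # block correlation is unaffected, but the damped variance keeps total
  # community mass — and hence compositional closure — stable
  sig_t <- rep(cfg$latent_sigma, n_t)
  sig_t[seq_len(n_core)] <- 0.3 * cfg$latent_sigma
  sig <- cfg$latent_sigma
  # block factors are orthogonalized across blocks within each dataset so
  # planted communities are uncorrelated by construction (the finite-sample
  # correlation of raw Gaussian factor vectors would otherwise couple whole
  # block pairs in a seed-dependent way)
  Z <- matrix(stats::rnorm(cfg$n_blocks * n_s), cfg$n_blocks, n_s)
  if (cfg$n_blocks > 1 && cfg$n_blocks <= n_s) {
    Q <- qr.Q(qr(t(Z)))
    Z <- t(Q) * sqrt(n_s)
  }
  E <- matrix(stats::rnorm(n_t * n_s), n_t, n_s)
  latent <- matrix(baseline, n_t, n_s) +
    sqrt(rho) * sig_t * Z[blocks, , drop = FALSE] +
    sqrt(1 - rho) * sig_t * E
  # hubs load on two block factors as a contrast (+Z_b1 - Z_b2): under
  # compositional closure the common normalization term cancels, so a hub
  # correlates strongly positively with one community and negatively with
  # the other and its edges span both — participation is high by
  # construction (negative edges are first-class in the network stage)
  for (h in names(hub_pair)) {
    i <- match(h, taxa)
    b <- hub_pair[[h]]
    latent[i, ] <- baseline[i] + sqrt(1 / 2) * sig * (Z[b[1], ] - Z[b[2], ])
  }
  for (i in enr_idx) {
    g <- enriched_of[i]
    latent[i, groups == g] <- latent[i, groups == g] + cfg$effect_size
  }

  depth <- exp(stats::rnorm(n_s, 0, cfg$depth_lognormal_sigma))
  prob <- apply(latent, 2, function(v) { e <- exp(v - max(v)); e / sum(e) })
  mu <- sweep(prob, 2, depth * cfg$library_size, "*")
  # planted absences: enriched taxa have zero occupancy outside their group
  for (i in enr_idx) mu[i, groups != enriched_of[i]] <- 0

  if (is.finite(cfg$dispersion)) {
    counts <- matrix(stats::rnbinom(n_t * n_s, mu = as.vector(mu),
                                    size = cfg$dispersion), n_t, n_s)
  } else {
    counts <- round(mu)
  }
  dimnames(counts) <- list(taxa, samples)

  truth <- list(core_taxa = core_taxa,
                enriched_taxa = enriched_taxa,
                community_blocks = blocks,
                hub_taxa = hub_taxa,
                depth_factors = stats::setNames(depth, samples),
                group_design = cfg$group_design)
  list(matrix = count_matrix(counts, stats::setNames(groups, samples), "raw"),
       truth = truth)
}

#' Simulate a protein-alignment hit table and transcript count matrix
#'
#' Emulates the output of best-hit blastx annotation of an assembled
#' metatranscriptome: each transcript either carries no passing hit (with
#' probability `fraction_no_hit`) or is assigned a (protein, genus, lineage,
#' trait path) annotation with an e-value and bitscore. Proteins are shared
#' across genera so metaprotein aggregation merges transcripts from multiple
#' genera. Per-transcript read counts follow the same lognormal-depth,
#' negative-binomial model as [simulate_counts()].
#'
#' @param cfg a [sim_config()]; `n_taxa` is reused as the number of genera.
#' @param ontology an ontology `data.frame` as returned by [read_ontology()];
#'   trait paths are sampled uniformly from its leaves.
#' @param n_transcripts number of transcripts to simulate.
#' @param fraction_no_hit fraction of transcripts without a passing hit.
#' @param n_proteins size of the protein pool (smaller than `n_transcripts`
#'   so proteins recur across transcripts and genera).
#' @return list with `hits` (data.frame: transcript_id, protein_id, genus,
#'   lineage, e_value, bitscore, trait_path), `counts` (transcript-by-sample
#'   [count_matrix()] over all transcripts) and `truth` (list with the
#'   annotated/unannotated split).
#' @export
simulate_hit_table <- function(cfg, ontology, n_transcripts = 2000,
                               fraction_no_hit = 0.506, n_proteins = 200) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(ontology) || !nrow(ontology)) stop("ontology must be non-empty")
  set.seed(cfg$seed + 1L)
  groups <- rep(names(cfg$group_design), cfg$group_design)
  samples <- paste0(groups, ".", unlist(lapply(cfg$group_design, seq_len)))
  tx <- sprintf("tx%05d", seq_len(n_transcripts))

  annotated <- stats::runif(n_transcripts) >= fraction_no_hit
  n_hit <- sum(annotated)
  genera <- sprintf("g%03d", seq_len(cfg$n_taxa))
  leaf <- ontology$id[!ontology$id %in% ontology$parent]
  hit_genus <- sample(genera, n_hit, replace = TRUE)
  hits <- data.frame(
    transcript_id = tx[annotated],
    protein_id = sprintf("P%04d", sample.int(n_proteins, n_hit, replace = TRUE)),
    genus = hit_genus,
    lineage = paste0("Bacteria;", hit_genus),
    e_value = 10^stats::runif(n_hit, -30, log10(0.05)),
    bitscore = round(stats::runif(n_hit, 60, 400), 1),
    trait_path = ontology$path[match(sample(leaf, n_hit, replace = TRUE),
                                     ontology$id)],
    stringsAsFactors = FALSE)

  depth <- exp(stats::rnorm(length(samples), 0, cfg$depth_lognormal_sigma))
  base <- exp(stats::rnorm(n_transcripts, 0, cfg$latent_sigma))
  mu <- outer(base / sum(base), depth * cfg$library_size)
  if (is.finite(cfg$dispersion)) {
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = cfg$dispersion),
                     n_transcripts, length(samples))
  } else {
    counts <- round(mu)
  }
  dimnames(counts) <- list(tx, samples)
  list(hits = hits,
       counts = count_matrix(counts, stats::setNames(groups, samples), "raw"),
       truth = list(n_transcripts = n_transcripts, n_annotated = n_hit,
                    fraction_no_hit = fraction_no_hit))
}
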