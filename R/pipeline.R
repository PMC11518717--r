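#' Default pipeline configuration
#'
#' Returns the demo configuration the end-to-end pipeline runs on: a
#' synthetic community under the 4/3/3/2 genotype design with planted core,
#' enriched, block and hub structure, followed by every analysis stage.
#'
#' @param seed master seed; each stochastic stage derives its own substream
#'   from it.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 7) {
  list(seed = seed,
       simulate = list(n_taxa = 60, n_blocks = 3, block_correlation = 0.9,
                       core_fraction = 0.25, enriched_fraction = 0.2,
                       effect_size = 2, depth_lognormal_sigma = 0.3,
                       dispersion = 10, n_hubs = 2, library_size = 1e5),
       diversity = list(permutations = 999),
       membership = list(detection = 500, prevalence = 0.4),
       lefse = list(alpha = 0.05, lda_threshold = 2, n_boot = 30,
                    min_replicates = 3),
       network = list(min_abundance = 100, r_min = 0.7, p_max = 0.05,
                      method = "spearman", topk = 30,
                      z_cut = 2.5, p_cut = 0.62))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, normalize, diversity, membership, lefse and network
#' stages in order on a synthetic community and returns a machine-readable
#' run report (stage parameters echoed verbatim, headline outputs, seeds).
#' The report plus the config reproduce the run bit-identically.
#'
#' @param config a config list as from [default_pipeline_config()], or a
#'   path to a YAML file with the same structure.
#' @param report_path optional path; when given, the report is written there
#'   as JSON.
#' @return The run report, invisibly a list.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         report_path = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: field 'seed' is required")
  for (field in c("simulate", "diversity", "membership", "lefse", "network")) {
    if (is.null(config[[field]]))
      stop("config error: missing stage '", field, "'")
  }
  seed <- as.integer(config$seed)
  report <- list(version = as.character(utils::packageVersion("pitchercosm")),
                 seed = seed, stages = list())
  stage <- function(name, params, f) {
    out <- tryCatch(f(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- c(list(parameters = params),
                                out[names(out) != "result"])
    out
  }

  sim <- stage("simulate", config$simulate, function() {
    cfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    res <- simulate_counts(cfg)
    list(n_taxa = nrow(res$matrix$counts),
         n_samples = ncol(res$matrix$counts),
         result = res)
  })
  m_raw <- sim$result$matrix
  truth <- sim$result$truth

  norm <- stage("normalize", list(method = "cpm"), function() {
    m_cpm <- cpm_normalize(m_raw)
    list(column_sums_ok = all(abs(colSums(m_cpm$counts) - 1e6) < 1),
         result = m_cpm)
  })
  m_cpm <- norm$result

  stage("diversity", config$diversity, function() {
    alpha <- alpha_diversity(m_raw)
    d <- bray_curtis_matrix(m_cpm)
    ord <- pcoa(d)
    nperm <- config$diversity$permutations
    pmv <- permanova(d, m_raw$groups, nperm, seed + 1L)
    pdp <- permdisp(d, m_raw$groups, nperm, seed + 2L)
    wil <- pairwise_wilcoxon(alpha, "shannon")
    list(mean_shannon = mean(alpha$shannon),
         permanova_F = pmv$statistic, permanova_p = pmv$p_value,
         permdisp_F = pdp$statistic, permdisp_p = pdp$p_value,
         min_wilcoxon_p = min(wil$p_value, na.rm = TRUE),
         seed = seed + 1L)
  })

  mem <- stage("membership", config$membership, function() {
    groups <- unique(m_raw$groups)
    enr <- lapply(stats::setNames(groups, groups),
                  function(g) genotype_enriched(m_raw, g))
    ubi <- ubiquitous_set(m_raw)
    venn <- venn_partition(enr)
    core <- core_microbiome(m_cpm,
                            prevalence_cutoff = config$membership$prevalence,
                            detection = config$membership$detection)
    shared <- length(intersect(ubi, core$core))
    list(n_ubiquitous = length(ubi),
         n_core = length(core$core),
         venn_union = venn$total_union,
         ubiquitous_core_overlap_pct =
           if (length(ubi) && length(core$core))
             overlap_percent(shared, "set_a", size_a = length(ubi)) else NA,
         enriched_recovery =
           mean(unlist(lapply(names(truth$enriched_taxa), function(g)
             truth$enriched_taxa[[g]] %in% enr[[g]]))))
  })

  stage("lefse", config$lefse, function() {
    tab <- table(m_raw$groups)
    ok <- names(tab)[tab >= config$lefse$min_replicates]
    pairs <- utils::combn(ok, 2, simplify = FALSE)
    res <- lapply(pairs, function(pr)
      lefse_pair(m_raw, pr, alpha = config$lefse$alpha,
                 threshold = config$lefse$lda_threshold,
                 n_boot = config$lefse$n_boot, seed = seed + 3L,
                 min_replicates = config$lefse$min_replicates))
    list(n_pairs = length(pairs),
         n_discriminative = sum(vapply(res, function(r) sum(r$passes), 0L)),
         seed = seed + 3L)
  })

  stage("network", config$network, function() {
    mf <- abundance_filter(m_cpm, config$network$min_abundance)
    net <- correlation_edges(mf, method = config$network$method,
                             r_min = config$network$r_min,
                             p_max = config$network$p_max)
    sc <- score_network(net, config$network$z_cut, config$network$p_cut)
    k <- min(config$network$topk, length(net$nodes))
    top_hub <- topk_subnetwork(net, stats::setNames(sc$nodes$hub_score,
                                                    sc$nodes$taxon), k)
    top_z <- topk_subnetwork(net, stats::setNames(sc$nodes$z,
                                                  sc$nodes$taxon), k)
    shared <- length(intersect(top_hub$nodes, top_z$nodes))
    list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
         n_communities = length(unique(sc$nodes$community)),
         modularity = sc$modularity,
         roles = as.list(table(sc$nodes$role)),
         topk_hub_z_overlap_pct =
           overlap_percent(shared, "union", size_a = k, size_b = k))
  })

  report$truth_summary <- list(
    n_core = length(truth$core_taxa),
    n_enriched = length(unlist(truth$enriched_taxa)),
    n_hubs = length(truth$hub_taxa))
  if (!is.null(report_path))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(report)
}
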