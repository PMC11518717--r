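#' Filter taxa by cumulative normalized abundance
#'
#' Retains taxa whose abundance summed over all samples strictly exceeds
#' `min_cumulative`, the pre-filter applied before network inference.
#'
#' @param m a normalized [count_matrix()].
#' @param min_cumulative row-sum threshold (default 100, strict `>`).
#' @return A filtered `count_matrix`.
#' @export
abundance_filter <- function(m, min_cumulative = 100) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- rowSums(m$counts) > min_cumulative
  count_matrix(m$counts[keep, , drop = FALSE],
               stats::setNames(m$groups, m$samples), m$normalized)
}

#' Correlation co-occurrence network
#'
#' For every taxon pair, computes the correlation across samples and a
#' two-sided p-value via the t transform `t = r sqrt((n-2)/(1-r^2))`; an
#' undirected edge connects the pair iff `|r| >= r_min` and `p <= p_max`.
#' Correlations are stored signed (negative edges are kept). Zero-variance
#' taxa are excluded from pairing with a warning.
#'
#' @param m a [count_matrix()] (typically CPM) with at least 4 samples.
#' @param method `"spearman"` (default, rank-based) or `"pearson"`.
#' @param r_min absolute-correlation threshold (default 0.7).
#' @param p_max p-value threshold (default 0.05).
#' @return list of class `cooccurrence_network`: `nodes` (taxon ids),
#'   `abundance` (cumulative per node), `edges` (data.frame u, v, r, p).
#' @export
correlation_edges <- function(m, method = c("spearman", "pearson"),
                              r_min = 0.7, p_max = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  method <- match.arg(method)
  n <- ncol(m$counts)
  if (n < 4) stop("need at least 4 samples for edge p-values")
  x <- m$counts
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance taxa: ",
            paste(m$taxa[sds == 0], collapse = ", "))
  }
  keep <- sds > 0
  x <- x[keep, , drop = FALSE]
  if (method == "spearman") x <- t(apply(x, 1, rank))
  r <- stats::cor(t(x))
  r[r > 1] <- 1; r[r < -1] <- -1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  ut <- which(upper.tri(r) & abs(r) >= r_min & p <= p_max, arr.ind = TRUE)
  edges <- data.frame(u = rownames(x)[ut[, 1]], v = rownames(x)[ut[, 2]],
                      r = r[ut], p = p[ut], stringsAsFactors = FALSE)
  structure(list(nodes = m$taxa[keep],
                 abundance = stats::setNames(rowSums(m$counts[keep, , drop = FALSE]),
                                             m$taxa[keep]),
                 edges = edges),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (%d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$r < 0)))
  invisible(x)
}

# unsigned igraph over all nodes (isolated nodes included)
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges))
    g <- igraph::add_edges(g, rbind(net$edges$u, net$edges$v))
  g
}

#' Greedy modularity community detection
#'
#' Clauset-Newman-Moore greedy agglomeration maximizing modularity
#' `Q = sum_c (e_cc - a_c^2)` on the unsigned, unweighted graph (edge
#' presence only; correlation signs ignored). Isolated nodes become
#' singleton communities.
#'
#' @param net a `cooccurrence_network`.
#' @return list: `membership` (named integer vector) and `modularity` (Q).
#' @export
greedy_modularity <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (!nrow(net$edges)) {
    return(list(membership = stats::setNames(seq_along(net$nodes), net$nodes),
                modularity = 0))
  }
  g <- as_igraph(net)
  cl <- igraph::cluster_fast_greedy(g)
  mem <- as.integer(igraph::membership(cl))
  q <- igraph::modularity(g, mem)
  # floating-point noise in the agglomeration can stop one merge early at an
  # exact modularity tie (e.g. a single clique); prefer the coarser
  # connected-component partition on ties
  comp <- as.integer(igraph::components(g)$membership)
  qc <- igraph::modularity(g, comp)
  if (qc >= q - 1e-12 && length(unique(comp)) < length(unique(mem))) {
    mem <- comp
    q <- qc
  }
  list(membership = stats::setNames(mem, igraph::V(g)$name),
       modularity = q)
}

#' Hub scores (eigenvector centrality)
#'
#' Principal-eigenvector centrality of the unsigned adjacency, computed per
#' connected component by exact symmetric eigendecomposition (robust where
#' iterative schemes stall on near-degenerate leading eigenvalues, e.g. two
#' dense modules joined by a single edge) and normalized so each component's
#' maximum — and hence the global maximum — is 1. Isolated nodes score 0.
#'
#' @param net a `cooccurrence_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
hub_scores <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nodes <- net$nodes
  score <- stats::setNames(numeric(length(nodes)), nodes)
  if (!nrow(net$edges)) return(score)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (c_id in seq_len(comp$no)) {
    idx <- which(comp$membership == c_id)
    if (length(idx) < 2) next
    Ac <- A[idx, idx, drop = FALSE]
    e <- eigen(Ac, symmetric = TRUE)
    v <- abs(e$vectors[, 1])
    score[idx] <- v / max(v)
  }
  score
}

# per-node edge counts into each community
community_degree <- function(net, communities) {
  nodes <- net$nodes
  k <- matrix(0L, length(nodes), max(communities),
              dimnames = list(nodes, NULL))
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      u <- net$edges$u[i]; v <- net$edges$v[i]
      k[u, communities[v]] <- k[u, communities[v]] + 1L
      k[v, communities[u]] <- k[v, communities[u]] + 1L
    }
  }
  k
}

#' Within-module degree z-score
#'
#' `kappa_i` is the number of edges from node i into its own community;
#' `z_i = (kappa_i - mean(kappa)) / sd(kappa)` standardized within the
#' community (population mean/sd over community members). Communities with
#' zero kappa variance get z = 0.
#'
#' @param net a `cooccurrence_network`.
#' @param communities named membership vector from [greedy_modularity()].
#' @return named numeric vector.
#' @export
within_module_z <- function(net, communities) {
  communities <- communities[net$nodes]
  kmat <- community_degree(net, communities)
  kappa <- kmat[cbind(seq_along(net$nodes), communities)]
  z <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  for (c_id in unique(communities)) {
    idx <- which(communities == c_id)
    s <- stats::sd(kappa[idx])
    if (length(idx) > 1 && !is.na(s) && s > 0)
      z[idx] <- (kappa[idx] - mean(kappa[idx])) / s
  }
  z
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (kappa_is / k_i)^2` over communities s; 0 when all of a
#' node's edges stay in one community and approaches `1 - 1/m` for edges
#' spread evenly over m communities. Degree-0 nodes get P = 0.
#'
#' @inheritParams within_module_z
#' @return named numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(net, communities) {
  communities <- communities[net$nodes]
  kmat <- community_degree(net, communities)
  k <- rowSums(kmat)
  p <- 1 - rowSums((kmat / pmax(k, 1))^2)
  p[k == 0] <- 0
  stats::setNames(p, net$nodes)
}

#' Classify node roles from z and participation
#'
#' Joint thresholds on within-module degree z-score and participation
#' coefficient: `z >= z_cut & P <= p_cut` module hub; `z >= z_cut & P >
#' p_cut` network hub; `z < z_cut & P > p_cut` connector; otherwise
#' peripheral.
#'
#' @param z named z-score vector.
#' @param p named participation vector.
#' @param z_cut z threshold (default 2.5).
#' @param p_cut participation threshold (default 0.62).
#' @return named character vector of roles.
#' @export
classify_roles <- function(z, p, z_cut = 2.5, p_cut = 0.62) {
  stopifnot(identical(names(z), names(p)))
  role <- ifelse(z >= z_cut,
                 ifelse(p <= p_cut, "module_hub", "network_hub"),
                 ifelse(p > p_cut, "connector", "peripheral"))
  stats::setNames(role, names(z))
}

#' Full node-score table for a network
#'
#' Runs community detection, hub scores, within-module z, participation and
#' role classification in one pass.
#'
#' @param net a `cooccurrence_network`.
#' @param z_cut,p_cut role thresholds passed to [classify_roles()].
#' @return list: `nodes` (data.frame with community, degree, kappa,
#'   hub_score, z, participation, role, abundance), `modularity`.
#' @export
score_network <- function(net, z_cut = 2.5, p_cut = 0.62) {
  com <- greedy_modularity(net)
  mem <- com$membership[net$nodes]
  kmat <- community_degree(net, mem)
  z <- within_module_z(net, mem)
  p <- participation_coefficient(net, mem)
  list(nodes = data.frame(
         taxon = net$nodes,
         community = as.integer(mem),
         degree = rowSums(kmat),
         kappa = kmat[cbind(seq_along(net$nodes), mem)],
         hub_score = hub_scores(net),
         z = z,
         participation = p,
         role = classify_roles(z, p, z_cut, p_cut),
         abundance = net$abundance[net$nodes],
         row.names = NULL),
       modularity = com$modularity)
}

#' Induced top-k subnetwork under a node ranking
#'
#' Takes the top `k` nodes by the given ranking (hub score, within-module z,
#' cumulative abundance, or participation; ties broken by node id) and
#' returns the induced subgraph; communities and scores are recomputed on
#' the subgraph by the caller via [score_network()].
#'
#' @param net a `cooccurrence_network`.
#' @param ranking named numeric vector over all nodes (higher is better).
#' @param k number of nodes to keep (default 100; capped at the node count
#'   with a warning).
#' @return A `cooccurrence_network` on the selected nodes.
#' @export
topk_subnetwork <- function(net, ranking, k = 100) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (!all(net$nodes %in% names(ranking)))
    stop("ranking must cover every node")
  if (k > length(net$nodes)) {
    warning("k exceeds node count; using all nodes")
    k <- length(net$nodes)
  }
  ord <- order(-ranking[net$nodes], net$nodes)
  keep <- net$nodes[ord[seq_len(k)]]
  sub_edges <- net$edges[net$edges$u %in% keep & net$edges$v %in% keep, ,
                         drop = FALSE]
  structure(list(nodes = sort(keep),
                 abundance = net$abundance[sort(keep)],
                 edges = sub_edges),
            class = "cooccurrence_network")
}
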