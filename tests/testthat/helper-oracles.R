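# shared oracles and fixture builders, independent of the package internals

# adjusted Rand index between two labelings
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  s <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (s - e) / ((si + sj) / 2 - e)
}

# random raw count matrix with named dims and a two-or-more group design
random_count_matrix <- function(n_taxa, design = c(A = 3, B = 3), lambda = 50) {
  samples <- paste0("s", seq_len(sum(design)))
  groups <- stats::setNames(rep(names(design), design), samples)
  x <- matrix(stats::rpois(n_taxa * sum(design), lambda), n_taxa,
              dimnames = list(sprintf("t%03d", seq_len(n_taxa)), samples))
  count_matrix(x, groups)
}

# brute-force all-pairs correlation edges via cor.test
brute_force_edges <- function(counts, method = "spearman", r_min = 0.7,
                              p_max = 0.05) {
  taxa <- rownames(counts)
  sds <- apply(counts, 1, stats::sd)
  taxa <- taxa[sds > 0]
  out <- list()
  for (i in seq_along(taxa)) {
    for (j in seq_len(i - 1)) {
      ct <- suppressWarnings(
        stats::cor.test(counts[taxa[j], ], counts[taxa[i], ],
                        method = method))
      r <- unname(ct$estimate)
      n <- ncol(counts)
      # same t transform the package documents, so both routes share the
      # p-value definition and differ only in implementation
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- if (abs(r) >= 1 - 1e-12) 0 else 2 * stats::pt(abs(tt), n - 2,
                                                         lower.tail = FALSE)
      if (abs(r) >= r_min && p <= p_max)
        out[[length(out) + 1]] <- data.frame(u = taxa[j], v = taxa[i])
    }
  }
  if (!length(out)) return(data.frame(u = character(0), v = character(0)))
  do.call(rbind, out)
}

edge_key <- function(edges) {
  if (!nrow(edges)) return(character(0))
  sort(paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v)))
}

# all set partitions of n elements (Bell-number enumeration)
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (c_id in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, c_id)
  }
  out
}

# modularity of a partition on an unweighted undirected edge list
modularity_oracle <- function(edges, membership) {
  m <- nrow(edges)
  nodes <- names(membership)
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(m)) {
    deg[edges$u[i]] <- deg[edges$u[i]] + 1
    deg[edges$v[i]] <- deg[edges$v[i]] + 1
  }
  q <- 0
  for (c_id in unique(membership)) {
    inc <- membership[edges$u] == c_id & membership[edges$v] == c_id
    e_cc <- sum(inc) / m
    a_c <- sum(deg[membership == c_id]) / (2 * m)
    q <- q + e_cc - a_c^2
  }
  q
}

# build a cooccurrence_network directly from an edge list (for graph-theory
# unit tests that do not need a count matrix)
make_network <- function(nodes, edges_df) {
  structure(list(nodes = nodes,
                 abundance = stats::setNames(rep(1, length(nodes)), nodes),
                 edges = edges_df),
            class = "cooccurrence_network")
}
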