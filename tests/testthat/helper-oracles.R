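# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately use the most literal formulation available (double
# loops, explicit enumeration, iterative propagation) rather than the
# package's code paths.

# Brute-force BH step-up: sort ascending, q_(i) = min_{j >= i} p_(j)*m/j,
# cap at 1, map back. Double loop, no cummin.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    qs[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- qs
  out
}

# Hypergeometric upper tail by explicit choose() summation (exact integers
# for N <= 20, so ratios are exact to double precision).
hyper_enum <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Iterative perturbation propagation in topological order (Kahn's
# algorithm, written out by hand). Only valid for acyclic topologies.
pf_propagate <- function(topology, delta_e) {
  nodes <- topology$nodes
  de <- setNames(numeric(length(nodes)), nodes)
  de[names(delta_e)] <- delta_e
  e <- topology$edges
  indeg <- setNames(integer(length(nodes)), nodes)
  for (t in e$target) indeg[t] <- indeg[t] + 1L
  queue <- nodes[indeg == 0]
  pf <- de
  order_seen <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_seen <- c(order_seen, v)
    out <- which(e$source == v)
    for (idx in out) {
      t <- e$target[idx]
      pf[t] <- pf[t] + e$weight[idx] / topology$n_downstream[v] * pf[v]
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
  }
  stopifnot(length(order_seen) == length(nodes))  # else not a DAG
  pf
}

# All-DE table: every feature passes the default thresholds.
all_de_table <- function(ids, class) {
  de_table(ids, class, log2fc = rep(2, length(ids)),
           pvalue = rep(1e-8, length(ids)), qvalue = rep(1e-8, length(ids)))
}

interaction_rows <- function(reg, class, targets, source_db = "test",
                             evidence = "test") {
  data.frame(regulator_id = reg, regulator_class = class,
             target_gene = targets, source_db = source_db,
             evidence = evidence, stringsAsFactors = FALSE)
}

# Fixture network encoding the published ZEB1 / NFATC1 regulator overlay:
# ZEB1 is targeted by 4 miRNAs and 6 lncRNAs, NFATC1 by 2 lncRNAs and
# 2 miRNAs. The SERHL spelling variant is carried as an alias.
overlay_fixture_network <- function() {
  zeb1_mirnas <- c("miR-335-3p", "miR-493-5p", "miR-543", "miR-548h-5p")
  zeb1_lncrnas <- c("H19", "LINC00313", "LINC00152", "TPTEP1",
                    "LINC00086/SMIM10L2A", "DGCR5")
  de_mirnas <- all_de_table(c(zeb1_mirnas, "miR-218-5p"), "miRNA")
  de_lncrnas <- all_de_table(c(zeb1_lncrnas, "SERHL/SRHL"), "lncRNA")
  de_genes <- all_de_table(c("ZEB1", "NFATC1", "EGFR"), "gene")
  mirna_int <- rbind(
    interaction_rows(zeb1_mirnas, "miRNA", "ZEB1"),
    interaction_rows(c("miR-218-5p", "miR-493-5p"), "miRNA", "NFATC1"))
  # the interaction table uses the single-symbol spellings; the DE table's
  # "A/B" aliases must reconcile them
  lncrna_int <- rbind(
    interaction_rows(sub(".*/", "", zeb1_lncrnas), "lncRNA", "ZEB1"),
    interaction_rows(c("TPTEP1", "SRHL"), "lncRNA", "NFATC1"))
  merge_networks(
    build_network(de_mirnas, de_genes, mirna_int),
    build_network(de_lncrnas, de_genes, lncrna_int))
}

# Small fixed DAG used by several impact tests.
toy_dag <- function() {
  pathway_topology(
    nodes = c("A", "B", "C", "D", "E"),
    edges = data.frame(
      source = c("A", "A", "B", "C", "D"),
      target = c("B", "C", "D", "D", "E"),
      weight = c(1, -1, 1, 1, -1),
      stringsAsFactors = FALSE))
}

random_dag <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  w <- sample(c(1, -1), sum(keep), replace = TRUE)
  pathway_topology(nodes, data.frame(
    source = nodes[pairs[keep, 1]], target = nodes[pairs[keep, 2]],
    weight = w, stringsAsFactors = FALSE))
}
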