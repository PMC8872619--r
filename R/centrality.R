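# Degree-centrality ranking of regulators and co-regulation partition
# statistics. In a bipartite regulator->target network the only centrality
# in play is the out-degree over distinct DE targets; hubs are regulators
# with exceptionally many targets (here labelled "hub" above 100 distinct
# DE targets and "minor" below 20, the split observed for lncRNAs).

#' Rank regulators by degree centrality
#'
#' Degree = number of distinct DE gene targets. Regulators present in the
#' network's candidate list but retaining zero edges are reported with
#' degree 0. Rows are ordered by decreasing degree (ties broken
#' lexicographically by regulator id) with 1-based ranks; lncRNAs are
#' additionally labelled `"hub"` (degree > 100) or `"minor"` (degree < 20)
#' for reporting.
#'
#' @param net a [regulatory_network()].
#' @return a `data.frame` of class `ranking_result` with columns
#'   `regulator_id`, `regulator_class`, `degree`, `rank`, `label`.
#' @export
regulator_degrees <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  deg <- tapply(net$edges$target_gene, net$edges$regulator_id,
                function(x) length(unique(x)))
  all_regs <- net$regulators
  extra <- setdiff(names(deg), all_regs$regulator_id)
  if (length(extra)) {
    cls <- net$edges$regulator_class[match(extra, net$edges$regulator_id)]
    all_regs <- rbind(all_regs,
                      data.frame(regulator_id = extra, regulator_class = cls,
                                 stringsAsFactors = FALSE))
  }
  d <- deg[all_regs$regulator_id]
  d[is.na(d)] <- 0L
  out <- data.frame(
    regulator_id = all_regs$regulator_id,
    regulator_class = all_regs$regulator_class,
    degree = as.integer(d),
    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$regulator_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$label <- ifelse(out$degree > 100, "hub",
                      ifelse(out$degree < 20, "minor", "intermediate"))
  rownames(out) <- NULL
  attr(out, "tie_rule") <- "lexicographic"
  class(out) <- unique(c("ranking_result", class(out)))
  out
}

#' Select the top-k regulators of a class
#'
#' Returns the `k` highest-degree regulators, optionally restricted to one
#' regulator class. Boundary ties are resolved by `tie_rule`:
#' `"lexicographic"` (deterministic, default) keeps the alphabetically
#' first ids; `"keep-all-ties"` keeps every regulator tied with the k-th.
#' Asking for more regulators than exist returns all of them with a warning.
#'
#' @param ranking a `ranking_result` from [regulator_degrees()].
#' @param k number of regulators to select (default 10).
#' @param tie_rule `"lexicographic"` or `"keep-all-ties"`.
#' @param class optional filter: `"miRNA"` or `"lncRNA"`.
#' @return character vector of regulator ids, highest degree first.
#' @export
top_k <- function(ranking, k = 10, tie_rule = c("lexicographic", "keep-all-ties"),
                  class = NULL) {
  tie_rule <- match.arg(tie_rule)
  stopifnot_scalar_number(k, "k", min = 1)
  if (!is.null(class)) ranking <- ranking[ranking$regulator_class %in% class, ]
  ranking <- ranking[order(-ranking$degree, ranking$regulator_id), , drop = FALSE]
  n <- nrow(ranking)
  if (k >= n) {
    if (k > n) warning(sprintf("requested k = %d but only %d regulators exist", k, n))
    return(ranking$regulator_id)
  }
  if (tie_rule == "keep-all-ties") {
    cutoff <- ranking$degree[k]
    return(ranking$regulator_id[ranking$degree >= cutoff])
  }
  ranking$regulator_id[seq_len(k)]
}

#' Co-regulation partition statistics from counts
#'
#' Given the sizes of the top-miRNA target set M, the top-lncRNA target set
#' L, their intersection, and the total number of DE genes, computes the
#' network target count `|M u L|` by inclusion-exclusion and the seven
#' reporting percentages. Percentages are rounded to one decimal place
#' (half away from zero); `display = "integer"` truncates to whole percents
#' (the "26%" reporting style).
#'
#' @param m_targets,l_targets,shared set sizes `|M|`, `|L|`, `|M n L|`.
#' @param n_de_genes total number of DE genes (the percentage denominator).
#' @param display `"decimal"` (default) or `"integer"`.
#' @return a `partition_stats` list of counts and percentages.
#' @export
#' @examples
#' partition_stats_counts(567, 478, 217, 1361)$pct_network_of_de  # 60.8
partition_stats_counts <- function(m_targets, l_targets, shared, n_de_genes,
                                   display = c("decimal", "integer")) {
  display <- match.arg(display)
  for (nm in c("m_targets", "l_targets", "shared", "n_de_genes"))
    stopifnot_scalar_number(get(nm), nm, min = 0)
  if (shared > min(m_targets, l_targets))
    abort_validation("'shared' exceeds the smaller of |M| and |L|")
  network_targets <- m_targets + l_targets - shared
  if (n_de_genes < network_targets)
    abort_validation(sprintf(
      "n_de_genes (%d) is smaller than the network target count (%d)",
      n_de_genes, network_targets))
  pc <- function(num, den) format_pct(num, den, display)
  structure(list(
    n_de_genes = n_de_genes, m_targets = m_targets, l_targets = l_targets,
    shared = shared, network_targets = network_targets,
    pct_network_of_de = pc(network_targets, n_de_genes),
    pct_m_of_network = pc(m_targets, network_targets),
    pct_m_of_de = pc(m_targets, n_de_genes),
    pct_l_of_network = pc(l_targets, network_targets),
    pct_l_of_de = pc(l_targets, n_de_genes),
    pct_shared_of_network = pc(shared, network_targets),
    pct_shared_of_de = pc(shared, n_de_genes),
    display = display
  ), class = "partition_stats")
}

#' Co-regulation partition statistics from a network
#'
#' Computes the distinct target-gene sets of the listed top miRNAs (M) and
#' top lncRNAs (L) within `net`, then delegates to
#' [partition_stats_counts()].
#'
#' @param net a [regulatory_network()].
#' @param top_mirnas,top_lncrnas character vectors of regulator ids.
#' @param n_de_genes total DE gene count; defaults to the size of the
#'   network's DE gene universe.
#' @inheritParams partition_stats_counts
#' @return a `partition_stats` list; the realised sets are attached as
#'   attributes `m_set`, `l_set`.
#' @export
partition_stats <- function(net, top_mirnas, top_lncrnas,
                            n_de_genes = length(net$genes),
                            display = c("decimal", "integer")) {
  stopifnot(inherits(net, "regulatory_network"))
  e <- net$edges
  m_set <- unique(e$target_gene[e$regulator_id %in% top_mirnas])
  l_set <- unique(e$target_gene[e$regulator_id %in% top_lncrnas])
  out <- partition_stats_counts(length(m_set), length(l_set),
                                length(intersect(m_set, l_set)),
                                n_de_genes, display)
  attr(out, "m_set") <- m_set
  attr(out, "l_set") <- l_set
  out
}

#' @export
print.partition_stats <- function(x, ...) {
  cat(sprintf("co-regulation partition (of %d DE genes):\n", x$n_de_genes))
  cat(sprintf("  network targets |M u L|: %d (%s%% of DE genes)\n",
              x$network_targets, x$pct_network_of_de))
  cat(sprintf("  miRNA targets   |M|:     %d (%s%% of network, %s%% of DE)\n",
              x$m_targets, x$pct_m_of_network, x$pct_m_of_de))
  cat(sprintf("  lncRNA targets  |L|:     %d (%s%% of network, %s%% of DE)\n",
              x$l_targets, x$pct_l_of_network, x$pct_l_of_de))
  cat(sprintf("  co-regulated    |M n L|: %d (%s%% of network, %s%% of DE)\n",
              x$shared, x$pct_shared_of_network, x$pct_shared_of_de))
  invisible(x)
}

#' Pairwise regulator similarity by shared targets
#'
#' Jaccard index `|T(a) n T(b)| / |T(a) u T(b)|` over every pair of
#' regulators in the network; the diagonal is 1. A regulator with zero
#' retained targets has similarity 0 against all others and is flagged in
#' the `"zero_degree"` attribute.
#'
#' @param net a [regulatory_network()] with at least two regulators.
#' @return a symmetric numeric matrix with regulator ids as dimnames.
#' @export
regulator_similarity <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  regs <- net$regulators$regulator_id
  if (length(regs) < 2)
    abort_validation("similarity needs at least two regulators")
  tsets <- lapply(setNames(regs, regs), function(r)
    unique(net$edges$target_gene[net$edges$regulator_id == r]))
  n <- length(regs)
  sim <- matrix(0, n, n, dimnames = list(regs, regs))
  for (i in seq_len(n)) {
    sim[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      u <- length(union(tsets[[i]], tsets[[j]]))
      sim[i, j] <- sim[j, i] <-
        if (u == 0) 0 else length(intersect(tsets[[i]], tsets[[j]])) / u
    }
  }
  zero <- regs[lengths(tsets) == 0]
  if (length(zero)) {
    sim[zero, ] <- 0; sim[, zero] <- 0
    diag(sim) <- 1
    attr(sim, "zero_degree") <- zero
  }
  sim
}
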