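# Topology-based pathway impact analysis in the SPIA style.
#
# Each pathway gene i receives a perturbation factor
#   PF(i) = dE(i) + sum_j beta_ij / N_ds(j) * PF(j)
# over its upstream regulators j, where dE is the observed log2 fold change
# (0 for non-DE genes), beta_ij is the signed edge weight (+1 activation,
# -1 inhibition) and N_ds(j) the number of downstream edges of j. The net
# accumulation Acc = PF - dE sums to the total accumulation tA. Evidence of
# enrichment (pNDE, hypergeometric) and of perturbation (pPERT, bootstrap
# on |tA|) combine as pG = c - c*ln(c) with c = pNDE * pPERT.

#' Construct a signed pathway topology
#'
#' @param nodes character vector of unique gene identifiers.
#' @param edges data frame with columns `source`, `target`, `weight`
#'   (only +1/-1) and optionally `relation` (annotation only).
#' @return a `pathway_topology` object with per-node downstream counts.
#' @export
pathway_topology <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort_validation("pathway node ids must be unique")
  if (nrow(edges)) {
    if (!all(edges$weight %in% c(-1, 1)))
      abort_validation("pathway edge weights must be +1 or -1")
    bad <- setdiff(unique(c(edges$source, edges$target)), nodes)
    if (length(bad))
      abort_validation(paste0("edge endpoint(s) not in node set: ",
                              paste(bad, collapse = ", ")))
    if (anyDuplicated(edges[c("source", "target")]))
      abort_validation("duplicate pathway edges")
  }
  if (is.null(edges$relation))
    edges$relation <- ifelse(edges$weight > 0, "activation", "inhibition")
  n_ds <- table(factor(edges$source, levels = nodes))
  structure(list(nodes = nodes,
                 edges = as.data.frame(edges, stringsAsFactors = FALSE),
                 n_downstream = setNames(as.integer(n_ds), nodes)),
            class = "pathway_topology")
}

#' @export
print.pathway_topology <- function(x, ...) {
  cat(sprintf("pathway_topology: %d nodes, %d signed edges (%d activating)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight > 0)))
  invisible(x)
}

# Normalised influence matrix B with B[target, source] = weight / N_ds(source).
influence_matrix <- function(topology) {
  n <- length(topology$nodes)
  B <- matrix(0, n, n, dimnames = list(topology$nodes, topology$nodes))
  e <- topology$edges
  if (nrow(e)) {
    w <- e$weight / topology$n_downstream[e$source]
    B[cbind(match(e$target, topology$nodes), match(e$source, topology$nodes))] <- w
  }
  B
}

name_singular_cycle <- function(topology) {
  g <- igraph::graph_from_data_frame(topology$edges[c("source", "target")],
                                     vertices = topology$nodes)
  comp <- igraph::components(g, mode = "strong")
  cyc <- names(comp$membership)[comp$membership %in%
                                  which(comp$csize > 1)]
  loops <- topology$edges$source[topology$edges$source == topology$edges$target]
  unique(c(cyc, loops))
}

#' Per-gene perturbation factors and accumulation
#'
#' Solves the linear system `(I - B) PF = dE` where `B` is the normalised
#' influence matrix, then `Acc = PF - dE`. Genes with no upstream edges
#' have `Acc = 0`; on an edgeless topology `PF = dE` everywhere.
#'
#' @param topology a [pathway_topology()].
#' @param delta_e named numeric vector of log2 fold changes (0 or missing
#'   for non-DE genes); names must be pathway node ids.
#' @return list with `pf`, `acc` (named vectors) and `tA = sum(acc)`.
#' @export
perturbation_factors <- function(topology, delta_e) {
  stopifnot(inherits(topology, "pathway_topology"))
  de <- setNames(numeric(length(topology$nodes)), topology$nodes)
  if (length(delta_e)) {
    if (is.null(names(delta_e)))
      abort_validation("'delta_e' must be a named vector")
    unknown <- setdiff(names(delta_e), topology$nodes)
    if (length(unknown))
      abort_validation(paste0("delta_e name(s) not in the pathway: ",
                              paste(unknown, collapse = ", ")))
    de[names(delta_e)] <- delta_e
  }
  B <- influence_matrix(topology)
  A <- diag(nrow(B)) - B
  pf <- tryCatch(solve(A, de), error = function(e) e)
  if (inherits(pf, "error") || any(!is.finite(pf))) {
    cyc <- name_singular_cycle(topology)
    abort_validation(paste0(
      "perturbation system (I - B) is singular; feedback cycle involving: ",
      paste(cyc, collapse = ", ")))
  }
  pf <- setNames(as.numeric(pf), topology$nodes)
  acc <- pf - de
  list(pf = pf, acc = acc, tA = sum(acc))
}

#' SPIA-style pathway impact analysis
#'
#' Combines two independent lines of evidence for a pathway:
#' \itemize{
#'   \item `pNDE`: hypergeometric upper-tail probability of observing at
#'     least the observed number of DE genes on the pathway, given the DE
#'     count among all measured genes;
#'   \item `pPERT`: bootstrap probability of a total accumulation at least
#'     as extreme as observed, obtained by re-assigning the observed DE
#'     log2 fold changes to uniformly sampled pathway gene positions
#'     (`n_boot` replicates, add-one smoothed).
#' }
#' The combined evidence is `pG = c - c*ln(c)` with `c = pNDE * pPERT`.
#' With no DE gene on the pathway the result is degenerate
#' (`tA = 0`, `pNDE = pPERT = 1`) and flagged.
#'
#' @param topology a [pathway_topology()].
#' @param de_table a [de_table()] of selected DE features (genes).
#' @param all_measured character vector of all measured gene ids (the
#'   hypergeometric universe).
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed for the bootstrap.
#' @return an `impact_result` list: `pf`, `acc`, `tA`, `n_de_pathway`,
#'   `pNDE`, `pPERT`, `pG`, `degenerate`.
#' @export
impact_analysis <- function(topology, de_table, all_measured, n_boot = 2000,
                            seed = 1) {
  stopifnot(inherits(topology, "pathway_topology"))
  de_table <- validate_de_table(de_table)
  stopifnot_scalar_number(n_boot, "n_boot", min = 100)
  all_measured <- unique(normalize_gene_id(all_measured))
  node_key <- normalize_gene_id(topology$nodes)
  de_key <- normalize_gene_id(de_table$feature_id)
  de_key <- intersect(de_key, all_measured)
  pw_measured <- intersect(node_key, all_measured)
  de_on_pathway <- intersect(pw_measured, de_key)
  n_de_pw <- length(de_on_pathway)

  pNDE <- if (n_de_pw == 0) 1 else
    hypergeom_tail(n_de_pw, length(de_key), length(pw_measured),
                   length(all_measured))

  lfc <- de_table$log2fc[match(de_on_pathway, normalize_gene_id(de_table$feature_id))]
  delta_e <- setNames(lfc, topology$nodes[match(de_on_pathway, node_key)])
  pert <- perturbation_factors(topology, delta_e)

  if (n_de_pw == 0) {
    return(structure(list(pf = pert$pf, acc = pert$acc, tA = 0,
                          n_de_pathway = 0L, pNDE = 1, pPERT = 1, pG = 1,
                          degenerate = TRUE),
                     class = "impact_result"))
  }
  # tA is linear in delta_e: tA = cvec . dE with cvec = colSums((I-B)^-1 - I),
  # so the bootstrap only permutes positions and takes one dot product each.
  B <- influence_matrix(topology)
  M <- solve(diag(nrow(B)) - B) - diag(nrow(B))
  cvec <- colSums(M)
  n_nodes <- length(topology$nodes)
  set.seed(sub_seed(seed, 17L))
  t_boot <- vapply(seq_len(n_boot), function(b) {
    pos <- sample.int(n_nodes, n_de_pw)
    sum(cvec[pos] * lfc)
  }, numeric(1))
  pPERT <- (1 + sum(abs(t_boot) >= abs(pert$tA) - 1e-12)) / (n_boot + 1)
  c_ <- pNDE * pPERT
  pG <- if (c_ <= 0) 0 else c_ - c_ * log(c_)
  structure(list(pf = pert$pf, acc = pert$acc, tA = pert$tA,
                 n_de_pathway = as.integer(n_de_pw), pNDE = pNDE,
                 pPERT = pPERT, pG = min(1, pG), degenerate = FALSE),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf(
    "impact_result: %d DE genes on pathway, tA = %.4g, pNDE = %.3g, pPERT = %.3g, pG = %.3g%s\n",
    x$n_de_pathway, x$tA, x$pNDE, x$pPERT, x$pG,
    if (x$degenerate) " (degenerate: no DE genes)" else ""))
  invisible(x)
}

#' Overlay regulator counts on pathway genes
#'
#' For every pathway gene, reports the incident DE miRNAs and DE lncRNAs
#' from the regulatory network, their counts, and flags the most-regulated
#' gene(s) (highest total regulator count; ties all flagged).
#'
#' @param net a [regulatory_network()].
#' @param pathway_genes character vector of pathway gene ids.
#' @return a `data.frame` with columns `gene`, `n_mirna`, `n_lncrna`,
#'   `n_total`, `mirnas`, `lncrnas` (`;`-joined lists), `most_regulated`.
#' @export
regulator_overlay <- function(net, pathway_genes) {
  stopifnot(inherits(net, "regulatory_network"))
  genes <- unique(as.character(pathway_genes))
  gkey <- normalize_gene_id(genes)
  ekey <- normalize_gene_id(net$edges$target_gene)
  rows <- lapply(seq_along(genes), function(i) {
    inc <- net$edges[ekey == gkey[i], , drop = FALSE]
    mir <- sort(unique(inc$regulator_id[inc$regulator_class == "miRNA"]))
    lnc <- sort(unique(inc$regulator_id[inc$regulator_class == "lncRNA"]))
    data.frame(gene = genes[i], n_mirna = length(mir), n_lncrna = length(lnc),
               n_total = length(mir) + length(lnc),
               mirnas = paste(mir, collapse = ";"),
               lncrnas = paste(lnc, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$most_regulated <- out$n_total == max(out$n_total) & out$n_total > 0
  out <- out[order(-out$n_total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
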