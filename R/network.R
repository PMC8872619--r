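# Directed bipartite regulator->target networks restricted to DE targets.
#
# Edges are unsigned: at this level the analysis counts regulatory contacts,
# not activation/repression direction (signs live only in pathway
# topologies). Duplicate (regulator, target) pairs from different source
# databases collapse into a single edge carrying the merged evidence.

#' Construct a regulatory network object
#'
#' @param edges data frame with columns `regulator_id`, `regulator_class`,
#'   `target_gene`, `sources`, `evidence`, `n_sources` (one row per distinct
#'   regulator-target pair).
#' @param regulators data frame (`regulator_id`, `regulator_class`) of all
#'   candidate regulators considered, including those retaining zero edges.
#' @param genes character vector of the DE gene universe used as targets.
#' @return an object of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, regulators, genes) {
  cls <- tapply(c(edges$regulator_class, regulators$regulator_class),
                c(edges$regulator_id, regulators$regulator_id),
                function(x) length(unique(x)))
  if (any(cls > 1))
    abort_validation(paste0("regulator(s) carrying two classes: ",
                            paste(names(cls)[cls > 1], collapse = ", ")))
  if (any(duplicated(edges[c("regulator_id", "target_gene")])))
    abort_validation("duplicate (regulator, target) pairs in edge set")
  structure(list(edges = edges, regulators = regulators,
                 genes = unique(as.character(genes))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "regulatory_network: %d edges, %d regulators (%d miRNA, %d lncRNA), %d target genes\n",
    nrow(x$edges), nrow(x$regulators),
    sum(x$regulators$regulator_class == "miRNA"),
    sum(x$regulators$regulator_class == "lncRNA"),
    length(unique(x$edges$target_gene))))
  invisible(x)
}

#' Build a bipartite network from DE lists and an interaction table
#'
#' Keeps interaction rows whose regulator is among the DE regulators and
#' whose target is a DE gene; collapses duplicate (regulator, target) pairs
#' across source databases into one edge with concatenated evidence.
#' Matching is performed after identifier normalisation: gene symbols
#' case-insensitively, miRNA names with the species prefix stripped, and
#' `"A/B"` aliases expanded to both synonyms. Interaction rows whose
#' regulator equals its target (self-loop) are rejected, as is a gene-class
#' regulator table.
#'
#' @param de_regulators [de_table()] of DE miRNAs or lncRNAs.
#' @param de_genes [de_table()] of DE genes (targets universe).
#' @param interactions interaction data frame (`regulator_id`,
#'   `regulator_class`, `target_gene`, `source_db`, `evidence`).
#' @return a [regulatory_network()].
#' @export
build_network <- function(de_regulators, de_genes, interactions) {
  de_regulators <- validate_de_table(de_regulators)
  de_genes <- validate_de_table(de_genes)
  if (any(de_regulators$feature_class == "gene"))
    abort_validation("'de_regulators' must not contain gene-class features")
  interactions <- validate_interactions(interactions)
  if (any(normalize_gene_id(interactions$regulator_id) ==
          normalize_gene_id(interactions$target_gene) &
          nzchar(interactions$regulator_id)))
    abort_validation("interaction table contains regulator self-loop(s)")

  reg_keys <- id_match_keys(de_regulators$feature_id, normalize_gene_id)
  reg_keys$key <- normalize_regulator_id(
    reg_keys$key, rep(de_regulators$feature_class,
                      lengths(strsplit(de_regulators$feature_id, "/", fixed = TRUE))))
  gene_keys <- id_match_keys(de_genes$feature_id, normalize_gene_id)

  regulators <- unique(data.frame(
    regulator_id = de_regulators$feature_id,
    regulator_class = de_regulators$feature_class,
    stringsAsFactors = FALSE))

  if (nrow(interactions) == 0L || nrow(de_regulators) == 0L)
    return(regulatory_network(empty_edges(), regulators, de_genes$feature_id))

  ikey_reg <- normalize_regulator_id(interactions$regulator_id,
                                     interactions$regulator_class)
  ikey_tgt <- normalize_gene_id(interactions$target_gene)
  rmatch <- match(ikey_reg, reg_keys$key)
  gmatch <- match(ikey_tgt, gene_keys$key)
  keep <- !is.na(rmatch) & !is.na(gmatch)
  kept <- interactions[keep, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(regulatory_network(empty_edges(), regulators, de_genes$feature_id))

  # canonical display spellings come from the DE tables
  kept$regulator_id <- reg_keys$display[rmatch[keep]]
  kept$target_gene <- gene_keys$display[gmatch[keep]]
  key <- paste(kept$regulator_id, kept$target_gene, sep = "\r")
  agg <- function(v) vapply(split(v, key)[unique(key)],
                            function(s) paste(unique(s), collapse = ";"),
                            character(1))
  first <- !duplicated(key)
  edges <- data.frame(
    regulator_id = kept$regulator_id[first],
    regulator_class = kept$regulator_class[first],
    target_gene = kept$target_gene[first],
    sources = unname(agg(kept$source_db)),
    evidence = unname(agg(kept$evidence)),
    n_sources = unname(vapply(split(kept$source_db, key)[unique(key)],
                              function(s) length(unique(s)), integer(1))),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  regulatory_network(edges, regulators, de_genes$feature_id)
}

empty_edges <- function() {
  data.frame(regulator_id = character(0), regulator_class = character(0),
             target_gene = character(0), sources = character(0),
             evidence = character(0), n_sources = integer(0),
             stringsAsFactors = FALSE)
}

validate_interactions <- function(tab) {
  req <- c("regulator_id", "regulator_class", "target_gene")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    abort_validation(paste0("interaction table lacks column(s): ",
                            paste(miss, collapse = ", ")))
  bad <- setdiff(unique(tab$regulator_class), c("miRNA", "lncRNA"))
  if (length(bad))
    abort_validation(paste0("unknown regulator_class value(s): ",
                            paste(bad, collapse = ", ")))
  ncls <- tapply(tab$regulator_class, tab$regulator_id,
                 function(x) length(unique(x)))
  if (any(ncls > 1))
    abort_validation("regulator_class inconsistent within a regulator_id")
  if (is.null(tab$source_db)) tab$source_db <- rep("unspecified", nrow(tab))
  if (is.null(tab$evidence)) tab$evidence <- rep("unspecified", nrow(tab))
  tab
}

#' Merge two bipartite regulatory networks
#'
#' Edge-set union with evidence merging; a regulator appearing in both
#' networks with different classes is a validation error. The merged target
#' set is the union of the two target sets. Merging is commutative and
#' associative on edge sets.
#'
#' @param net_a,net_b [regulatory_network()] objects sharing the gene
#'   namespace.
#' @return the merged [regulatory_network()].
#' @export
merge_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "regulatory_network"),
            inherits(net_b, "regulatory_network"))
  edges <- rbind(net_a$edges, net_b$edges)
  key <- paste(edges$regulator_id, edges$target_gene, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    merged <- edges[first, , drop = FALSE]
    merged$sources <- vapply(split(edges$sources, key)[unique(key)],
                             function(s) paste(unique(unlist(strsplit(s, ";"))), collapse = ";"),
                             character(1), USE.NAMES = FALSE)
    merged$evidence <- vapply(split(edges$evidence, key)[unique(key)],
                              function(s) paste(unique(unlist(strsplit(s, ";"))), collapse = ";"),
                              character(1), USE.NAMES = FALSE)
    merged$n_sources <- vapply(strsplit(merged$sources, ";"), length, integer(1))
    edges <- merged
  }
  rownames(edges) <- NULL
  regulators <- unique(rbind(net_a$regulators, net_b$regulators))
  rownames(regulators) <- NULL
  regulatory_network(edges, regulators, union(net_a$genes, net_b$genes))
}

#' Export a network as SIF
#'
#' Cytoscape simple-interaction format: one `regulator regulates target`
#' line per edge, tab-separated.
#'
#' @param net a [regulatory_network()].
#' @param path output file path.
#' @param provenance optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path, provenance = NULL) {
  lines <- c(provenance,
             paste(net$edges$regulator_id, "regulates", net$edges$target_gene,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML with node attributes
#'
#' Node attributes: `class` (miRNA/lncRNA/gene) and, when DE tables are
#' supplied, `log2fc` and `direction` (up/down), for Cytoscape styling.
#'
#' @param net a [regulatory_network()].
#' @param path output file path.
#' @param de_tables optional list of [de_table()]s used to annotate nodes.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, de_tables = NULL) {
  regs <- unique(net$edges[c("regulator_id", "regulator_class")])
  genes <- setdiff(unique(net$edges$target_gene), regs$regulator_id)
  nodes <- data.frame(
    name = c(regs$regulator_id, genes),
    class = c(regs$regulator_class, rep("gene", length(genes))),
    stringsAsFactors = FALSE)
  nodes$log2fc <- rep(NA_real_, nrow(nodes))
  if (!is.null(de_tables)) {
    de_all <- do.call(rbind, lapply(de_tables, function(t)
      t[c("feature_id", "log2fc")]))
    nodes$log2fc <- de_all$log2fc[match(nodes$name, de_all$feature_id)]
  }
  nodes$direction <- ifelse(is.na(nodes$log2fc), "unknown",
                            ifelse(nodes$log2fc >= 0, "up", "down"))
  nodes$log2fc[is.na(nodes$log2fc)] <- 0
  g <- igraph::graph_from_data_frame(
    net$edges[c("regulator_id", "target_gene")], directed = TRUE,
    vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
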