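# End-to-end pipeline: DE selection -> network construction/merge -> degree
# ranking -> co-regulation partition -> overrepresentation -> pathway impact
# -> regulator overlay -> exports. Fully deterministic given config + seed.

#' Build a pipeline configuration
#'
#' Either `simulate = TRUE` (inputs generated by the synthetic-data module
#' from `synth`) or explicit input paths (`genes_file`, `mirnas_file`,
#' `lncrnas_file`, `mirna_interactions_file`, `lncrna_interactions_file`,
#' and optionally `gmt_file`, `pathway_file`). All thresholds are surfaced
#' here; there are no hidden defaults beyond the documented module
#' defaults.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate generate synthetic inputs instead of reading files.
#' @param synth list of [synth_params()] arguments (when simulating).
#' @param fc_linear_min,q_max DE selection thresholds.
#' @param k,tie_rule top-k hub selection parameters.
#' @param background ORA background: `"measured"` (all genes in the DE
#'   input, the default) or a character vector of gene ids.
#' @param n_boot impact-analysis bootstrap replicates.
#' @param seed master seed recorded in every output's provenance header.
#' @param ... input file paths (see above).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, synth = list(),
                            fc_linear_min = 1.5, q_max = 0.01, k = 10,
                            tie_rule = "lexicographic",
                            background = "measured", n_boot = 2000,
                            seed = 1, ...) {
  cfg <- c(list(out_dir = out_dir, simulate = simulate, synth = synth,
                fc_linear_min = fc_linear_min, q_max = q_max, k = k,
                tie_rule = tie_rule, background = background,
                n_boot = n_boot, seed = as.integer(seed)),
           list(...))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with [pipeline_config()] fields.
#' @return a `pipeline_config` list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

# Fingerprint of the analytic configuration; the output location is
# excluded so the same analysis hashes identically wherever it is written.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}

provenance_lines <- function(config) {
  c(sprintf("# sennet %s", as.character(utils::packageVersion("sennet"))),
    sprintf("# config_hash %s", config_hash(config)),
    sprintf("# seed %d", config$seed))
}

pipeline_stage <- function(name, expr, log = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          "sennet_pipeline_error")
  })
  if (log)
    message(sprintf("[sennet] stage %-12s %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes, under `config$out_dir`:
#' `report.json` (all counts, percentages, rankings and p-values),
#' `ranking.tsv`, `partition.tsv`, `enrichment.tsv` (when a GMT is given),
#' `overlay.tsv` and `network.sif`/`network.graphml`. Every output carries
#' a provenance header (package version, config hash, seed); reruns with
#' an identical config produce byte-identical files.
#'
#' @param config a [pipeline_config()], or a path to its JSON form.
#' @param quiet suppress stage timing messages.
#' @return the report, invisibly (a named list).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  log <- !quiet
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- pipeline_stage("inputs", {
    if (isTRUE(config$simulate)) {
      sp <- do.call(synth_params, c(config$synth,
                                    if (is.null(config$synth$seed))
                                      list(seed = config$seed)))
      tabs <- simulate_de_tables(sp)
      de_genes_pre <- select_de(tabs$genes, config$fc_linear_min, config$q_max)
      ints <- simulate_interactions(sp, de_genes_pre$feature_id)
      list(genes = tabs$genes, mirnas = tabs$mirnas, lncrnas = tabs$lncrnas,
           mirna_int = ints$mirna, lncrna_int = ints$lncrna,
           gmt = if (!is.null(config$gmt_file)) read_gmt(config$gmt_file),
           pathway = if (!is.null(config$pathway_file))
             read_pathway(config$pathway_file)
           else simulate_pathway(min(25, max(1, nrow(tabs$genes))), 0.15,
                                 tabs$genes, seed = config$seed))
    } else {
      list(genes = read_de_table(config$genes_file),
           mirnas = read_de_table(config$mirnas_file),
           lncrnas = read_de_table(config$lncrnas_file),
           mirna_int = read_edge_table(config$mirna_interactions_file),
           lncrna_int = read_edge_table(config$lncrna_interactions_file),
           gmt = if (!is.null(config$gmt_file)) read_gmt(config$gmt_file),
           pathway = if (!is.null(config$pathway_file))
             read_pathway(config$pathway_file))
    }
  }, log)

  de <- pipeline_stage("de_select", {
    lapply(inputs[c("genes", "mirnas", "lncrnas")], select_de,
           fc_linear_min = config$fc_linear_min, q_max = config$q_max)
  }, log)

  net <- pipeline_stage("network", {
    net_m <- build_network(de$mirnas, de$genes, inputs$mirna_int)
    net_l <- build_network(de$lncrnas, de$genes, inputs$lncrna_int)
    merge_networks(net_m, net_l)
  }, log)

  ranking <- pipeline_stage("rank", regulator_degrees(net), log)
  top_m <- top_k(ranking, config$k, config$tie_rule, class = "miRNA")
  top_l <- top_k(ranking, config$k, config$tie_rule, class = "lncRNA")

  part <- pipeline_stage("partition", {
    if (nrow(de$genes) >= 1 && length(c(top_m, top_l)))
      partition_stats(net, top_m, top_l, n_de_genes = nrow(de$genes))
    else NULL
  }, log)

  enr <- pipeline_stage("enrich", {
    if (is.null(inputs$gmt)) NULL else {
      bg <- if (identical(config$background, "measured"))
        inputs$genes$feature_id else config$background
      ora(intersect(normalize_gene_id(de$genes$feature_id),
                    normalize_gene_id(bg)),
          inputs$gmt, bg)
    }
  }, log)

  imp <- pipeline_stage("impact", {
    if (is.null(inputs$pathway)) NULL
    else impact_analysis(inputs$pathway, de$genes, inputs$genes$feature_id,
                         n_boot = config$n_boot, seed = config$seed)
  }, log)

  overlay <- pipeline_stage("overlay", {
    if (is.null(inputs$pathway)) NULL
    else regulator_overlay(net, inputs$pathway$nodes)
  }, log)

  report <- pipeline_stage("export", {
    prov <- provenance_lines(config)
    write_sif(net, file.path(config$out_dir, "network.sif"), prov)
    write_graphml(net, file.path(config$out_dir, "network.graphml"),
                  de_tables = de)
    write_tsv_with_header(ranking, file.path(config$out_dir, "ranking.tsv"), prov)
    if (!is.null(enr))
      write_tsv_with_header(enr, file.path(config$out_dir, "enrichment.tsv"), prov)
    if (!is.null(overlay))
      write_tsv_with_header(overlay, file.path(config$out_dir, "overlay.tsv"), prov)
    report <- list(
      provenance = list(
        version = as.character(utils::packageVersion("sennet")),
        config_hash = config_hash(config), seed = config$seed),
      n_de = lapply(de, nrow),
      n_edges = nrow(net$edges),
      top_mirnas = top_m, top_lncrnas = top_l,
      ranking = ranking[c("regulator_id", "regulator_class", "degree",
                          "rank", "label")],
      partition = if (!is.null(part)) unclass(part)[setdiff(names(unclass(part)),
                                                            "display")],
      enrichment = enr,
      impact = if (!is.null(imp)) list(
        tA = imp$tA, n_de_pathway = imp$n_de_pathway, pNDE = imp$pNDE,
        pPERT = imp$pPERT, pG = imp$pG, degenerate = imp$degenerate),
      overlay = overlay)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    report
  }, log)

  invisible(report)
}
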