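# Seeded synthetic-data generators for the whole pipeline: DE tables with a
# null + shifted-effect mixture, regulator-target interaction tables with
# heavy-tailed out-degrees, planted hubs and a controllable target-set
# overlap, and small signed acyclic pathway topologies.
#
# Every generator consumes a single integer seed; per-table sub-streams are
# derived deterministically so adding one table never perturbs another.

#' Parameters for the synthetic-data generators
#'
#' Defaults describe a study-scale world: a few thousand measured genes of
#' which ~10% respond, a few hundred measured miRNAs and a few dozen
#' lncRNAs, strong effects (mean |log2FC| = 2 against a null scatter of
#' 0.35), a heavy-tailed regulator out-degree law (exponent 2), and an
#' overlap fraction of 0.45 - the share of lncRNA targets drawn from the
#' miRNA-target pool, matching the observed co-regulation scale where
#' roughly 45% of top-lncRNA targets were also miRNA targets.
#'
#' @param n_genes,n_mirna,n_lncrna feature counts (non-negative).
#' @param de_fraction probability a feature is differentially expressed.
#' @param effect_mean mean modular log2 fold change of DE features.
#' @param effect_sd spread of DE log2 fold changes.
#' @param null_sd scatter of null log2 fold changes (also the standard
#'   error coupling effect size to p-value).
#' @param degree_exponent power-law exponent (> 1) of regulator out-degrees.
#' @param planted_hubs list of planted hubs, each a list with `id`,
#'   `n_targets` and optionally `class` (`"miRNA"`/`"lncRNA"`; guessed from
#'   the id when absent).
#' @param overlap_fraction fraction of lncRNA targets sampled from the
#'   union of miRNA targets.
#' @param seed integer seed for all derived random streams.
#' @return a validated `synth_params` list.
#' @export
synth_params <- function(n_genes = 5000, n_mirna = 400, n_lncrna = 60,
                         de_fraction = 0.1, effect_mean = 2, effect_sd = 0.5,
                         null_sd = 0.35, degree_exponent = 2,
                         planted_hubs = list(), overlap_fraction = 0.45,
                         seed = 1) {
  for (nm in c("n_genes", "n_mirna", "n_lncrna")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm, min = 0)
    if (v != floor(v)) abort_parameter(sprintf("'%s' must be a whole number", nm))
  }
  stopifnot_scalar_number(de_fraction, "de_fraction", min = 0, max = 1)
  stopifnot_scalar_number(overlap_fraction, "overlap_fraction", min = 0, max = 1)
  stopifnot_scalar_number(effect_mean, "effect_mean")
  stopifnot_scalar_number(effect_sd, "effect_sd", min = 0)
  stopifnot_scalar_number(null_sd, "null_sd", min = 0)
  stopifnot_scalar_number(degree_exponent, "degree_exponent")
  if (degree_exponent <= 1) abort_parameter("'degree_exponent' must exceed 1")
  stopifnot_scalar_number(seed, "seed")
  if (!is.list(planted_hubs)) abort_parameter("'planted_hubs' must be a list")
  planted_hubs <- lapply(planted_hubs, function(h) {
    if (is.null(h$id) || is.null(h$n_targets))
      abort_parameter("each planted hub needs 'id' and 'n_targets'")
    if (h$n_targets > n_genes)
      abort_parameter(sprintf("planted hub '%s' wants %d targets but only %d genes exist",
                              h$id, h$n_targets, n_genes))
    h$class <- h$class %||%
      if (grepl("mir", h$id, ignore.case = TRUE)) "miRNA" else "lncRNA"
    h
  })
  structure(list(
    n_genes = as.integer(n_genes), n_mirna = as.integer(n_mirna),
    n_lncrna = as.integer(n_lncrna), de_fraction = de_fraction,
    effect_mean = effect_mean, effect_sd = effect_sd, null_sd = null_sd,
    degree_exponent = degree_exponent, planted_hubs = planted_hubs,
    overlap_fraction = overlap_fraction, seed = as.integer(seed)
  ), class = "synth_params")
}

# Per-table random sub-streams (fixed indices; do not renumber).
.streams <- c(genes = 1L, mirna = 2L, lncrna = 3L,
              mirna_net = 4L, lncrna_net = 5L, pathway = 6L)

simulate_one_de_table <- function(n, ids, feature_class, params, stream) {
  if (n == 0L) {
    empty <- de_table(character(0), character(0), numeric(0), numeric(0))
    empty$is_de_truth <- logical(0)
    return(empty)
  }
  set.seed(sub_seed(params$seed, .streams[[stream]]))
  is_de <- runif(n) < params$de_fraction
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  lfc <- rnorm(n, 0, params$null_sd)
  lfc[is_de] <- sgn[is_de] *
    (params$effect_mean + rnorm(sum(is_de), 0, params$effect_sd))
  # One-sided location-shift statistic with known null scale, folded to a
  # two-sided p: null features get uniform p, shifted features small p, and
  # p is a deterministic function of log2FC (effect and p stay coherent).
  z <- lfc / max(params$null_sd, 1e-12)
  p <- 2 * pnorm(-abs(z))
  tab <- de_table(ids, feature_class, log2fc = lfc, pvalue = p)
  tab$is_de_truth <- is_de
  tab
}

#' Simulate differential-expression tables
#'
#' Draws log2 fold changes from a two-component mixture (null centred at 0
#' with `null_sd`; with probability `de_fraction` an effect centred at
#' +/- `effect_mean` with `effect_sd`), couples p-values to effect sizes
#' through a location-shift z statistic, and BH-adjusts per table. A
#' ground-truth indicator column `is_de_truth` is kept for benchmarking.
#'
#' @param params a [synth_params()] object.
#' @return named list of three [de_table()]s: `genes`, `mirnas`, `lncrnas`.
#' @export
#' @examples
#' tabs <- simulate_de_tables(synth_params(n_genes = 50, n_mirna = 10,
#'                                         n_lncrna = 5, seed = 7))
#' nrow(tabs$genes)
simulate_de_tables <- function(params) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  list(
    genes = simulate_one_de_table(
      params$n_genes, sprintf("GENE%05d", seq_len(params$n_genes)),
      "gene", params, "genes"),
    mirnas = simulate_one_de_table(
      params$n_mirna, sprintf("hsa-miR-%04d", seq_len(params$n_mirna)),
      "miRNA", params, "mirna"),
    lncrnas = simulate_one_de_table(
      params$n_lncrna, sprintf("LNC%04d", seq_len(params$n_lncrna)),
      "lncRNA", params, "lncrna")
  )
}

# Truncated discrete power law on 1..d_max with the stated exponent.
sample_power_degrees <- function(n, d_max, exponent) {
  if (n == 0L) return(integer(0))
  d_max <- max(1L, d_max)
  probs <- seq_len(d_max)^(-exponent)
  sample.int(d_max, n, replace = TRUE, prob = probs)
}

sample_targets <- function(pool, d) sample(pool, min(d, length(pool)))

#' Simulate regulator-target interaction tables
#'
#' Generates one miRNA->gene and one lncRNA->gene edge table. Background
#' out-degrees follow a truncated discrete power law with
#' `degree_exponent`; planted hubs are assigned after background sampling
#' and receive exactly their stated target count. A fraction
#' `overlap_fraction` of each lncRNA's targets is drawn from the union of
#' miRNA targets, the remainder from genes outside that union, so the
#' realised miRNA/lncRNA target-set overlap is controllable. No duplicate
#' (regulator, target) rows occur within a table.
#'
#' @param params a [synth_params()] object.
#' @param de_genes character vector of candidate target gene ids.
#' @return named list of two interaction `data.frame`s (`mirna`, `lncrna`)
#'   with columns regulator_id, regulator_class, target_gene, source_db,
#'   evidence.
#' @export
simulate_interactions <- function(params, de_genes) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  de_genes <- unique(as.character(de_genes))
  hubs <- params$planted_hubs
  if (length(de_genes) == 0L && any(vapply(hubs, function(h) h$n_targets > 0, logical(1))))
    abort_parameter("planted hubs require a non-empty 'de_genes' pool")
  for (h in hubs) {
    if (h$n_targets > length(de_genes))
      abort_parameter(sprintf(
        "planted hub '%s' wants %d targets but only %d are available",
        h$id, h$n_targets, length(de_genes)))
  }
  d_max <- max(1L, min(length(de_genes), 150L))

  build_table <- function(reg_ids, class, stream, target_fun, source_db) {
    set.seed(sub_seed(params$seed, .streams[[stream]]))
    class_hubs <- Filter(function(h) h$class == class, hubs)
    extra <- setdiff(vapply(class_hubs, `[[`, character(1), "id"), reg_ids)
    reg_ids <- c(reg_ids, extra)
    deg <- sample_power_degrees(length(reg_ids), d_max, params$degree_exponent)
    names(deg) <- reg_ids
    for (h in class_hubs) deg[[h$id]] <- h$n_targets  # replaces background degree
    rows <- lapply(reg_ids, function(r) {
      tg <- target_fun(deg[[r]])
      if (length(tg) == 0L) return(NULL)
      data.frame(regulator_id = r, regulator_class = class, target_gene = tg,
                 source_db = source_db, evidence = "simulated",
                 stringsAsFactors = FALSE)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) == 0L)
      return(data.frame(regulator_id = character(0), regulator_class = character(0),
                        target_gene = character(0), source_db = character(0),
                        evidence = character(0), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }

  mirna_ids <- sprintf("hsa-miR-%04d", seq_len(params$n_mirna))
  mirna_tab <- build_table(mirna_ids, "miRNA", "mirna_net",
                           function(d) sample_targets(de_genes, d),
                           "synthetic_multimir")

  mirna_pool <- unique(mirna_tab$target_gene)
  other_pool <- setdiff(de_genes, mirna_pool)
  lnc_targets <- function(d) {
    d <- min(d, length(de_genes))
    n_ov <- rbinom(1, d, params$overlap_fraction)
    n_ov <- min(n_ov, length(mirna_pool))
    n_out <- min(d - n_ov, length(other_pool))
    # top up from the overlap pool if the outside pool ran short, but never
    # violate a hard overlap_fraction = 0 contract
    if (params$overlap_fraction > 0)
      n_ov <- min(d - n_out, length(mirna_pool))
    c(sample_targets(mirna_pool, n_ov), sample_targets(other_pool, n_out))
  }
  lnc_ids <- sprintf("LNC%04d", seq_len(params$n_lncrna))
  lncrna_tab <- build_table(lnc_ids, "lncRNA", "lncrna_net", lnc_targets,
                            "synthetic_longhorn")

  list(mirna = mirna_tab, lncrna = lncrna_tab)
}

#' Simulate a small signed pathway topology
#'
#' Builds an acyclic signed gene-gene graph: nodes are drawn (without
#' replacement, where possible) from the feature ids of `de_overlay` so the
#' topology overlaps the DE universe; each ordered pair (i, j), i < j in a
#' random topological order, receives an edge with probability `edge_prob`;
#' edge weights are +1 (activation, 75%) or -1 (inhibition, 25%), the
#' activation-heavy mix typical of curated signalling maps.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edge_prob edge probability in `[0, 1]`.
#' @param de_overlay a [de_table()] supplying the node-id universe.
#' @param seed integer seed.
#' @return a [pathway_topology()].
#' @export
simulate_pathway <- function(n_nodes, edge_prob, de_overlay, seed = 1) {
  stopifnot_scalar_number(n_nodes, "n_nodes", min = 1)
  stopifnot_scalar_number(edge_prob, "edge_prob", min = 0, max = 1)
  set.seed(sub_seed(seed, .streams[["pathway"]]))
  ids <- unique(as.character(de_overlay$feature_id))
  nodes <- if (length(ids) >= n_nodes) sample(ids, n_nodes) else
    c(sample(ids), sprintf("PWNODE%03d", seq_len(n_nodes - length(ids))))
  src <- integer(0); tgt <- integer(0)
  if (n_nodes > 1) {
    pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < edge_prob
    src <- pairs[keep, 1]; tgt <- pairs[keep, 2]
  }
  w <- if (length(src)) sample(c(1, -1), length(src), replace = TRUE,
                               prob = c(0.75, 0.25)) else numeric(0)
  edges <- data.frame(
    source = nodes[src], target = nodes[tgt], weight = w,
    relation = ifelse(w > 0, "activation", "inhibition"),
    stringsAsFactors = FALSE
  )
  pathway_topology(nodes, edges)
}
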