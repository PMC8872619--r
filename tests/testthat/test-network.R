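test_that("build_network filters to DE regulators and DE targets", {
  de_mirnas <- all_de_table(c("miR-A", "miR-B"), "miRNA")
  de_genes <- all_de_table(c("GENE1", "GENE2"), "gene")
  ints <- interaction_rows(c("miR-A", "miR-B", "miR-A"), "miRNA",
                           c("GENE1", "GENE2", "GENE9"))  # GENE9 not DE
  net <- build_network(de_mirnas, de_genes, ints)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$target_gene, c("GENE1", "GENE2"))

  # no DE regulators -> empty network
  empty_reg <- de_mirnas[0, ]
  net0 <- build_network(empty_reg, de_genes, ints)
  expect_equal(nrow(net0$edges), 0)
})

test_that("duplicate (regulator, target) pairs collapse with merged evidence", {
  de_mirnas <- all_de_table("miR-A", "miRNA")
  de_genes <- all_de_table("GENE1", "gene")
  ints <- rbind(
    interaction_rows("miR-A", "miRNA", "GENE1", source_db = "db1",
                     evidence = "validated"),
    interaction_rows("miR-A", "miRNA", "GENE1", source_db = "db2",
                     evidence = "predicted"))
  net <- build_network(de_mirnas, de_genes, ints)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$n_sources, 2L)
  expect_length(strsplit(net$edges$evidence, ";")[[1]], 2)
})

test_that("identifier normalisation reconciles spellings and aliases", {
  de_mirnas <- all_de_table("miR-335-3p", "miRNA")
  de_lncrnas <- all_de_table("LINC00086/SMIM10L2A", "lncRNA")
  de_genes <- all_de_table(c("Zeb1", "LINC00086/SMIM10L2A"), "gene")
  # species-prefixed, case-shuffled miRNA spelling still matches
  ints_m <- interaction_rows("hsa-miR-335-3P", "miRNA", "ZEB1")
  net_m <- build_network(de_mirnas, de_genes, ints_m)
  expect_equal(nrow(net_m$edges), 1)
  expect_equal(net_m$edges$regulator_id, "miR-335-3p")  # DE-table spelling wins
  expect_equal(net_m$edges$target_gene, "Zeb1")
  # alias halves match independently
  ints_l <- interaction_rows("SMIM10L2A", "lncRNA", "zeb1")
  net_l <- build_network(de_lncrnas, de_genes, ints_l)
  expect_equal(nrow(net_l$edges), 1)
  expect_equal(net_l$edges$regulator_id, "LINC00086/SMIM10L2A")
})

test_that("invalid inputs are rejected, not silently dropped", {
  de_mirnas <- all_de_table("miR-A", "miRNA")
  de_genes <- all_de_table("GENE1", "gene")
  bad_class <- interaction_rows("miR-A", "circRNA", "GENE1")
  expect_error(build_network(de_mirnas, de_genes, bad_class),
               class = "sennet_validation_error")
  self_loop <- interaction_rows("GENE1", "lncRNA", "GENE1")
  expect_error(build_network(all_de_table("GENE1", "lncRNA"), de_genes, self_loop),
               class = "sennet_validation_error")
  expect_error(build_network(all_de_table("g", "gene"), de_genes,
                             interaction_rows("miR-A", "miRNA", "GENE1")),
               class = "sennet_validation_error")
})

test_that("build_network is idempotent on its own emitted edge table", {
  de_mirnas <- all_de_table(c("miR-A", "miR-B", "miR-C"), "miRNA")
  de_genes <- all_de_table(sprintf("G%02d", 1:10), "gene")
  set.seed(2)
  ints <- interaction_rows(sample(de_mirnas$feature_id, 15, replace = TRUE),
                           "miRNA",
                           sample(de_genes$feature_id, 15, replace = TRUE))
  net <- build_network(de_mirnas, de_genes, ints)
  emitted <- net$edges
  emitted$source_db <- emitted$sources
  net2 <- build_network(de_mirnas, de_genes, emitted)
  cols <- c("regulator_id", "regulator_class", "target_gene")
  expect_equal(net2$edges[cols], net$edges[cols])
})

test_that("merge_networks is identity with empty, commutative and associative", {
  de_genes <- all_de_table(sprintf("G%02d", 1:12), "gene")
  mk <- function(regs, class, seed) {
    set.seed(seed)
    build_network(all_de_table(regs, class), de_genes,
                  interaction_rows(sample(regs, 10, replace = TRUE), class,
                                   sample(de_genes$feature_id, 10, replace = TRUE)))
  }
  a <- mk(c("miR-1", "miR-2"), "miRNA", 1)
  b <- mk(c("LNC-1", "LNC-2"), "lncRNA", 2)
  c_ <- mk(c("LNC-3", "LNC-4"), "lncRNA", 3)
  empty <- build_network(all_de_table(character(0), character(0))[0, ],
                         de_genes, a$edges[0, c(1:3)])

  keyset <- function(net) sort(paste(net$edges$regulator_id,
                                     net$edges$target_gene))
  expect_equal(keyset(merge_networks(a, empty)), keyset(a))
  expect_equal(keyset(merge_networks(a, b)), keyset(merge_networks(b, a)))
  expect_equal(keyset(merge_networks(merge_networks(a, b), c_)),
               keyset(merge_networks(a, merge_networks(b, c_))))
  # independent set-union oracle on a random pair
  expect_setequal(
    paste(merge_networks(a, b)$edges$regulator_id,
          merge_networks(a, b)$edges$target_gene),
    union(paste(a$edges$regulator_id, a$edges$target_gene),
          paste(b$edges$regulator_id, b$edges$target_gene)))
  # merged target set is the union of the two target sets
  expect_setequal(unique(merge_networks(a, b)$edges$target_gene),
                  union(a$edges$target_gene, b$edges$target_gene))
})

test_that("a regulator carrying two classes across networks is rejected", {
  de_genes <- all_de_table("G1", "gene")
  net_m <- build_network(all_de_table("X", "miRNA"), de_genes,
                         interaction_rows("X", "miRNA", "G1"))
  net_l <- build_network(all_de_table("X", "lncRNA"), de_genes,
                         interaction_rows("X", "lncRNA", "G1"))
  expect_error(merge_networks(net_m, net_l), class = "sennet_validation_error")
})

test_that("bipartite conservation: sum of out-degrees equals edge count", {
  net <- overlay_fixture_network()
  deg <- regulator_degrees(net)
  expect_equal(sum(deg$degree), nrow(net$edges))
})

test_that("SIF and GraphML exports are well-formed", {
  net <- overlay_fixture_network()
  tdir <- withr::local_tempdir()
  sif <- file.path(tdir, "net.sif")
  write_sif(net, sif, provenance = "# test")
  lines <- readLines(sif)
  expect_equal(length(lines), 1 + nrow(net$edges))
  expect_true(all(grepl("\tregulates\t", lines[-1])))
  gml <- file.path(tdir, "net.graphml")
  write_graphml(net, gml, de_tables = list(all_de_table("ZEB1", "gene")))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_true("class" %in% igraph::vertex_attr_names(g))
})
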