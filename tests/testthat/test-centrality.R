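star_network <- function(reg = "miR-A", class = "miRNA", n = 5) {
  genes <- sprintf("G%02d", seq_len(n))
  build_network(all_de_table(reg, class), all_de_table(genes, "gene"),
                interaction_rows(reg, class, genes))
}

test_that("regulator_degrees counts distinct DE targets and labels hubs", {
  expect_equal(regulator_degrees(star_network(n = 5))$degree, 5)

  big <- star_network("H19", "lncRNA", n = 120)
  r <- regulator_degrees(big)
  expect_equal(r$label, "hub")       # > 100 DE targets
  small <- star_network("SNHG5", "lncRNA", n = 3)
  expect_equal(regulator_degrees(small)$label, "minor")  # < 20

  # a DE regulator retaining zero edges is reported with degree 0
  de_genes <- all_de_table("G1", "gene")
  net <- build_network(all_de_table(c("miR-A", "miR-B"), "miRNA"), de_genes,
                       interaction_rows("miR-A", "miRNA", "G1"))
  r2 <- regulator_degrees(net)
  expect_equal(r2$degree[r2$regulator_id == "miR-B"], 0)
})

test_that("degrees equal an independent edge-list group-by count", {
  set.seed(31)
  regs <- sprintf("miR-%02d", 1:8)
  genes <- sprintf("G%03d", 1:40)
  ints <- unique(interaction_rows(sample(regs, 60, replace = TRUE), "miRNA",
                                  sample(genes, 60, replace = TRUE)))
  net <- build_network(all_de_table(regs, "miRNA"), all_de_table(genes, "gene"),
                       ints)
  r <- regulator_degrees(net)
  oracle <- sapply(regs, function(x)
    length(unique(ints$target_gene[ints$regulator_id == x])))
  expect_equal(setNames(r$degree, r$regulator_id)[regs], oracle)
  # ranks contiguous, degrees non-increasing
  expect_equal(r$rank, seq_len(nrow(r)))
  expect_true(all(diff(r$degree) <= 0))
})

test_that("top_k honours k, class filter and tie rules", {
  ranking <- data.frame(
    regulator_id = c("b", "a", "c", "d"),
    regulator_class = c("miRNA", "miRNA", "miRNA", "lncRNA"),
    degree = c(9L, 9L, 9L, 5L), stringsAsFactors = FALSE)
  expect_warning(full <- top_k(ranking, k = 10), "only 4")
  expect_length(full, 4)
  expect_equal(top_k(ranking, 2, "lexicographic", class = "miRNA"),
               c("a", "b"))
  expect_length(top_k(ranking, 2, "keep-all-ties", class = "miRNA"), 3)
})

test_that("keep-all-ties length matches a brute-force sort at the boundary", {
  set.seed(12)
  deg <- sample(1:8, 30, replace = TRUE)
  ranking <- data.frame(regulator_id = sprintf("r%02d", 1:30),
                        regulator_class = "miRNA", degree = deg,
                        stringsAsFactors = FALSE)
  got <- top_k(ranking, 10, "keep-all-ties")
  cutoff <- sort(deg, decreasing = TRUE)[10]
  expect_length(got, sum(deg >= cutoff))
  expect_length(top_k(ranking, 10, "lexicographic"), 10)
})

test_that("partition stats reproduce the published co-regulation accounting", {
  st <- partition_stats_counts(567, 478, 217, 1361)
  expect_equal(st$network_targets, 828)
  expect_equal(st$pct_network_of_de, 60.8)
  expect_equal(st$pct_m_of_network, 68.5)
  expect_equal(st$pct_m_of_de, 41.7)
  expect_equal(st$pct_l_of_network, 57.7)
  expect_equal(st$pct_l_of_de, 35.1)
  expect_equal(st$pct_shared_of_de, 15.9)
  sti <- partition_stats_counts(567, 478, 217, 1361, display = "integer")
  expect_equal(sti$pct_shared_of_network, 26)
})

test_that("partition stats boundaries and validation", {
  disjoint <- partition_stats_counts(10, 7, 0, 30)
  expect_equal(disjoint$network_targets, 17)
  identical_sets <- partition_stats_counts(12, 12, 12, 20)
  expect_equal(identical_sets$pct_shared_of_network, 100)
  expect_error(partition_stats_counts(10, 7, 8, 30),
               class = "sennet_validation_error")
  expect_error(partition_stats_counts(10, 7, 2, 10),
               class = "sennet_validation_error")
})

test_that("inclusion-exclusion holds on network-derived partitions", {
  set.seed(5)
  genes <- sprintf("G%03d", 1:60)
  regs_m <- sprintf("miR-%d", 1:6)
  regs_l <- sprintf("LNC-%d", 1:4)
  for (i in 1:10) {
    ints_m <- unique(interaction_rows(sample(regs_m, 40, TRUE), "miRNA",
                                      sample(genes, 40, TRUE)))
    ints_l <- unique(interaction_rows(sample(regs_l, 30, TRUE), "lncRNA",
                                      sample(genes, 30, TRUE)))
    net <- merge_networks(
      build_network(all_de_table(regs_m, "miRNA"), all_de_table(genes, "gene"), ints_m),
      build_network(all_de_table(regs_l, "lncRNA"), all_de_table(genes, "gene"), ints_l))
    st <- partition_stats(net, regs_m, regs_l, n_de_genes = 60)
    expect_equal(st$network_targets, st$m_targets + st$l_targets - st$shared)
    expect_equal(st$network_targets,
                 length(union(attr(st, "m_set"), attr(st, "l_set"))))
  }
})

test_that("planted hubs are recovered with recall 1.0 across 20 seeds", {
  genes <- sprintf("G%04d", 1:300)
  hubs <- sprintf("hsa-miR-HUB%d", 1:5)
  planted <- lapply(hubs, function(h) list(id = h, n_targets = 200,
                                           class = "miRNA"))
  for (seed in 1:20) {
    p <- synth_params(n_genes = 300, n_mirna = 40, n_lncrna = 5,
                      planted_hubs = planted, seed = seed)
    ints <- simulate_interactions(p, genes)
    regs <- unique(ints$mirna$regulator_id)
    net <- build_network(all_de_table(regs, "miRNA"),
                         all_de_table(genes, "gene"), ints$mirna)
    top <- top_k(regulator_degrees(net), 5, class = "miRNA")
    expect_setequal(top, hubs)
  }
})

test_that("regulator similarity is the Jaccard index over target sets", {
  genes <- all_de_table(c("g1", "g2", "g3", "g4"), "gene")
  regs <- all_de_table(c("A", "B", "C", "D"), "miRNA")
  ints <- rbind(interaction_rows("A", "miRNA", c("g1", "g2", "g3")),
                interaction_rows("B", "miRNA", c("g2", "g3", "g4")),
                interaction_rows("C", "miRNA", c("g1", "g2", "g3")))
  net <- build_network(regs, genes, ints)
  sim <- regulator_similarity(net)
  expect_equal(sim["A", "B"], 0.5)          # 2 shared / 4 union
  expect_equal(sim["A", "C"], 1)            # identical target sets
  expect_equal(unname(sim["A", "D"]), 0)    # D has no targets
  expect_equal(attr(sim, "zero_degree"), "D")
  expect_true(isSymmetric(unname(sim)))
  expect_true(all(sim >= 0 & sim <= 1))
  expect_equal(unname(diag(sim)), rep(1, 4))
  expect_error(regulator_similarity(star_network()),
               class = "sennet_validation_error")
})
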