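test_that("gene universe bookkeeping splits, deduplicates and counts probes", {
  res <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                    p_value = c(0.01, 0.2, 0.8))
  ann <- tiny_annotation(c("cg1", "cg2", "cg3", "cg9"),
                         genes = c("A;B;A", "B", "", "Z"))
  uni <- build_universe(res, ann)
  expect_setequal(uni$genes, c("A", "B"))
  expect_equal(uni$cpgs_per_gene[["A"]], 1L)
  expect_equal(uni$cpgs_per_gene[["B"]], 2L)
  expect_equal(uni$n_unannotated, 1L)      # cg3 has no genes
  expect_error(build_universe(res, tiny_annotation("cgX")), "empty")
  # synthetic generator bookkeeping round trip
  sim <- simulate_dataset(n_samples = 20, n_cpgs = 1500, seed = 41)
  r <- data.frame(probe_id = rownames(sim$beta), p_value = 0.5)
  u <- build_universe(r, sim$annotation)
  manual <- table(unlist(lapply(strsplit(sim$annotation$genes, ";"),
                                unique)))
  manual <- manual[names(manual) != ""]
  expect_equal(sort(u$cpgs_per_gene), sort(stats::setNames(as.integer(manual),
                                                           names(manual))))
})

test_that("nominal gene sets apply the strict threshold rule", {
  ann <- tiny_annotation(sprintf("cg%d", 1:6),
                         genes = c("A", "A", "B", "B", "C", "C"))
  res <- data.frame(probe_id = sprintf("cg%d", 1:6),
                    p_value = c(0.04, 0.8, 0.05, 0.9, 0.2, 0.3))
  expect_setequal(nominal_gene_set(res, ann, 0.05), "A")  # p=0.05 excluded
  expect_setequal(nominal_gene_set(res, ann, 0.21), c("A", "B", "C"))
  expect_equal(nominal_gene_set(res, ann, 0.001), character(0))
  expect_setequal(nominal_gene_set(res, ann, 0.99), c("A", "B", "C"))
  expect_error(nominal_gene_set(res, ann, 0), "threshold")
})

test_that("enrichment cells satisfy margin identities at every threshold", {
  sim <- simulate_dataset(n_samples = 60, n_cpgs = 4000, spike_fraction = 0.3,
                          delta = 0.08, seed = 42)
  res <- fit_sitewise(sim$beta, sim$sheet)
  enr <- enrichment_curve(res, sim$annotation, sim$risk_genes, n_perm = 3, seed = 2)
  expect_equal(nrow(enr$curve), 15)
  expect_true(all(diff(enr$curve$selected_genes) >= 0))
  expect_true(all(enr$curve$observed <= enr$curve$selected_genes))
  expect_true(all(enr$curve$observed <= enr$risk_in_universe))
  expect_equal(enr$curve$expected,
               enr$risk_in_universe * enr$curve$selected_genes / enr$universe_size)
  # restriction to the full probe set reproduces the curve exactly
  enr_all <- enrichment_curve(res, sim$annotation, sim$risk_genes, n_perm = 3,
                              seed = 2, restrict_cpgs = res$probe_id)
  expect_equal(enr_all$curve, enr$curve)
  expect_true(enr_all$restricted)
})

test_that("spiked risk genes produce strong enrichment with quiet permutation controls", {
  sim <- simulate_dataset(n_samples = 120, n_cpgs = 8000, k_latent = 0,
                          spike_fraction = 0.3, delta = 0.05, seed = 7)
  res <- fit_sitewise(sim$beta, sim$sheet)
  enr <- enrichment_curve(res, sim$annotation, sim$risk_genes, n_perm = 10, seed = 1)
  i <- which(enr$curve$threshold == 0.05)
  expect_lt(enr$curve$p_value[i], 1e-6)
  expect_gt(enr$curve$observed[i], enr$curve$expected[i])
  expect_true(all(enr$perm_p[, i] > 0.01))
})

test_that("enrichment p-values are uniform for random risk sets on null data", {
  sim <- simulate_dataset(n_samples = 120, n_cpgs = 6000, k_latent = 0,
                          delta = 0, seed = 43)
  res <- fit_sitewise(sim$beta, sim$sheet, adjustment = sim$truth$mixing[, -1])
  uni <- build_universe(res, sim$annotation)
  selected <- nominal_gene_set(res, uni, 0.05)
  set.seed(44)
  pv <- replicate(200, {
    rnd <- sample(uni$genes, 80)
    perewas:::enrichment_cells(selected, rnd, uni$genes)[4]
  })
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("larger spiked effects never weaken median enrichment", {
  meds <- vapply(c(0, 0.04, 0.08), function(delta) {
    sim <- simulate_dataset(n_samples = 100, n_cpgs = 4000, k_latent = 0,
                            spike_fraction = 0.3, delta = delta, seed = 45)
    res <- fit_sitewise(sim$beta, sim$sheet)
    enr <- enrichment_curve(res, sim$annotation, sim$risk_genes, n_perm = 1, seed = 1)
    stats::median(enr$curve$p_value[enr$curve$threshold <= 0.1], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) <= 1e-12))
})

test_that("cross-tissue overlap partitions match brute-force membership counts", {
  sets <- list(t1 = c("A", "B", "C"), t2 = c("A", "B", "C"), t3 = c("A", "B", "C"))
  risk <- gene_set(c("A", "B"))
  ov <- cross_tissue_overlap(sets, risk)
  expect_equal(ov$all_tissue_risk, 2)
  expect_equal(ov$all_tissue_nonrisk, 1)
  # disjoint sets intersect nowhere
  ov0 <- cross_tissue_overlap(list(t1 = "A", t2 = "B"), risk)
  expect_equal(ov0$all_tissue_risk, 0)
  # random subsets vs brute-force tabulation
  set.seed(46)
  genes <- sprintf("G%04d", 1:1000)
  sets5 <- lapply(1:5, function(i) sample(genes, 300))
  names(sets5) <- paste0("t", 1:5)
  risk5 <- gene_set(sample(genes, 100))
  ov5 <- cross_tissue_overlap(sets5, risk5)
  all_genes <- sort(unique(unlist(sets5)))
  memb <- sapply(sets5, function(s) all_genes %in% s)
  pat <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  brute <- table(pat[all_genes %in% risk5$genes])
  expect_equal(ov5$risk_counts[names(brute)],
               stats::setNames(as.integer(brute), names(brute)))
  expect_equal(sum(ov5$risk_counts) + sum(ov5$nonrisk_counts), length(all_genes))
})

test_that("ontology testing reduces to hypergeometric without probe-count bias", {
  set.seed(47)
  ngene <- 120
  genes <- sprintf("G%03d", 1:ngene)
  ann <- tiny_annotation(sprintf("cg%03d", 1:ngene), genes = genes)  # 1 CpG/gene
  res <- data.frame(probe_id = ann$probe_id,
                    p_value = ifelse(seq_len(ngene) <= 40, 0.01, 0.5))
  go_map <- data.frame(gene = genes,
                       category = rep(c("GO:1", "GO:2", "GO:3"), each = 40))
  tab <- ontology_enrichment(res, ann, go_map, threshold = 0.05)
  go1 <- tab[tab$category == "GO:1", ]
  expect_equal(go1$odds, 1, tolerance = 1e-9)
  expect_equal(go1$p_value, phyper(39, 40, 80, 40, lower.tail = FALSE),
               tolerance = 1e-6)
  # category equal to the whole universe is uninformative
  all_map <- data.frame(gene = genes, category = "GO:all")
  tab_all <- ontology_enrichment(res, ann, all_map, threshold = 0.05)
  expect_equal(tab_all$p_value, 1, tolerance = 1e-6)
  # categories below the minimum size are skipped
  small_map <- data.frame(gene = genes[1:3], category = "GO:small")
  expect_error(ontology_enrichment(res, ann, small_map), "at least 5")
})

test_that("a planted ontology category ranks first in most seeds", {
  wins <- 0
  for (s in 1:5) {
    sim <- simulate_dataset(n_samples = 100, n_cpgs = 4000, k_latent = 0,
                            spike_fraction = 0.6, delta = 0.07, seed = s)
    res <- fit_sitewise(sim$beta, sim$sheet)
    uni <- build_universe(res, sim$annotation)
    risk_in <- intersect(sim$risk_genes$genes, uni$genes)
    others <- setdiff(uni$genes, risk_in)
    set.seed(s)
    go_map <- rbind(
      data.frame(gene = risk_in, category = "GO:planted"),
      data.frame(gene = sample(others, min(200, length(others))),
                 category = rep(c("GO:a", "GO:b", "GO:c", "GO:d"), length.out =
                                  min(200, length(others)))))
    tab <- ontology_enrichment(res, sim$annotation, go_map)
    if (tab$category[1] == "GO:planted") wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("rank sums across tissues match brute-force recomputation", {
  t1 <- data.frame(category = c("a", "b", "c"), p_value = c(0.001, 0.5, 0.9))
  t2 <- data.frame(category = c("a", "b", "c"), p_value = c(0.01, 0.9, 0.5))
  rs <- rank_sum_across_tissues(list(x = t1, y = t2))
  expect_equal(rs$category[1], "a")
  expect_equal(rs$rank_sum[rs$category == "a"], 2)
  expect_equal(rs$rank_sum[rs$category == "b"], 5)
  # ties: identical p-values give equal average ranks everywhere
  tt <- data.frame(category = c("a", "b"), p_value = c(0.5, 0.5))
  rs2 <- rank_sum_across_tissues(list(x = tt, y = tt))
  expect_equal(rs2$rank_sum, c(3, 3))
  # missing categories are flagged
  rs3 <- rank_sum_across_tissues(list(x = t1, y = t2[1:2, ]))
  expect_false(rs3$complete[rs3$category == "c"])
  # random tables against direct recomputation
  set.seed(48)
  tabs <- lapply(1:5, function(i)
    data.frame(category = sprintf("c%02d", 1:30), p_value = runif(30)))
  names(tabs) <- paste0("t", 1:5)
  rs4 <- rank_sum_across_tissues(tabs)
  manual <- rowSums(sapply(tabs, function(tb) rank(tb$p_value)))
  expect_equal(rs4$rank_sum, sort(manual), tolerance = 1e-12)
})
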