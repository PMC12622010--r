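test_that("high-confidence map keeps only pathway co-members, per pathway", {
  genes <- c("g1", "g2", "g3"); mets <- c("m1", "m2"); cts <- c("A", "B")
  # (g1, m1) associated in both cell types; (g2, m2) associated in A only
  edges <- data.frame(gene = c("g1", "g1", "g2"),
                      metabolite = c("m1", "m1", "m2"),
                      cell_type = c("A", "B", "A"))
  map <- full_map_from_edges(edges, genes, mets, cts)
  gene_sets <- list(PW1 = c("g1", "g3"))
  membership <- data.frame(pathway_id = "PW1", metabolite_id = "m1")
  hc <- build_high_confidence_map(map, gene_sets, membership)
  # one pathway sharing g1 and m1, association in 2 cell types -> 2 quadruplets
  expect_equal(nrow(hc), 2L)
  expect_setequal(hc$cell_type, c("A", "B"))
  expect_equal(unique(hc$gene), "g1")
  # (g2, m2) associated but never co-members -> excluded
  expect_false("g2" %in% hc$gene)
  # a pair in k pathways yields k quadruplets
  gene_sets2 <- list(PW1 = "g1", PW2 = c("g1", "g2"))
  membership2 <- data.frame(pathway_id = c("PW1", "PW2"),
                            metabolite_id = c("m1", "m1"))
  hc2 <- build_high_confidence_map(map, gene_sets2, membership2)
  expect_equal(sum(hc2$gene == "g1" & hc2$cell_type == "A"), 2L)
})

test_that("the high-confidence map projects into the association map", {
  sim <- sim_config(n_patients = 60, n_celltypes = 2, n_genes = 60,
                    n_metabolites = 25, n_planted_pairs = 15,
                    n_planted_hub_genes = 0, n_planted_hub_metabolites = 0,
                    pathway_cover_fraction = 1, seed = 5)
  gen <- generate_cohort(sim)
  cfg <- analysis_config(n_hvg_genes = 60, n_hvg_metabolites = 25)
  map <- build_association_map(preprocess_cohort(gen$cohort, cfg), cfg)
  hc <- build_high_confidence_map(map, gen$pathways$gene_sets,
                                  gen$pathways$metabolite_membership)
  key <- function(d) paste(d$gene, d$metabolite, d$cell_type)
  sig <- map[map$p <= 0.005, ]
  expect_true(all(key(hc) %in% key(sig)))
  # membership conditions re-verifiable from the annotations
  for (i in seq_len(min(nrow(hc), 20))) {
    expect_true(hc$gene[i] %in% gen$pathways$gene_sets[[hc$pathway[i]]])
    mem <- gen$pathways$metabolite_membership
    expect_true(any(mem$pathway_id == hc$pathway[i] &
                      mem$metabolite_id == hc$metabolite[i]))
  }
})

test_that("frequency rankings tally quadruplets and conserve totals", {
  hc <- data.frame(
    metabolite = c(rep("m1", 3), "m2"),
    gene = c("g1", "g2", "g1", "g3"),
    cell_type = c("A", "A", "B", "A"),
    pathway = c("P1", "P1", "P2", "P2"),
    direction = c(-1L, -1L, 1L, -1L), p = 1e-4)
  rk <- rank_by_frequency(hc, "metabolite")
  expect_equal(rk$count[rk$id == "m1"], 3L)
  for (axis in c("metabolite", "gene", "pathway"))
    expect_equal(sum(rank_by_frequency(hc, axis)$count), nrow(hc))
  # distinct-pair counting collapses multi-pathway duplicates
  hc2 <- rbind(hc, transform(hc[1, ], pathway = "P9"))
  expect_equal(sum(rank_by_frequency(hc2, "metabolite", distinct_pairs = TRUE)$count),
               4L)
  # brute-force group-by oracle on a random fixture
  set.seed(6)
  rhc <- data.frame(metabolite = sample(c("m1", "m2", "m3"), 50, TRUE),
                    gene = sample(c("g1", "g2"), 50, TRUE),
                    cell_type = sample(c("A", "B"), 50, TRUE),
                    pathway = sample(c("P1", "P2"), 50, TRUE),
                    direction = 1L, p = 1e-4)
  rk <- rank_by_frequency(rhc, "gene")
  expect_equal(rk$count[rk$id == "g1"], sum(rhc$gene == "g1"))
  expect_true(all(diff(rk$count) <= 0))
  expect_equal(nrow(rank_by_frequency(rhc[0, ], "gene")), 0L)
})

test_that("direction-of-effect summary reports the inverse-trend share", {
  one_way <- data.frame(direction = rep(-1L, 5))
  expect_equal(direction_of_effect_summary(one_way), 1.0)
  balanced <- data.frame(direction = c(-1L, -1L, 1L, 1L))
  expect_equal(direction_of_effect_summary(balanced), 0.5)
})

test_that("planted negative-direction fraction is recovered", {
  sim <- sim_config(n_patients = 150, n_celltypes = 1, n_genes = 150,
                    n_metabolites = 50, n_planted_pairs = 100,
                    effect_size = 2, negative_fraction = 0.8,
                    n_planted_hub_genes = 0, n_planted_hub_metabolites = 0,
                    pathway_cover_fraction = 1, n_kl_metabolites = 0, seed = 41)
  gen <- generate_cohort(sim)
  cfg <- analysis_config(n_hvg_genes = 150, n_hvg_metabolites = 50)
  map <- build_association_map(preprocess_cohort(gen$cohort, cfg), cfg)
  hc <- build_high_confidence_map(map, gen$pathways$gene_sets,
                                  gen$pathways$metabolite_membership)
  frac <- direction_of_effect_summary(hc)
  se <- sqrt(0.8 * 0.2 / nrow(hc))
  # background (false-positive) quadruplets dilute the planted 80% slightly
  expect_lt(abs(frac - 0.8), 3 * se + 0.05)
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  # universe 5, set {a,b}, query {a,b}: P(X >= 2) = C(2,2)C(3,0)/C(5,2) = 0.1
  res <- set_enrichment(c("a", "b"), list(S = c("a", "b")), letters[1:5])
  expect_equal(res$p, 0.1)
  # zero overlap -> P(X >= 0) = 1
  res0 <- set_enrichment(c("d", "e"), list(S = c("a", "b")), letters[1:5])
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p, 1)
  # exhaustive enumeration oracle for all configurations with N <= 8
  tail_oracle <- function(k, K, N, n) {
    # enumerate all C(N, n) query draws, count those with >= k successes
    draws <- combn(N, n)
    mean(apply(draws, 2, function(d) sum(d <= K) >= k))
  }
  for (N in c(5, 8)) for (K in c(2, 4)) for (n in c(2, 3)) {
    universe <- sprintf("x%d", 1:N)
    gs <- list(S = universe[1:K])
    query <- universe[1:n]  # overlap = min(n, K) = n here
    res <- set_enrichment(query, gs, universe)
    expect_equal(res$p, tail_oracle(res$overlap, K, N, n), tolerance = 1e-12)
    query2 <- universe[(N - n + 1):N]  # overlap with tail of universe
    res2 <- set_enrichment(query2, gs, universe)
    expect_equal(res2$p, tail_oracle(res2$overlap, K, N, n), tolerance = 1e-12)
  }
  expect_error(set_enrichment("q", list(S = "a"), character(0)), "empty")
  expect_error(set_enrichment("zz", list(S = "a"), letters[1:3]), "subset")
})

test_that("GMT files round-trip through write and read", {
  sets <- list(PW1 = c("g1", "g2", "g3"), PW2 = c("g2", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})
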