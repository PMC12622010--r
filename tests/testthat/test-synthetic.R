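test_that("proportions rows sum to 1 and rare-type means match their targets", {
  sim <- sim_config(n_patients = 400, n_genes = 20, n_metabolites = 10,
                    n_planted_pairs = 0, n_planted_hub_genes = 0,
                    n_planted_hub_metabolites = 0, n_kl_metabolites = 0,
                    seed = 31)
  co <- generate_cohort(sim)$cohort
  expect_equal(unname(rowSums(co$proportions)), rep(1, 400), tolerance = 1e-9)
  # MSC mean proportion within 3 standard errors of its 0.12% target
  msc <- co$proportions[, "MSC"]
  se <- sd(msc) / sqrt(length(msc))
  expect_lt(abs(mean(msc) - 0.0012), 3 * se)
  hspc <- co$proportions[, "HSPC"]
  expect_lt(abs(mean(hspc) - 0.018), 3 * sd(hspc) / sqrt(length(hspc)))
})

test_that("null cohorts give uniform association p-values across seeds", {
  # KS test at level 0.01 should pass in >= 9 of 10 seeds
  passes <- vapply(1:10, function(s) {
    sim <- sim_config(n_patients = 60, n_celltypes = 1, n_genes = 100,
                      n_metabolites = 30, seed = 1000 + s)
    co <- generate_null_cohort(sim)
    cfg <- analysis_config(n_hvg_genes = 100, n_hvg_metabolites = 30)
    map <- build_association_map(preprocess_cohort(co, cfg), cfg)
    suppressWarnings(ks.test(map$p, "punif")$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(passes), 9L)
})

test_that("planted-pair recovery is monotone in effect size and cohort size", {
  tpr_at <- function(delta, n) {
    sim <- sim_config(n_patients = n, n_celltypes = 1, n_genes = 120,
                      n_metabolites = 40, n_planted_pairs = 40,
                      effect_size = delta, n_planted_hub_genes = 0,
                      n_planted_hub_metabolites = 0, n_kl_metabolites = 0,
                      seed = 77)
    gen <- generate_cohort(sim)
    cfg <- analysis_config(n_hvg_genes = 120, n_hvg_metabolites = 40)
    map <- build_association_map(preprocess_cohort(gen$cohort, cfg), cfg)
    evaluate_recovery(gen$truth, map)$tpr
  }
  by_delta <- c(tpr_at(0.5, 160), tpr_at(1.25, 160), tpr_at(2, 160))
  expect_true(all(diff(by_delta) >= 0))
  by_n <- c(tpr_at(1, 60), tpr_at(1, 120), tpr_at(1, 240))
  expect_true(all(diff(by_n) >= 0))
})

test_that("null truth gives NA TPR and near-alpha false discovery noise", {
  sim <- sim_config(n_patients = 80, n_celltypes = 1, n_genes = 100,
                    n_metabolites = 30, n_planted_pairs = 0,
                    n_planted_hub_genes = 0, n_planted_hub_metabolites = 0,
                    n_kl_metabolites = 0, seed = 13)
  gen <- generate_cohort(sim)
  cfg <- analysis_config(n_hvg_genes = 100, n_hvg_metabolites = 30)
  map <- build_association_map(preprocess_cohort(gen$cohort, cfg), cfg)
  r <- evaluate_recovery(gen$truth, map)
  expect_true(is.na(r$tpr))
  # every declared pair is a false positive under the null
  if (r$n_declared > 0) expect_equal(r$fdp, 1)
  expect_lt(r$n_declared, 0.005 * 3000 + 3 * sqrt(0.005 * 3000))
})

test_that("planted pathway pairs are present in the emitted annotations", {
  sim <- sim_config(n_patients = 40, n_celltypes = 2, n_genes = 60,
                    n_metabolites = 25, n_planted_pairs = 20,
                    n_planted_hub_genes = 1, n_planted_hub_metabolites = 1,
                    hub_fanout = 10, n_kl_metabolites = 3,
                    pathway_cover_fraction = 0.6, seed = 3)
  gen <- generate_cohort(sim)
  pp <- gen$truth$planted_pathway_pairs
  expect_gt(nrow(pp), 0)
  for (i in seq_len(nrow(pp))) {
    expect_true(pp$gene[i] %in% gen$pathways$gene_sets[[pp$pathway_id[i]]])
    mem <- gen$pathways$metabolite_membership
    expect_true(any(mem$pathway_id == pp$pathway_id[i] &
                      mem$metabolite_id == pp$metabolite[i]))
  }
  # pathway-planted pairs are a subset of all planted pairs
  key <- function(d) paste(d$gene, d$metabolite, d$cell_type)
  expect_true(all(key(pp) %in% key(gen$truth$planted_pairs)))
})

test_that("cell-level generation recovers the generating means", {
  sim <- sim_config(n_patients = 5, n_celltypes = 3, n_genes = 8,
                    n_metabolites = 5, n_planted_pairs = 0,
                    n_planted_hub_genes = 0, n_planted_hub_metabolites = 0,
                    n_kl_metabolites = 0, cell_noise_sd = 0, seed = 19)
  # one cell per (patient, cell type), zero noise -> exact recovery
  cl <- generate_cell_level(sim, cells_per_patient = 3L, balanced = TRUE)
  pb <- pseudobulk_average(cl$cell_matrix, cl$annotations$cell_type,
                           cl$annotations$patient_id)
  for (ct in names(pb))
    expect_equal(pb[[ct]], cl$means[[ct]], ignore_attr = TRUE)

  # many noisy cells: per-type recovery bias bounded by 3 * noise / sqrt(cells)
  sim$cell_noise_sd <- 1
  cl2 <- generate_cell_level(sim, cells_per_patient = 500L, balanced = TRUE)
  pb2 <- pseudobulk_average(cl2$cell_matrix, cl2$annotations$cell_type,
                            cl2$annotations$patient_id)
  for (ct in names(pb2)) {
    diffs <- pb2[[ct]] - cl2$means[[ct]]
    cells_per_type <- 500 / 3
    expect_lt(abs(mean(diffs)), 3 * 1 / sqrt(cells_per_type * length(diffs)) * 10)
    expect_lt(max(abs(diffs)), 5 * 1 / sqrt(cells_per_type / 3))
  }

  # fewer cells than cell types: absent combinations become missing entries
  cl3 <- generate_cell_level(sim, cells_per_patient = 2L)
  pb3 <- pseudobulk_average(cl3$cell_matrix, cl3$annotations$cell_type,
                            cl3$annotations$patient_id)
  expect_true(any(vapply(pb3, anyNA, logical(1))))
})

test_that("generation is deterministic and streams are independent", {
  sim <- sim_config(n_patients = 30, n_celltypes = 2, n_genes = 40,
                    n_metabolites = 15, n_planted_pairs = 0,
                    n_planted_hub_genes = 0, n_planted_hub_metabolites = 0,
                    n_kl_metabolites = 2, seed = 8)
  g1 <- generate_cohort(sim)
  g2 <- generate_cohort(sim)
  expect_equal(g1$cohort$metabolites, g2$cohort$metabolites)
  expect_equal(g1$cohort$pseudobulk, g2$cohort$pseudobulk)
  expect_equal(g1$truth, g2$truth)
  # switching off the metabolite severity plant leaves other draws alone
  sim0 <- sim; sim0$n_kl_metabolites <- 0L
  g0 <- generate_cohort(sim0)
  expect_equal(g0$cohort$pseudobulk, g1$cohort$pseudobulk)
  expect_equal(g0$cohort$metadata, g1$cohort$metadata)
  expect_equal(g0$cohort$proportions, g1$cohort$proportions)
  untouched <- setdiff(colnames(g0$cohort$metabolites),
                       g1$truth$kl_metabolites$metabolite)
  expect_equal(g0$cohort$metabolites[, untouched],
               g1$cohort$metabolites[, untouched])
})
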