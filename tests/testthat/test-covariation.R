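test_that("metabolite discretization follows the interpolated upper quartile", {
  g <- discretize_metabolite(1:8, q = 0.75, min_group = 2L)
  expect_equal(g$threshold_value, 6.25)
  expect_equal(which(g$group == 1L), c(7L, 8L))
  expect_equal(g$n1, 2L)

  set.seed(5)
  x <- sample(rnorm(119))  # 119 distinct values: 30 at/above Q0.75
  g <- discretize_metabolite(x)
  expect_equal(g$n1, 30L)
  expect_equal(g$n2, 89L)

  expect_null(discretize_metabolite(rep(3, 40)))       # degenerate: empty low group
  expect_null(discretize_metabolite(1:10, min_group = 5L))  # group 1 too small
})

test_that("pooled two-sample t matches the hand formula", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_stat, -3/sqrt(2/3), tolerance = 1e-12)  # pooled s2 = 1, df = 4
  expect_equal(r$t_stat, -3.674235, tolerance = 1e-6)
  expect_equal(r$p, 2 * pt(-abs(r$t_stat), 4))
  expect_equal(r$direction, -1L)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p, 1)

  flat <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(unlist(flat[c("t_stat", "p", "direction")]),
               c(t_stat = 0, p = 1, direction = 0))
  expect_true(flat$flag)
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
})

test_that("vectorized column t-tests agree with per-gene t.test", {
  set.seed(9)
  X <- matrix(rnorm(40 * 25), 40, 25)
  i1 <- 1:12; i2 <- 13:40
  got <- covomics:::col_t_stats(X, i1, i2)
  for (j in c(1, 7, 25)) {
    ref <- t.test(X[i1, j], X[i2, j], var.equal = TRUE)
    expect_equal(got$t_stat[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p[j], ref$p.value, tolerance = 1e-12)
  }
  # Welch variant
  gotw <- covomics:::col_t_stats(X, i1, i2, welch = TRUE)
  refw <- t.test(X[i1, 3], X[i2, 3])
  expect_equal(gotw$p[3], refw$p.value, tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up formula", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(1.0), 1.0)
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p); ro <- order(o)
    adj <- p[o] * n / seq_len(n)
    pmin(1, rev(cummin(rev(adj))))[ro]
  }
  set.seed(2)
  p <- runif(200)
  expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-14)
  expect_true(all(adjust_bh(p) >= p))
})

test_that("association map covers the full grid and flags planted pairs", {
  co <- toy_cohort(n = 30, n_genes = 5, n_mets = 3)
  cfg <- analysis_config(n_hvg_genes = 5, n_hvg_metabolites = 3)
  co <- preprocess_cohort(co, cfg)
  map <- build_association_map(co, cfg)
  expect_equal(nrow(map), 5 * 3 * 2)
  expect_true(all(map$p_adj >= map$p))
  expect_true(all(map$direction %in% c(-1L, 0L, 1L)))
  expect_equal(unique(map$n1 + map$n2), 30L)
  # single gene x metabolite x cell type toy has exactly one record
  co1 <- toy_cohort(n = 30, n_genes = 1, n_mets = 1, n_ct = 1)
  cfg1 <- analysis_config(n_hvg_genes = 1, n_hvg_metabolites = 1)
  map1 <- build_association_map(preprocess_cohort(co1, cfg1), cfg1)
  expect_equal(nrow(map1), 1L)
})

test_that("degree counts match a brute-force tally and keep zero entities", {
  genes <- sprintf("g%d", 1:4); mets <- sprintf("m%d", 1:3); cts <- c("A", "B")
  edges <- data.frame(gene = c("g1", "g1", "g2"),
                      metabolite = c("m1", "m2", "m1"),
                      cell_type = c("A", "A", "B"))
  map <- full_map_from_edges(edges, genes, mets, cts)
  deg <- compute_degrees(map)
  get <- function(kind, id, ct)
    deg$count[deg$kind == kind & deg$id == id & deg$cell_type == ct]
  expect_equal(get("gene", "g1", "A"), 2L)
  expect_equal(get("gene", "g2", "B"), 1L)
  expect_equal(get("gene", "g3", "A"), 0L)
  expect_equal(get("metabolite", "m1", "A"), 1L)
  expect_equal(sum(deg$count), 2L * nrow(edges))  # every edge counted on both sides
  # random map vs group-by oracle
  set.seed(4)
  grid <- expand.grid(gene = genes, metabolite = mets, cell_type = cts,
                      stringsAsFactors = FALSE)
  grid$p <- runif(nrow(grid))
  rmap <- make_map(grid, genes, mets, cts, alpha = 0.3)
  rdeg <- compute_degrees(rmap)
  sig <- grid[grid$p <= 0.3, ]
  for (g in genes) for (ct in cts)
    expect_equal(rdeg$count[rdeg$kind == "gene" & rdeg$id == g & rdeg$cell_type == ct],
                 sum(sig$gene == g & sig$cell_type == ct))
})

test_that("hub sets have exact sizes with deterministic tie-breaking", {
  genes <- sprintf("g%02d", 1:20); mets <- sprintf("m%02d", 1:10)
  deg <- rbind(
    data.frame(kind = "gene", id = rep(genes, 2),
               cell_type = rep(c("A", "B"), each = 20), count = 5L),
    data.frame(kind = "metabolite", id = rep(mets, 2),
               cell_type = rep(c("A", "B"), each = 10), count = 5L))
  cfg <- analysis_config(n_hub_genes = 4, n_hub_metabolites = 3)
  hubs <- select_hub_sets(deg, cfg)
  # all-equal degrees: first ids lexicographically
  expect_equal(hubs$A$hub_genes, c("g01", "g02", "g03", "g04"))
  expect_equal(hubs$B$hub_metabolites, c("m01", "m02", "m03"))
  # a high-degree entity displaces the ties
  deg$count[deg$kind == "gene" & deg$id == "g20" & deg$cell_type == "A"] <- 99L
  hubs <- select_hub_sets(deg, cfg)
  expect_equal(hubs$A$hub_genes[1], "g20")
  expect_error(select_hub_sets(deg, analysis_config(n_hub_genes = 50,
                                                    n_hub_metabolites = 3)),
               "available")
})

test_that("specificity score is the excess over the mean of other cell types", {
  deg <- data.frame(kind = "gene", id = "g1", cell_type = c("A", "B", "C"),
                    count = c(10L, 1L, 1L))
  s <- specificity_scores(rbind(deg,
    data.frame(kind = "metabolite", id = "m1", cell_type = c("A", "B", "C"),
               count = c(3L, 3L, 3L))))
  expect_equal(s$score[s$id == "g1" & s$cell_type == "A"], 9)
  expect_equal(s$score[s$id == "g1" & s$cell_type == "B"], 1 - 11 / 2)
  expect_equal(s$score[s$id == "m1"], rep(0, 3))
  # shift invariance: adding a constant to every count leaves scores unchanged
  shifted <- deg; shifted$count <- shifted$count + 7L
  expect_equal(specificity_scores(shifted)$score, specificity_scores(deg)$score)
})

test_that("pan ranking uses geometric means with min-rank then id tie-breaks", {
  deg <- data.frame(kind = "gene",
                    id = rep(c("A", "B", "C"), each = 2),
                    cell_type = rep(c("x", "y"), 3),
                    count = c(100L, 1L, 50L, 50L, 2L, 2L))
  # ranks: ct x -> A=1,B=2,C=3 ; ct y -> B=1,C=2... wait counts y: A=1,B=50,C=2
  # y ranks: B=1, C=2, A=3. gm: A=sqrt(3), B=sqrt(2), C=sqrt(6)
  out <- pan_celltype_ranks(deg, 3, "gene")
  expect_equal(out$id, c("B", "A", "C"))
  expect_equal(out$gm_rank, c(sqrt(2), sqrt(3), sqrt(6)))
  # entity ranked 1 everywhere gets combined rank 1
  top <- data.frame(kind = "gene", id = rep(c("A", "B"), each = 2),
                    cell_type = rep(c("x", "y"), 2), count = c(9L, 9L, 1L, 1L))
  expect_equal(pan_celltype_ranks(top, 1, "gene")$gm_rank, 1)
  # gm tie: A ranks (1,4), B ranks (2,2) -> both gm 2; A wins on min rank
  tie <- data.frame(kind = "gene", id = rep(c("A", "B", "C", "D"), each = 2),
                    cell_type = rep(c("x", "y"), 4),
                    count = c(40L, 10L, 30L, 30L, 20L, 40L, 10L, 20L))
  ranks_x <- rank(-c(40, 30, 20, 10)); ranks_y <- rank(-c(10, 30, 40, 20))
  gm <- sqrt(ranks_x * ranks_y)
  expect_equal(gm[1], gm[2])
  out <- pan_celltype_ranks(tie, 4, "gene")
  expect_equal(out$id, c("C", "A", "B", "D"))
  # permuting the cell-type axis changes nothing
  perm <- tie; perm$cell_type <- ifelse(perm$cell_type == "x", "y", "x")
  expect_equal(pan_celltype_ranks(perm, 4, "gene"), out)
})

test_that("bipartite density counts realized edges over possible pairs", {
  genes <- c("g1", "g2"); mets <- c("m1", "m2")
  all_edges <- expand.grid(gene = genes, metabolite = mets, cell_type = "A",
                           stringsAsFactors = FALSE)
  full <- full_map_from_edges(all_edges, genes, mets, "A")
  expect_equal(bipartite_density(full, genes, mets, "A"), 1)
  none <- full_map_from_edges(all_edges[0, ], genes, mets, "A")
  expect_equal(bipartite_density(none, genes, mets, "A"), 0)
  half <- full_map_from_edges(all_edges[1:2, ], genes, mets, "A")
  expect_equal(bipartite_density(half, genes, mets, "A"), 0.5)
  expect_error(bipartite_density(full, character(0), mets, "A"), "empty")
})

test_that("density permutation p-value hits its trivial bounds", {
  genes <- sprintf("g%02d", 1:12); mets <- sprintf("m%02d", 1:8)
  hub_g <- genes[1:3]; hub_m <- mets[1:2]
  # observed density 1, nothing can beat it strictly
  edges <- expand.grid(gene = hub_g, metabolite = hub_m, cell_type = "A",
                       stringsAsFactors = FALSE)
  map <- full_map_from_edges(edges, genes, mets, "A")
  r <- density_permutation_pvalue(map, hub_g, hub_m, "A", n_perm = 30, seed = 1)
  expect_equal(r$observed, 1)
  expect_equal(r$p, 0)
  # observed 0 while every non-hub pair is an edge -> p = 1
  non_edges <- expand.grid(gene = genes[4:12], metabolite = mets[3:8],
                           cell_type = "A", stringsAsFactors = FALSE)
  map0 <- full_map_from_edges(non_edges, genes, mets, "A")
  r0 <- density_permutation_pvalue(map0, hub_g, hub_m, "A", n_perm = 30, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)
  expect_error(density_permutation_pvalue(map, genes[1:7], hub_m, "A",
                                          n_perm = 10, seed = 1),
               "non-hub")
})

test_that("hub sharing null is the binomial pmf", {
  pmf <- hub_sharing_null_pmf(17, 0.05)
  expect_equal(pmf[1], 0.95^17)
  expect_equal(pmf[1], 0.4181, tolerance = 1e-4)
  expect_equal(sum(pmf), 1)
  expect_equal(hub_sharing_null_pmf(1, 0.3), c(0.7, 0.3))
  counts <- hub_sharing_counts(list(A = list(hub_genes = c("g1", "g2"),
                                             hub_metabolites = "m1"),
                                    B = list(hub_genes = "g1",
                                             hub_metabolites = "m2")))
  expect_equal(counts[["g1"]], 2L)
  expect_equal(counts[["g2"]], 1L)
})

test_that("hub statistics are equivariant under entity relabeling", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:15); mets <- sprintf("m%02d", 1:8); cts <- c("A", "B")
  grid <- expand.grid(gene = genes, metabolite = mets, cell_type = cts,
                      stringsAsFactors = FALSE)
  grid$p <- runif(nrow(grid))
  map <- make_map(grid, genes, mets, cts, alpha = 0.2)
  deg <- compute_degrees(map)
  # relabel genes by a fixed permutation
  perm <- setNames(sprintf("z%02d", sample(15)), genes)
  grid2 <- grid; grid2$gene <- unname(perm[grid2$gene])
  map2 <- make_map(grid2, unname(perm[genes]), mets, cts, alpha = 0.2)
  deg2 <- compute_degrees(map2)
  m1 <- covomics:::degree_matrix(deg, "gene")
  m2 <- covomics:::degree_matrix(deg2, "gene")
  expect_equal(m2[perm[rownames(m1)], ], m1, ignore_attr = TRUE)
})
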