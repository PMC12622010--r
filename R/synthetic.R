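feature_names <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

r_dirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  # guard against all-zero rows for tiny shapes
  g[g == 0] <- .Machine$double.xmin
  g / rowSums(g)
}

#' Generate a synthetic multi-omics cohort with planted structure
#'
#' Draws a cohort with the statistical structure the covariation analysis
#' assumes. Metabolite abundances are log-normal per patient (right-skewed,
#' like LC-MS peak areas, so the upper-quartile discretization is
#' non-degenerate); baseline pseudo-bulk expression is Gaussian noise; cell
#' type proportions follow a Dirichlet draw around the configured means; KL
#' grades, site and sex labels are sampled per patient.
#'
#' Planted structure, recorded in the returned truth tables:
#' * **pairs** — for each planted (gene, metabolite, cell type), patients in
#'   the metabolite's top-quartile group have the gene's mean shifted by
#'   `±effect_size * noise_sd` in that cell type only (sign drawn so that a
#'   `negative_fraction` share has the gene lower in the high-abundance
#'   group);
#' * **hubs** — each planted hub gene (metabolite) receives `hub_fanout`
#'   planted partners in one cell type;
#' * **pathways** — a `pathway_cover_fraction` share of planted pairs is
#'   assigned to a synthetic pathway whose gene and metabolite memberships
#'   are emitted as annotation tables;
#' * **severity** — `n_kl_metabolites` metabolites are shifted by
#'   `kl_effect` (log scale) in the target KL grade, and optionally
#'   `n_kl_genes` genes are shifted by `kl_gene_effect * noise_sd` in one
#'   cell type for target-grade patients.
#'
#' Each sub-draw uses its own seed stream derived from the master seed (see
#' [derive_seed()]), so enabling one planted feature never perturbs the
#' others.
#'
#' @param sim A [sim_config()].
#' @return List with `cohort` (an [omics_cohort()], unpreprocessed), `truth`
#'   (list of `planted_pairs`, `planted_hub_genes`, `planted_hub_metabolites`,
#'   `planted_pathway_pairs`, `kl_metabolites`, `kl_genes` data.frames) and
#'   `pathways` (list `gene_sets`, `metabolite_membership`).
#' @export
generate_cohort <- function(sim = sim_config()) {
  stopifnot(inherits(sim, "sim_config"))
  n <- sim$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  genes <- feature_names("G", sim$n_genes)
  mets <- feature_names("M", sim$n_metabolites)
  cts <- sim$celltype_names

  set.seed(derive_seed(sim$seed, "metadata"))
  metadata <- data.frame(
    patient_id = patients,
    site = sprintf("site%d", sample.int(sim$n_sites, n, replace = TRUE)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    kl_grade = sample(c(2L, 3L, 4L), n, replace = TRUE, prob = sim$kl_probs))

  set.seed(derive_seed(sim$seed, "proportions"))
  alpha <- sim$proportion_means * sim$proportion_concentration
  proportions <- r_dirichlet(n, alpha)
  dimnames(proportions) <- list(patients, cts)

  # metabolites: log-normal, severity shifts applied on the log scale
  set.seed(derive_seed(sim$seed, "metabolites"))
  logab <- matrix(stats::rnorm(n * sim$n_metabolites), n, sim$n_metabolites,
                  dimnames = list(patients, mets))
  kl_metabolites <- data.frame(metabolite = character(), target_grade = integer(),
                               direction = integer())
  if (sim$n_kl_metabolites > 0L) {
    if (sim$n_kl_metabolites > sim$n_metabolites)
      stopf("n_kl_metabolites exceeds available metabolites")
    set.seed(derive_seed(sim$seed, "kl_metabolites"))
    km <- sample_ids(mets, sim$n_kl_metabolites)
    dirs <- sample(c(1L, -1L), sim$n_kl_metabolites, replace = TRUE)
    in_grade <- metadata$kl_grade == sim$kl_target
    for (i in seq_along(km))
      logab[in_grade, km[i]] <- logab[in_grade, km[i]] + dirs[i] * sim$kl_effect
    kl_metabolites <- data.frame(metabolite = km, target_grade = sim$kl_target,
                                 direction = dirs)
  }
  # baseline expression noise per cell type
  pseudobulk <- vector("list", length(cts))
  names(pseudobulk) <- cts
  for (ct in cts) {
    set.seed(derive_seed(sim$seed, paste0("expr:", ct)))
    pseudobulk[[ct]] <- matrix(stats::rnorm(n * sim$n_genes, 0, sim$noise_sd),
                               n, sim$n_genes, dimnames = list(patients, genes))
  }

  # planted pairs: hubs consume hub_fanout partners each, then free pairs
  set.seed(derive_seed(sim$seed, "planting"))
  planted <- list()
  used_hub_genes <- character(0); used_hub_mets <- character(0)
  hub_partner_mets <- character(0)
  if (sim$n_planted_hub_genes > 0L) {
    hub_g <- sample_ids(genes, sim$n_planted_hub_genes)
    used_hub_genes <- hub_g
    avail <- setdiff(mets, kl_metabolites$metabolite)
    for (g in hub_g) {
      ct <- sample_ids(cts, 1L)
      if (length(avail) < sim$hub_fanout)
        stopf("requested planted entities exceed available ids")
      partners <- sample_ids(avail, sim$hub_fanout)
      avail <- setdiff(avail, partners)
      hub_partner_mets <- c(hub_partner_mets, partners)
      planted[[length(planted) + 1L]] <- data.frame(
        gene = g, metabolite = partners, cell_type = ct, kind = "hub_gene")
    }
  }
  if (sim$n_planted_hub_metabolites > 0L) {
    avail_m <- setdiff(mets, c(hub_partner_mets, kl_metabolites$metabolite))
    if (length(avail_m) < sim$n_planted_hub_metabolites)
      stopf("requested planted entities exceed available ids")
    hub_m <- sample_ids(avail_m, sim$n_planted_hub_metabolites)
    used_hub_mets <- hub_m
    for (m in hub_m) {
      ct <- sample_ids(cts, 1L)
      partners <- sample_ids(setdiff(genes, used_hub_genes), sim$hub_fanout)
      planted[[length(planted) + 1L]] <- data.frame(
        gene = partners, metabolite = m, cell_type = ct, kind = "hub_metabolite")
    }
  }
  if (sim$n_planted_pairs > 0L) {
    free_g <- setdiff(genes, used_hub_genes)
    free_m <- setdiff(mets, c(used_hub_mets, hub_partner_mets))
    if (!length(free_g) || !length(free_m))
      stopf("requested planted entities exceed available ids")
    planted[[length(planted) + 1L]] <- data.frame(
      gene = sample(free_g, sim$n_planted_pairs, replace = TRUE),
      metabolite = sample(free_m, sim$n_planted_pairs, replace = TRUE),
      cell_type = sample(cts, sim$n_planted_pairs, replace = TRUE),
      kind = "pair")
  }
  planted_pairs <- if (length(planted)) {
    pp <- do.call(rbind, planted)
    pp <- pp[!duplicated(pp[, c("gene", "metabolite", "cell_type")]), ]
    pp$delta <- sim$effect_size *
      ifelse(stats::runif(nrow(pp)) < sim$negative_fraction, -1, 1)
    pp
  } else {
    data.frame(gene = character(), metabolite = character(),
               cell_type = character(), kind = character(), delta = numeric())
  }

  # Hub-gene partners are realized as metabolites correlated with the hub
  # gene's expression rather than as repeated mean shifts of the gene:
  # stacking hub_fanout shifts on one gene would inflate its variance and
  # dilute every per-partner effect after standardization. The correlation
  # is chosen so the induced mean expression difference between the
  # metabolite's top-quartile and bottom group matches effect_size gene-sd
  # units (E[z | top quartile] - E[z | rest] = 1.6949 for a standard normal).
  is_hub_gene <- planted_pairs$kind == "hub_gene"
  if (any(is_hub_gene)) {
    r_cor <- min(0.999, sim$effect_size / 1.6949)
    for (i in which(is_hub_gene)) {
      g <- planted_pairs$gene[i]; m <- planted_pairs$metabolite[i]
      ct <- planted_pairs$cell_type[i]
      z_g <- pseudobulk[[ct]][, g] / sim$noise_sd
      sgn <- sign(planted_pairs$delta[i])
      logab[, m] <- sgn * r_cor * z_g + sqrt(1 - r_cor^2) * stats::rnorm(n)
    }
  }
  metabolites <- exp(logab)

  # remaining planted effects act on the discretized grouping: the gene's
  # mean is shifted between the metabolite's high/low groups, in that cell
  # type only
  shift_rows <- which(!is_hub_gene)
  if (length(shift_rows)) {
    q <- 0.75
    thr <- apply(metabolites, 2L, stats::quantile, probs = q, type = 7,
                 names = FALSE)
    for (r in shift_rows) {
      m <- planted_pairs$metabolite[r]; g <- planted_pairs$gene[r]
      ct <- planted_pairs$cell_type[r]
      grp1 <- metabolites[, m] >= thr[[m]]
      pseudobulk[[ct]][grp1, g] <- pseudobulk[[ct]][grp1, g] +
        planted_pairs$delta[r] * sim$noise_sd
    }
  }

  # transcriptomic severity plant (one cell type)
  kl_genes <- data.frame(gene = character(), cell_type = character(),
                         target_grade = integer(), effect = numeric())
  if (sim$n_kl_genes > 0L) {
    ct <- sim$kl_gene_celltype %||% cts[1L]
    if (!ct %in% cts) stopf("kl_gene_celltype '%s' not a cell type", ct)
    set.seed(derive_seed(sim$seed, "kl_genes"))
    kg <- sample_ids(setdiff(genes, unique(planted_pairs$gene)), sim$n_kl_genes)
    in_grade <- metadata$kl_grade == sim$kl_target
    for (g in kg)
      pseudobulk[[ct]][in_grade, g] <- pseudobulk[[ct]][in_grade, g] +
        sim$kl_gene_effect * sim$noise_sd
    kl_genes <- data.frame(gene = kg, cell_type = ct,
                           target_grade = sim$kl_target,
                           effect = sim$kl_gene_effect)
  }

  # synthetic pathway annotations covering a fraction of planted pairs
  set.seed(derive_seed(sim$seed, "pathways"))
  pw_ids <- sprintf("PW%03d", seq_len(sim$pathway_count))
  gene_sets <- stats::setNames(
    lapply(pw_ids, function(p) sample_ids(genes, min(25L, sim$n_genes))), pw_ids)
  met_members <- stats::setNames(
    lapply(pw_ids, function(p) sample_ids(mets, min(15L, sim$n_metabolites))), pw_ids)
  planted_pathway_pairs <- planted_pairs[0, c("gene", "metabolite", "cell_type")]
  planted_pathway_pairs$pathway_id <- character(0)
  if (nrow(planted_pairs) && sim$pathway_cover_fraction > 0 && sim$pathway_count > 0L) {
    n_cov <- round(sim$pathway_cover_fraction * nrow(planted_pairs))
    if (n_cov > 0L) {
      cov_idx <- sample.int(nrow(planted_pairs), n_cov)
      pw_assign <- sample(pw_ids, n_cov, replace = TRUE)
      for (i in seq_len(n_cov)) {
        r <- cov_idx[i]; p <- pw_assign[i]
        gene_sets[[p]] <- union(gene_sets[[p]], planted_pairs$gene[r])
        met_members[[p]] <- union(met_members[[p]], planted_pairs$metabolite[r])
      }
      planted_pathway_pairs <- data.frame(
        gene = planted_pairs$gene[cov_idx],
        metabolite = planted_pairs$metabolite[cov_idx],
        cell_type = planted_pairs$cell_type[cov_idx],
        pathway_id = pw_assign)
    }
  }
  met_membership <- data.frame(
    pathway_id = rep(names(met_members), lengths(met_members)),
    metabolite_id = unlist(met_members, use.names = FALSE))

  cohort <- omics_cohort(pseudobulk, metabolites, proportions, metadata)
  truth <- list(
    planted_pairs = planted_pairs,
    planted_hub_genes = unique(planted_pairs[planted_pairs$kind == "hub_gene",
                                             c("gene", "cell_type")]),
    planted_hub_metabolites = unique(planted_pairs[planted_pairs$kind == "hub_metabolite",
                                                   c("metabolite", "cell_type")]),
    planted_pathway_pairs = planted_pathway_pairs,
    kl_metabolites = kl_metabolites,
    kl_genes = kl_genes)
  cov_log("INFO", "generate_cohort: %d patients, %d planted pairs", n,
          nrow(planted_pairs))
  list(cohort = cohort, truth = truth,
       pathways = list(gene_sets = gene_sets,
                       metabolite_membership = met_membership))
}

#' Generate a null cohort with no planted structure
#'
#' Identical to [generate_cohort()] with all planted counts set to zero, so
#' every gene-metabolite independence holds by construction. Used for type-I
#' error and permutation-calibration checks.
#'
#' @param sim A [sim_config()].
#' @return An [omics_cohort()].
#' @export
generate_null_cohort <- function(sim = sim_config()) {
  sim$n_planted_pairs <- 0L
  sim$n_planted_hub_genes <- 0L
  sim$n_planted_hub_metabolites <- 0L
  sim$n_kl_metabolites <- 0L
  sim$n_kl_genes <- 0L
  generate_cohort(sim)$cohort
}

#' Generate a cell-level expression matrix around a cohort's means
#'
#' Draws single cells per patient whose type frequencies follow the patient's
#' proportions (or exactly one cell per type when `balanced = TRUE`) and
#' whose expression is the patient/cell-type generating mean plus Gaussian
#' within-type noise of sd `sim$cell_noise_sd`. [pseudobulk_average()]
#' applied to the output recovers the generating means within sampling
#' error.
#'
#' @param sim A [sim_config()].
#' @param cells_per_patient Number of cells drawn per patient
#'   (>= `n_celltypes` recommended; types can be absent for some patients
#'   otherwise, yielding missing pseudo-bulk entries).
#' @param balanced If `TRUE`, allocate cells as evenly as possible across
#'   cell types instead of drawing from the proportions.
#' @return List with `cell_matrix` (cells x genes), `annotations`
#'   (data.frame `cell_id`, `patient_id`, `cell_type`) and `means` (the
#'   generating pseudo-bulk list).
#' @export
generate_cell_level <- function(sim = sim_config(), cells_per_patient = 100L,
                                balanced = FALSE) {
  gen <- generate_cohort(sim)
  cohort <- gen$cohort
  n_ct <- length(cohort$cell_types)
  set.seed(derive_seed(sim$seed, "cells"))
  ann <- list(); rows <- list()
  for (p in cohort$patient_ids) {
    types <- if (balanced) {
      rep(cohort$cell_types, length.out = cells_per_patient)
    } else {
      sample(cohort$cell_types, cells_per_patient, replace = TRUE,
             prob = cohort$proportions[p, ])
    }
    mu <- do.call(rbind, lapply(types, function(t) cohort$pseudobulk[[t]][p, ]))
    noise <- matrix(stats::rnorm(length(mu), 0, sim$cell_noise_sd), nrow(mu))
    rows[[p]] <- mu + noise
    ann[[p]] <- data.frame(patient_id = p, cell_type = types)
  }
  cell_matrix <- do.call(rbind, rows)
  annotations <- do.call(rbind, ann)
  annotations$cell_id <- sprintf("C%06d", seq_len(nrow(annotations)))
  rownames(cell_matrix) <- annotations$cell_id
  rownames(annotations) <- NULL
  list(cell_matrix = cell_matrix,
       annotations = annotations[, c("cell_id", "patient_id", "cell_type")],
       means = cohort$pseudobulk)
}

#' Evaluate recovery of planted structure
#'
#' Compares an association map (and optionally hub sets) computed on a
#' synthetic cohort against the truth tables that generated it.
#'
#' @param truth Truth list from [generate_cohort()].
#' @param map Association map computed on the same cohort.
#' @param hub_sets Optional [select_hub_sets()] output.
#' @param alpha Significance threshold (default the map's).
#' @return List with `tpr` (planted-pair true positive rate, `NA` when no
#'   pairs were planted), `fdp` (false discovery proportion among declared
#'   pairs), `n_declared`, and `hub_recovery` (fraction of planted hubs in
#'   their cell type's hub set, `NA` without hubs).
#' @export
evaluate_recovery <- function(truth, map, hub_sets = NULL, alpha = NULL) {
  alpha <- map_alpha(map, alpha)
  pp <- truth$planted_pairs
  key <- function(d) paste(d$gene, d$metabolite, d$cell_type, sep = "\r")
  bad <- !(pp$gene %in% attr(map, "genes")) |
    !(pp$metabolite %in% attr(map, "metabolites"))
  if (any(bad)) stopf("evaluate_recovery: truth ids absent from the map")
  declared <- map[map$p <= alpha, ]
  tpr <- if (nrow(pp)) mean(key(pp) %in% key(declared)) else NA_real_
  fdp <- if (nrow(declared)) mean(!(key(declared) %in% key(pp))) else NA_real_
  hub_recovery <- NA_real_
  if (!is.null(hub_sets)) {
    hits <- c(
      if (nrow(truth$planted_hub_genes))
        mapply(function(g, ct) g %in% hub_sets[[ct]]$hub_genes,
               truth$planted_hub_genes$gene, truth$planted_hub_genes$cell_type),
      if (nrow(truth$planted_hub_metabolites))
        mapply(function(m, ct) m %in% hub_sets[[ct]]$hub_metabolites,
               truth$planted_hub_metabolites$metabolite,
               truth$planted_hub_metabolites$cell_type))
    if (length(hits)) hub_recovery <- mean(hits)
  }
  list(tpr = tpr, fdp = fdp, n_declared = nrow(declared),
       hub_recovery = hub_recovery)
}

#' Write synthetic truth and pathway annotation files
#'
#' Emits `truth_*.tsv` tables, a GMT file of the synthetic pathway gene sets
#' and `pathway_metabolites.tsv`, alongside the cohort files of
#' [write_cohort()].
#'
#' @param gen Output of [generate_cohort()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(gen$cohort, dir)
  for (nm in names(gen$truth))
    data.table::fwrite(gen$truth[[nm]], file.path(dir, sprintf("truth_%s.tsv", nm)),
                       sep = "\t", quote = FALSE)
  write_gmt(gen$pathways$gene_sets, file.path(dir, "pathways.gmt"))
  data.table::fwrite(gen$pathways$metabolite_membership,
                     file.path(dir, "pathway_metabolites.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}
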