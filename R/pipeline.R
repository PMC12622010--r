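# Stage orchestration: each stage consumes the cohort (and earlier stage
# outputs) and returns plain data.frames ready for write_results().

hub_sets_table <- function(hub_sets) {
  do.call(rbind, lapply(names(hub_sets), function(ct) {
    rbind(data.frame(cell_type = ct, kind = "gene",
                     id = hub_sets[[ct]]$hub_genes),
          data.frame(cell_type = ct, kind = "metabolite",
                     id = hub_sets[[ct]]$hub_metabolites))
  }))
}

#' Run hub statistics on an association map
#'
#' Degrees, per-cell-type hub sets, specificity scores with top specific
#' hubs, pan-cell-type geometric-mean rankings, and the hub-interconnection
#' density permutation test per cell type.
#'
#' @param map An association map.
#' @param config An [analysis_config()].
#' @param density_test Run the permutation test (the slow part).
#' @return List of tables: `degrees`, `hubs_celltype`, `hubs_specific`,
#'   `hubs_pan`, `density_test`, plus the raw `hub_sets` list.
#' @export
run_hub_stage <- function(map, config = analysis_config(), density_test = TRUE) {
  degrees <- compute_degrees(map, config$assoc_alpha)
  hub_sets <- select_hub_sets(degrees, config)
  scores <- specificity_scores(degrees)
  specific <- rbind(
    cbind(top_specific_hubs(scores, config$n_specific_hubs, "gene")),
    cbind(top_specific_hubs(scores, config$n_specific_hubs, "metabolite")))
  pan <- rbind(
    data.frame(kind = "gene",
               pan_celltype_ranks(degrees, config$n_pan_hubs, "gene")),
    data.frame(kind = "metabolite",
               pan_celltype_ranks(degrees, config$n_pan_hubs, "metabolite")))
  dens <- NULL
  if (density_test) {
    dens <- do.call(rbind, lapply(names(hub_sets), function(ct) {
      r <- density_permutation_pvalue(map, hub_sets[[ct]]$hub_genes,
                                      hub_sets[[ct]]$hub_metabolites, ct,
                                      n_perm = config$n_density_perms,
                                      seed = config$seed,
                                      alpha = config$assoc_alpha)
      data.frame(cell_type = ct, observed_density = r$observed,
                 mean_perm_density = mean(r$perm_densities), p = r$p)
    }))
  }
  list(degrees = degrees, hubs_celltype = hub_sets_table(hub_sets),
       hubs_specific = specific, hubs_pan = pan, density_test = dens,
       hub_sets = hub_sets)
}

#' Run the metabolite-to-cell-type prediction stage
#'
#' Repeated random-forest prediction of each metabolite's abundance group
#' from every cell type's pseudo-bulk transcriptome, plus the
#' proportion-confounder baseline, followed by the linking rules.
#'
#' @param cohort A preprocessed [omics_cohort()].
#' @param config An [analysis_config()].
#' @param metabolites Metabolite ids to process (default: all; the full
#'   protocol is expensive, so pipelines may restrict it).
#' @return List with `predictions` (table) and `links` (table).
#' @export
run_predict_stage <- function(cohort, config = analysis_config(),
                              metabolites = colnames(cohort$metabolites)) {
  records <- list()
  for (m in metabolites) {
    grp <- discretize_metabolite(cohort$metabolites[, m],
                                 q = config$metabolite_split_quantile,
                                 min_group = config$min_group, id = m)
    if (is.null(grp)) next
    for (ct in cohort$cell_types) {
      X <- cohort$pseudobulk[[ct]]
      ok <- stats::complete.cases(X)
      sub_grp <- grp
      sub_grp$group <- grp$group[ok]
      seed <- derive_seed(config$seed, paste0("predict:", m, ":", ct))
      records[[length(records) + 1L]] <-
        repeat_metabolite_prediction(X[ok, , drop = FALSE], sub_grp, config,
                                     seed = seed, cell_type = ct)
    }
    if (!is.null(cohort$proportions)) {
      seed <- derive_seed(config$seed, paste0("predict:", m, ":proportions"))
      records[[length(records) + 1L]] <-
        proportion_baseline(cohort$proportions, grp, config, seed = seed)
    }
  }
  predictions <- prediction_table(records)
  links <- if (!is.null(predictions) && nrow(predictions))
    link_metabolites_to_celltypes(predictions, config) else NULL
  list(predictions = predictions, links = links)
}

#' Run the severity stage
#'
#' Hub-gene random-forest severity classifiers per cell type and target
#' grade (2 and 4), plus the metabolite-severity proportion tests.
#'
#' @param cohort A preprocessed [omics_cohort()].
#' @param hub_sets Per-cell-type hub sets from [run_hub_stage()].
#' @param config An [analysis_config()].
#' @param targets KL target grades to test.
#' @return List with `severity` (table), `met_kl` (table) and `results`
#'   (raw `severity_result` objects).
#' @export
run_severity_stage <- function(cohort, hub_sets, config = analysis_config(),
                               targets = c(2L, 4L)) {
  results <- list(); rows <- list()
  for (target in targets) {
    labels <- kl_binarize(cohort$metadata$kl_grade, target)
    if (min(table(labels)) < 10L) {
      cov_log("WARNING", "severity: target %d skipped (class < 10 patients)", target)
      next
    }
    for (ct in cohort$cell_types) {
      X <- cohort$pseudobulk[[ct]]
      ok <- stats::complete.cases(X)
      if (min(table(labels[ok])) < 10L) next
      seed <- derive_seed(config$seed, paste0("severity:", ct, ":", target))
      r <- severity_classification(X[ok, , drop = FALSE],
                                   hub_sets[[ct]]$hub_genes, labels[ok],
                                   config, seed = seed, cell_type = ct,
                                   target = target)
      results[[paste(ct, target)]] <- r
      rows[[paste(ct, target)]] <- data.frame(
        cell_type = ct, target = target, auroc = r$auroc,
        median_run_accuracy = r$median_run_accuracy)
    }
  }
  met_kl <- do.call(rbind, lapply(targets, function(t)
    metabolite_kl_table(cohort, t, config)))
  list(severity = do.call(rbind, rows), met_kl = met_kl, results = results)
}

#' Run the full pipeline on a cohort directory
#'
#' Reads the cohort, preprocesses it, builds the association map and hub
#' statistics, the pathway-filtered high-confidence map (when annotation
#' files are present), hub-gene set enrichment, the metabolite-cell-type
#' prediction stage and the severity stage, and writes every table plus a
#' `summary.json` (which echoes the effective configuration) to `out_dir`.
#'
#' @param in_dir Directory holding the cohort (and optional `pathways.gmt`,
#'   `pathway_metabolites.tsv`).
#' @param out_dir Output directory.
#' @param config An [analysis_config()].
#' @param predict_metabolites Metabolites to run through the prediction
#'   stage (`NULL` = all; an integer = the first n testable ones).
#' @param stages Character vector of stages to run.
#' @return Invisibly, the list of all stage outputs.
#' @export
run_pipeline <- function(in_dir, out_dir, config = analysis_config(),
                         predict_metabolites = NULL,
                         stages = c("associate", "hubs", "highconf", "enrich",
                                    "predict", "severity")) {
  t0 <- Sys.time()
  cohort <- read_cohort(in_dir, config)
  cohort <- preprocess_cohort(cohort, config)
  tables <- list()
  summary <- list(config = unclass(config),
                  n_patients = length(cohort$patient_ids),
                  n_celltypes = length(cohort$cell_types))
  map <- NULL; hubs <- NULL
  if ("associate" %in% stages) {
    map <- build_association_map(cohort, config)
    tables$associations <- map
    summary$n_associations <- sum(map$p <= config$assoc_alpha)
    summary$assoc_fraction <- mean(map$p <= config$assoc_alpha)
    cov_log("INFO", "associate: %d significant pairs", summary$n_associations)
  }
  if ("hubs" %in% stages && !is.null(map)) {
    hubs <- run_hub_stage(map, config)
    tables$degrees <- hubs$degrees
    tables$hubs_celltype <- hubs$hubs_celltype
    tables$hubs_specific <- hubs$hubs_specific
    tables$hubs_pan <- hubs$hubs_pan
    tables$density_test <- hubs$density_test
  }
  gmt_path <- file.path(in_dir, "pathways.gmt")
  pm_path <- file.path(in_dir, "pathway_metabolites.tsv")
  if ("highconf" %in% stages && !is.null(map) &&
      file.exists(gmt_path) && file.exists(pm_path)) {
    gene_sets <- read_gmt(gmt_path)
    membership <- read_pathway_metabolites(pm_path)
    hc <- build_high_confidence_map(map, gene_sets, membership,
                                    config$assoc_alpha)
    tables$highconf <- hc
    tables$highconf_metabolites <- rank_by_frequency(hc, "metabolite",
                                                     config$count_distinct_pairs)
    tables$highconf_pathways <- rank_by_frequency(hc, "pathway",
                                                  config$count_distinct_pairs)
    tables$highconf_genes <- rank_by_frequency(hc, "gene",
                                               config$count_distinct_pairs)
    summary$n_highconf <- nrow(hc)
    summary$fraction_negative_direction <- direction_of_effect_summary(hc)
    if ("enrich" %in% stages && !is.null(hubs)) {
      universe <- cohort$selected$hvg_genes
      enr <- do.call(rbind, lapply(names(hubs$hub_sets), function(ct) {
        e <- set_enrichment(hubs$hub_sets[[ct]]$hub_genes, gene_sets, universe)
        cbind(cell_type = ct, e)
      }))
      tables$enrichment <- enr
    }
  }
  if ("predict" %in% stages) {
    mets <- colnames(cohort$metabolites)
    if (is.numeric(predict_metabolites)) mets <- utils::head(mets, predict_metabolites)
    else if (is.character(predict_metabolites)) mets <- predict_metabolites
    pred <- run_predict_stage(cohort, config, mets)
    tables$predictions <- pred$predictions
    tables$links <- pred$links
    if (!is.null(pred$links)) {
      summary$n_linked_metabolites <- sum(pred$links$n_links > 0)
      summary$n_pan_metabolites <- sum(pred$links$pan)
    }
  }
  if ("severity" %in% stages && !is.null(hubs)) {
    sev <- run_severity_stage(cohort, hubs$hub_sets, config)
    tables$severity <- sev$severity
    tables$met_kl <- sev$met_kl
    if (!is.null(sev$severity)) {
      for (t in unique(sev$severity$target)) {
        s <- sev$severity[sev$severity$target == t, ]
        summary[[sprintf("best_auroc_kl%d", t)]] <- max(s$auroc)
      }
    }
  }
  tables <- Filter(Negate(is.null), tables)
  write_results(tables, out_dir, summary)
  cov_log("INFO", "pipeline finished in %.1fs",
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(c(tables, list(summary = summary)))
}
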