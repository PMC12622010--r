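#' Analysis configuration
#'
#' Collects every tunable constant of the covariation pipeline. Defaults are
#' the study's operating point: 2000 highly variable genes, 1000 highly
#' variable metabolites, outlier saturation at the 95th quantile, an upper
#' (75th-percentile) quartile split of each metabolite, a nominal association
#' threshold of p <= 0.005, 50 hub metabolites and 100 hub genes per cell
#' type (the top 5%), 10 cell-type-specific and 50 pan-cell-type hubs, 200
#' density permutations, 100 random-forest repeats for metabolite attribution
#' and 30 for severity, 70/30 train/test splits, a 0.65 balanced-accuracy
#' linking threshold with pan links at four or more cell types, and a 0.6
#' accuracy cutoff for the predictable-metabolite overlap filter.
#'
#' @param n_hvg_genes Number of highly variable genes retained.
#' @param n_hvg_metabolites Number of highly variable metabolites retained.
#' @param saturation_quantile Upper quantile at which features are saturated.
#' @param metabolite_split_quantile Quantile splitting each metabolite into
#'   high (Group 1) vs low (Group 2) abundance patients.
#' @param assoc_alpha Nominal p-value threshold declaring a gene-metabolite
#'   pair associated.
#' @param de_alpha Significance level for within-training-set differential
#'   expression feature selection (and for BH-adjusted reporting).
#' @param n_hub_metabolites,n_hub_genes Hub set sizes per cell type.
#' @param n_specific_hubs Cell-type-specific hubs reported per cell type.
#' @param n_pan_hubs Pan-cell-type hubs reported.
#' @param n_density_perms Permutations for the hub interconnection density test.
#' @param rf_repeats_metabolite,rf_repeats_severity Train/test repeats for the
#'   metabolite-attribution and severity classifiers.
#' @param train_fraction Fraction of patients assigned to the training set.
#' @param link_accuracy_threshold Reported balanced accuracy required to link
#'   a metabolite to a cell type.
#' @param pan_link_min_celltypes Linked cell types required for a pan flag.
#' @param overlap_accuracy_threshold Accuracy cutoff used when intersecting
#'   transcriptome-predictable metabolites with severity-associated ones.
#' @param ci_n_eff Effective n in the accuracy standard error
#'   `sqrt(a(1-a)/n_eff)`: `"repeats"` (default, the number of repeats),
#'   `"test_size"`, `"one"`, or a positive number.
#' @param min_group Minimum patients on each side of the quartile split for a
#'   metabolite to be testable.
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @param rf_tune_candidates,rf_cv_folds Randomized hyperparameter search
#'   budget: candidates drawn from the tree/depth/leaf grid and CV folds.
#' @param specific_link_margin A cell-type-specific link requires every other
#'   cell type's reported accuracy below `link_accuracy_threshold - margin`.
#' @param count_distinct_pairs If `TRUE`, high-confidence frequency rankings
#'   count distinct (gene, metabolite, cell type) triples instead of
#'   (triple, pathway) quadruplets.
#' @param seed Master seed for all stochastic stages.
#' @return An object of class `analysis_config` (a validated named list).
#' @export
analysis_config <- function(n_hvg_genes = 2000L,
                            n_hvg_metabolites = 1000L,
                            saturation_quantile = 0.95,
                            metabolite_split_quantile = 0.75,
                            assoc_alpha = 0.005,
                            de_alpha = 0.05,
                            n_hub_metabolites = 50L,
                            n_hub_genes = 100L,
                            n_specific_hubs = 10L,
                            n_pan_hubs = 50L,
                            n_density_perms = 200L,
                            rf_repeats_metabolite = 100L,
                            rf_repeats_severity = 30L,
                            train_fraction = 0.70,
                            link_accuracy_threshold = 0.65,
                            pan_link_min_celltypes = 4L,
                            overlap_accuracy_threshold = 0.6,
                            ci_n_eff = "repeats",
                            min_group = 5L,
                            welch = FALSE,
                            rf_tune_candidates = 20L,
                            rf_cv_folds = 5L,
                            specific_link_margin = 0,
                            count_distinct_pairs = FALSE,
                            seed = 1L) {
  cfg <- list(
    n_hvg_genes = as.integer(n_hvg_genes),
    n_hvg_metabolites = as.integer(n_hvg_metabolites),
    saturation_quantile = saturation_quantile,
    metabolite_split_quantile = metabolite_split_quantile,
    assoc_alpha = assoc_alpha,
    de_alpha = de_alpha,
    n_hub_metabolites = as.integer(n_hub_metabolites),
    n_hub_genes = as.integer(n_hub_genes),
    n_specific_hubs = as.integer(n_specific_hubs),
    n_pan_hubs = as.integer(n_pan_hubs),
    n_density_perms = as.integer(n_density_perms),
    rf_repeats_metabolite = as.integer(rf_repeats_metabolite),
    rf_repeats_severity = as.integer(rf_repeats_severity),
    train_fraction = train_fraction,
    link_accuracy_threshold = link_accuracy_threshold,
    pan_link_min_celltypes = as.integer(pan_link_min_celltypes),
    overlap_accuracy_threshold = overlap_accuracy_threshold,
    ci_n_eff = ci_n_eff,
    min_group = as.integer(min_group),
    welch = isTRUE(welch),
    rf_tune_candidates = as.integer(rf_tune_candidates),
    rf_cv_folds = as.integer(rf_cv_folds),
    specific_link_margin = specific_link_margin,
    count_distinct_pairs = isTRUE(count_distinct_pairs),
    seed = as.integer(seed)
  )
  validate_analysis_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_analysis_config <- function(cfg) {
  fracs <- c("saturation_quantile", "metabolite_split_quantile", "assoc_alpha",
             "de_alpha", "train_fraction", "link_accuracy_threshold",
             "overlap_accuracy_threshold")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stopf("config field '%s' must be a fraction in (0, 1), got %s", f, format(v))
  }
  counts <- c("n_hvg_genes", "n_hvg_metabolites", "n_hub_metabolites",
              "n_hub_genes", "n_specific_hubs", "n_pan_hubs", "n_density_perms",
              "rf_repeats_metabolite", "rf_repeats_severity",
              "pan_link_min_celltypes", "min_group", "rf_tune_candidates",
              "rf_cv_folds")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      stopf("config field '%s' must be a positive count", f)
  }
  if (cfg$assoc_alpha >= cfg$de_alpha)
    stopf("assoc_alpha (%g) must be smaller than de_alpha (%g)",
          cfg$assoc_alpha, cfg$de_alpha)
  ne <- cfg$ci_n_eff
  ok <- (is.character(ne) && ne %in% c("repeats", "test_size", "one")) ||
    (is.numeric(ne) && length(ne) == 1L && ne >= 1)
  if (!ok) stopf("ci_n_eff must be 'repeats', 'test_size', 'one' or a count")
  invisible(cfg)
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Fields present in the file override the defaults of [analysis_config()];
#' fields supplied through `...` (e.g. from command-line flags) override both.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   defaults only.
#' @param ... Named overrides taking highest precedence.
#' @return An `analysis_config`.
#' @export
read_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    unknown <- setdiff(names(vals), names(formals(analysis_config)))
    if (length(unknown))
      stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

default_celltype_names <- function(n) {
  base <- c("NaiveCD4T", "CD8T", "CD14Mono", "MatureB", "NK", "CD16Mono",
            "Macrophage", "PlasmaB", "PreB", "ProB", "TransB", "cDC", "pDC",
            "MonoProgenitor", "HSPC", "Megakaryocyte", "MSC")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("CellType%02d", seq_len(n - length(base))))
}

# 17-vector of mean proportions: lymphocyte/monocyte dominated, with the three
# numeric anchors 1.8% HSPC, 0.67% megakaryocytes and 0.12% MSC.
default_proportion_means <- function(n) {
  base <- c(NaiveCD4T = 0.2261, CD8T = 0.18, CD14Mono = 0.15, MatureB = 0.12,
            NK = 0.11, CD16Mono = 0.05, Macrophage = 0.04, PlasmaB = 0.02,
            PreB = 0.02, ProB = 0.015, TransB = 0.015, cDC = 0.01, pDC = 0.008,
            MonoProgenitor = 0.01, HSPC = 0.018, Megakaryocyte = 0.0067,
            MSC = 0.0012)
  if (n == length(base)) return(unname(base))
  # non-default cell type counts: renormalize a truncated/extended vector
  v <- if (n <= length(base)) base[seq_len(n)] else
    c(base, rep(0.01, n - length(base)))
  unname(v / sum(v))
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the study cohort: 119 patients from 5 sites, 17 cell
#' types with highly skewed proportions (means include 1.8% HSPC, 0.67%
#' megakaryocytes and 0.12% MSC), 2000 genes, 1000 metabolites, and
#' Kellgren/Lawrence severity grades in \{2, 3, 4\}.
#'
#' @param n_patients,n_celltypes,n_genes,n_metabolites Cohort dimensions.
#' @param celltype_names Cell type labels (defaults to a bone-marrow panel).
#' @param proportion_means Mean cell type proportions (sums to 1).
#' @param proportion_concentration Dirichlet concentration controlling
#'   patient-to-patient spread of proportions.
#' @param n_planted_pairs Gene-metabolite-cell-type associations planted in
#'   addition to hub fan-outs.
#' @param effect_size Standardized mean shift delta applied to a planted
#'   gene between the metabolite's high and low abundance groups.
#' @param n_planted_hub_genes,n_planted_hub_metabolites Planted hubs.
#' @param hub_fanout Planted partners per hub.
#' @param pathway_count Number of synthetic metabolic pathways emitted.
#' @param pathway_cover_fraction Fraction of planted pairs made pathway
#'   co-members (and hence recoverable in the high-confidence map).
#' @param negative_fraction Fraction of planted pairs with the gene expressed
#'   lower in the high-metabolite group (direction -1).
#' @param kl_probs Probabilities of KL grades 2, 3, 4.
#' @param n_kl_metabolites Metabolites with a planted severity shift.
#' @param kl_effect Log-scale abundance shift of severity metabolites in the
#'   target grade.
#' @param kl_target Target KL grade of planted severity signals (2 or 4).
#' @param n_kl_genes,kl_gene_effect,kl_gene_celltype Transcriptomic severity
#'   plant: `n_kl_genes` genes shifted by `kl_gene_effect` (in units of
#'   `noise_sd`) in the target grade, in cell type `kl_gene_celltype` only
#'   (`NULL` disables the plant).
#' @param n_sites Number of collection sites.
#' @param noise_sd Standard deviation of baseline pseudo-bulk expression.
#' @param cell_noise_sd Within-cell-type noise used by [generate_cell_level()].
#' @param seed Master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 119L,
                       n_celltypes = 17L,
                       n_genes = 2000L,
                       n_metabolites = 1000L,
                       celltype_names = default_celltype_names(n_celltypes),
                       proportion_means = default_proportion_means(n_celltypes),
                       proportion_concentration = 300,
                       n_planted_pairs = 200L,
                       effect_size = 2,
                       n_planted_hub_genes = 5L,
                       n_planted_hub_metabolites = 5L,
                       hub_fanout = 60L,
                       pathway_count = 20L,
                       pathway_cover_fraction = 0.5,
                       negative_fraction = 0.72,
                       kl_probs = c(0.35, 0.40, 0.25),
                       n_kl_metabolites = 20L,
                       kl_effect = 1,
                       kl_target = 4L,
                       n_kl_genes = 0L,
                       kl_gene_effect = 1.5,
                       kl_gene_celltype = NULL,
                       n_sites = 5L,
                       noise_sd = 1,
                       cell_noise_sd = 1,
                       seed = 1L) {
  sim <- list(
    n_patients = as.integer(n_patients),
    n_celltypes = as.integer(n_celltypes),
    n_genes = as.integer(n_genes),
    n_metabolites = as.integer(n_metabolites),
    celltype_names = as.character(celltype_names),
    proportion_means = as.numeric(proportion_means),
    proportion_concentration = proportion_concentration,
    n_planted_pairs = as.integer(n_planted_pairs),
    effect_size = effect_size,
    n_planted_hub_genes = as.integer(n_planted_hub_genes),
    n_planted_hub_metabolites = as.integer(n_planted_hub_metabolites),
    hub_fanout = as.integer(hub_fanout),
    pathway_count = as.integer(pathway_count),
    pathway_cover_fraction = pathway_cover_fraction,
    negative_fraction = negative_fraction,
    kl_probs = as.numeric(kl_probs),
    n_kl_metabolites = as.integer(n_kl_metabolites),
    kl_effect = kl_effect,
    kl_target = as.integer(kl_target),
    n_kl_genes = as.integer(n_kl_genes),
    kl_gene_effect = kl_gene_effect,
    kl_gene_celltype = kl_gene_celltype,
    n_sites = as.integer(n_sites),
    noise_sd = noise_sd,
    cell_noise_sd = cell_noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(sim)
  structure(sim, class = "sim_config")
}

validate_sim_config <- function(sim) {
  with(sim, {
    if (length(celltype_names) != n_celltypes)
      stopf("celltype_names must have length n_celltypes (%d)", n_celltypes)
    if (length(proportion_means) != n_celltypes)
      stopf("proportion_means must have length n_celltypes (%d)", n_celltypes)
    if (abs(sum(proportion_means) - 1) > 1e-8)
      stopf("proportion_means must sum to 1 (got %g)", sum(proportion_means))
    if (any(proportion_means <= 0)) stopf("proportion_means must be positive")
    if (length(kl_probs) != 3L || abs(sum(kl_probs) - 1) > 1e-8)
      stopf("kl_probs must be a 3-vector summing to 1")
    if (effect_size < 0) stopf("effect_size must be >= 0")
    if (noise_sd <= 0) stopf("noise_sd must be positive")
    if (proportion_concentration <= 0)
      stopf("proportion_concentration must be positive")
    if (!kl_target %in% c(2L, 4L)) stopf("kl_target must be 2 or 4")
    if (pathway_cover_fraction < 0 || pathway_cover_fraction > 1)
      stopf("pathway_cover_fraction must be in [0, 1]")
  })
  invisible(sim)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patients x %d cell types, %d genes, %d metabolites\n",
              x$n_patients, x$n_celltypes, x$n_genes, x$n_metabolites))
  cat(sprintf("  planted: %d pairs (delta=%g), %d+%d hubs (fanout %d), %d KL metabolites\n",
              x$n_planted_pairs, x$effect_size, x$n_planted_hub_genes,
              x$n_planted_hub_metabolites, x$hub_fanout, x$n_kl_metabolites))
  invisible(x)
}
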