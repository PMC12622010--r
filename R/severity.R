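#' Binarize KL grades against a target grade
#'
#' @param kl_grades Integer vector of Kellgren/Lawrence grades in \{2,3,4\}.
#' @param target Grade defining the positive class (2 or 4).
#' @return Integer 0/1 vector (1 iff grade equals the target).
#' @export
kl_binarize <- function(kl_grades, target) {
  if (!target %in% c(2L, 4L)) stopf("kl_binarize: target must be 2 or 4")
  if (!all(kl_grades %in% c(2L, 3L, 4L)))
    stopf("kl_binarize: grades outside {2,3,4}")
  as.integer(kl_grades == target)
}

#' ROC curve and area under it
#'
#' Threshold sweep over the unique scores (descending), yielding the
#' (FPR, TPR) polyline from (0, 0) to (1, 1); the area is computed by the
#' trapezoidal rule and equals the normalized Mann-Whitney U statistic
#' (ties credited 1/2).
#'
#' @param scores Real-valued classifier scores (larger = more case-like).
#' @param labels Binary vector (both classes present).
#' @return List with `roc_points` (data.frame `fpr`, `tpr`) and `auroc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stopf("roc_auc: both classes must be present")
  pos <- labels == classes[2L]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  ord <- order(-scores)
  s <- scores[ord]; y <- pos[ord]
  # group tied scores so the curve steps once per distinct threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(!y)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auroc = auroc)
}

#' Severity classification from a cell type's transcriptome
#'
#' Random-forest classification of a KL severity group (target grade vs the
#' other two grades) from pseudo-bulk expression restricted to the cell
#' type's hub genes. Each of `rf_repeats_severity` (30) repeats performs a
#' stratified 70/30 split, within-training differential-expression selection
#' over the hub genes at `de_alpha`, a cross-validated hyperparameter search
#' and a test-set balanced accuracy. The run achieving the median balanced
#' accuracy (lower median for an even repeat count) supplies the test-set
#' scores for the reported ROC curve and AUROC.
#'
#' @param expr Patients x genes matrix.
#' @param hub_genes Feature subset (nonempty; intersected with columns).
#' @param labels Binary severity labels from [kl_binarize()] (each class
#'   >= 10 patients).
#' @param config An [analysis_config()].
#' @param seed Seed for the repeats.
#' @param cell_type Label stored on the result.
#' @param target Target grade stored on the result.
#' @return A `severity_result` list: `cell_type`, `target`,
#'   `repeat_accuracies`, `median_run_accuracy`, `roc_points`, `auroc`,
#'   `seed`.
#' @export
severity_classification <- function(expr, hub_genes, labels,
                                    config = analysis_config(),
                                    seed = config$seed,
                                    cell_type = NA_character_, target = NA_integer_) {
  feats <- intersect(hub_genes, colnames(expr))
  if (!length(feats)) stopf("severity_classification: no hub genes present")
  if (length(unique(labels)) < 2L)
    stopf("severity_classification: single-class labels")
  if (min(table(labels)) < 10L)
    stopf("severity_classification: each class needs >= 10 patients")
  X <- expr[, feats, drop = FALSE]
  res <- rf_repeat_protocol(X, labels, config, seed,
                            config$rf_repeats_severity, "de")
  if (!length(res$accs)) stopf("severity_classification: all repeats failed")
  ord <- order(res$accs)
  median_idx <- ord[floor((length(res$accs) + 1) / 2)]  # lower median
  run <- res$runs[[median_idx]]
  roc <- roc_auc(run$scores, labels[run$test_idx])
  structure(list(cell_type = cell_type, target = target,
                 repeat_accuracies = res$accs,
                 median_run_accuracy = res$accs[median_idx],
                 roc_points = roc$roc_points, auroc = roc$auroc, seed = seed),
            class = "severity_result")
}

#' One-sided two-proportion test of a metabolite against a KL group
#'
#' Compares the proportion of high-abundance (Group 1) patients inside the
#' target KL group with the proportion among all other patients, using the
#' continuity-corrected chi-square construction of [stats::prop.test()] with
#' the one-sided alternative that the proportion is greater inside the
#' target group.
#'
#' @param grouping A [discretize_metabolite()] grouping.
#' @param kl_binary 0/1 vector from [kl_binarize()] over the same patients
#'   (both groups nonempty).
#' @return List with `prop_in`, `prop_out`, `p`.
#' @export
metabolite_kl_association <- function(grouping, kl_binary) {
  stopifnot(inherits(grouping, "metabolite_grouping"))
  high <- grouping$group == 1L
  n_in <- sum(kl_binary == 1L); n_out <- sum(kl_binary == 0L)
  if (n_in == 0L || n_out == 0L)
    stopf("metabolite_kl_association: empty KL group")
  x_in <- sum(high & kl_binary == 1L)
  x_out <- sum(high & kl_binary == 0L)
  pt <- suppressWarnings(stats::prop.test(c(x_in, x_out), c(n_in, n_out),
                                          alternative = "greater"))
  list(prop_in = x_in / n_in, prop_out = x_out / n_out, p = pt$p.value)
}

#' Metabolite-severity association table for a cohort
#'
#' Applies [metabolite_kl_association()] to every testable metabolite for
#' one target grade.
#'
#' @param cohort A preprocessed [omics_cohort()].
#' @param target KL grade (2 or 4).
#' @param config An [analysis_config()].
#' @return data.frame (`metabolite`, `target`, `prop_in`, `prop_out`, `p`).
#' @export
metabolite_kl_table <- function(cohort, target, config = analysis_config()) {
  kl <- kl_binarize(cohort$metadata$kl_grade, target)
  mets <- colnames(cohort$metabolites)
  rows <- lapply(mets, function(m) {
    grp <- discretize_metabolite(cohort$metabolites[, m],
                                 q = config$metabolite_split_quantile,
                                 min_group = config$min_group, id = m)
    if (is.null(grp)) return(NULL)
    r <- metabolite_kl_association(grp, kl)
    data.frame(metabolite = m, target = target, prop_in = r$prop_in,
               prop_out = r$prop_out, p = r$p)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Hypergeometric enrichment of the predictable/severity metabolite overlap
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' intersection between the transcriptome-predictable metabolites and the
#' severity-associated metabolites, in a universe of `universe_size`
#' metabolites. The predictable set is expected to be pre-filtered: reported
#' accuracy above the overlap threshold with the proportion-confounder
#' baseline below it (see [select_predictable_metabolites()]).
#'
#' @param predictable Metabolite id set.
#' @param severity_associated Metabolite id set.
#' @param universe_size Number of metabolites in the universe (>= both set
#'   sizes).
#' @return List with `k` (intersection size) and `p`.
#' @export
overlap_enrichment <- function(predictable, severity_associated, universe_size) {
  predictable <- unique(predictable)
  severity_associated <- unique(severity_associated)
  if (length(predictable) > universe_size ||
      length(severity_associated) > universe_size ||
      length(union(predictable, severity_associated)) > universe_size)
    stopf("overlap_enrichment: sets exceed the universe")
  k <- length(intersect(predictable, severity_associated))
  p <- stats::phyper(k - 1, length(predictable),
                     universe_size - length(predictable),
                     length(severity_associated), lower.tail = FALSE)
  list(k = k, p = p)
}

#' Select transcriptome-predictable metabolites for the overlap analysis
#'
#' Metabolites whose reported accuracy from a cell type's transcriptome
#' exceeds `overlap_accuracy_threshold` and whose proportion-confounder
#' baseline accuracy stays below it.
#'
#' @param pred Prediction table rows for one cell type.
#' @param confounder Prediction table rows with `cell_type = "proportions"`.
#' @param config An [analysis_config()].
#' @return Character vector of metabolite ids.
#' @export
select_predictable_metabolites <- function(pred, confounder,
                                           config = analysis_config()) {
  thr <- config$overlap_accuracy_threshold
  keep <- pred$metabolite[pred$reported_acc > thr]
  conf_high <- confounder$metabolite[confounder$reported_acc >= thr]
  setdiff(keep, conf_high)
}
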