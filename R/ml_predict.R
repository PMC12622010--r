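#' Balanced accuracy of a binary prediction
#'
#' The mean of sensitivity and specificity, the chance level being 0.5
#' regardless of class imbalance.
#'
#' @param y_true Binary vector (two classes present).
#' @param y_pred Binary vector of predictions, same coding.
#' @return Fraction in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  classes <- sort(unique(y_true))
  if (length(classes) != 2L)
    stopf("balanced_accuracy: y_true must contain exactly two classes")
  sens <- mean(y_pred[y_true == classes[2L]] == classes[2L])
  spec <- mean(y_pred[y_true == classes[1L]] == classes[1L])
  (sens + spec) / 2
}

#' Differential-expression feature selection within a training set
#'
#' Selects the genes whose pooled two-sample t-test p-value between the two
#' training label groups is `<= alpha`. Computed on training patients only,
#' so no information from the test set leaks into the features. An empty
#' selection falls back to the 10 smallest-p genes (logged).
#'
#' @param train_expr Training patients x genes matrix.
#' @param train_labels Binary vector over training patients (two classes,
#'   each with >= 2 patients).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of selected gene ids.
#' @export
de_feature_select <- function(train_expr, train_labels, alpha = 0.05) {
  classes <- sort(unique(train_labels))
  if (length(classes) != 2L) stopf("de_feature_select: need two classes")
  idx1 <- which(train_labels == classes[1L])
  idx2 <- which(train_labels == classes[2L])
  if (length(idx1) < 2L || length(idx2) < 2L)
    stopf("de_feature_select: each class needs >= 2 training patients")
  tt <- col_t_stats(train_expr, idx1, idx2)
  genes <- colnames(train_expr)
  sel <- genes[tt$p <= alpha]
  if (!length(sel)) {
    sel <- genes[order(tt$p, genes, method = "radix")][seq_len(min(10L, length(genes)))]
    cov_log("DEBUG", "de_feature_select: empty selection, falling back to 10 smallest p")
  }
  sel
}

rf_grid <- list(num_trees = c(100L, 300L, 500L),
                max_depth = c(3L, 5L, 10L, 0L),   # 0 = unbounded
                min_node = c(1L, 3L, 5L))

stratified_split <- function(y, train_fraction) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, round(train_fraction * length(idx)))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    train <- c(train, sample_ids(idx, n_tr))
  }
  sort(train)
}

fit_rf <- function(X, y, params, seed) {
  ranger::ranger(x = X, y = factor(y, levels = sort(unique(y))),
                 num.trees = params$num_trees,
                 max.depth = params$max_depth,
                 min.node.size = params$min_node,
                 probability = TRUE, seed = seed, num.threads = 1L,
                 verbose = FALSE)
}

rf_predict <- function(fit, X) {
  pr <- stats::predict(fit, data = X, num.threads = 1L)$predictions
  pos <- colnames(pr)[ncol(pr)]
  list(score = pr[, ncol(pr)],
       class = ifelse(pr[, ncol(pr)] >= 0.5, pos, colnames(pr)[1L]))
}

# Randomized hyperparameter search by stratified k-fold CV on the training
# set; returns the best candidate's parameters.
tune_rf <- function(X, y, n_candidates, n_folds, seed) {
  set.seed(seed)
  cands <- unique(data.frame(
    num_trees = sample(rf_grid$num_trees, n_candidates, replace = TRUE),
    max_depth = sample(rf_grid$max_depth, n_candidates, replace = TRUE),
    min_node = sample(rf_grid$min_node, n_candidates, replace = TRUE)))
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  cv_acc <- vapply(seq_len(nrow(cands)), function(ci) {
    accs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- fit_rf(X[tr, , drop = FALSE], y[tr], cands[ci, ], seed + ci)
      pred <- rf_predict(fit, X[te, , drop = FALSE])$class
      balanced_accuracy(y[te], pred)
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  cands[which.max(cv_acc), ]
}

# Shared repeated 70/30 protocol: stratified split, optional within-train DE
# feature selection, CV-tuned random forest, balanced accuracy + test scores.
rf_repeat_protocol <- function(X, y, config, seed, n_repeats,
                               feature_select = c("de", "none"),
                               de_alpha = config$de_alpha) {
  feature_select <- match.arg(feature_select)
  accs <- numeric(0)
  runs <- list()
  n_feats <- integer(0)
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- seed + rep_i
    set.seed(rep_seed)
    tr <- stratified_split(y, config$train_fraction)
    te <- setdiff(seq_along(y), tr)
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
      cov_log("DEBUG", "repeat %d skipped: single-class split", rep_i)
      next
    }
    feats <- if (feature_select == "de") {
      tryCatch(de_feature_select(X[tr, , drop = FALSE], y[tr], de_alpha),
               error = function(e) NULL)
    } else colnames(X)
    if (is.null(feats)) next
    Xtr <- X[tr, feats, drop = FALSE]; Xte <- X[te, feats, drop = FALSE]
    params <- tune_rf(Xtr, y[tr], config$rf_tune_candidates,
                      config$rf_cv_folds, rep_seed)
    fit <- fit_rf(Xtr, y[tr], params, rep_seed)
    pred <- rf_predict(fit, Xte)
    acc <- balanced_accuracy(y[te], pred$class)
    accs <- c(accs, acc)
    n_feats <- c(n_feats, length(feats))
    runs[[length(runs) + 1L]] <- list(repeat_id = rep_i, test_idx = te,
                                      scores = pred$score, accuracy = acc,
                                      n_features = length(feats))
  }
  list(accs = accs, runs = runs, n_features = n_feats)
}

#' Reported accuracy and confidence interval over repeated splits
#'
#' Centers a 95% interval at the mean balanced accuracy with standard error
#' `sqrt(mean * (1 - mean) / n_eff)`. If the lower end of the interval is
#' below 0.5 the mean is reported; if it is strictly above 0.5 the median of
#' the 20 largest accuracies is reported instead.
#'
#' @param accs Vector of balanced accuracies (nonempty).
#' @param n_eff Effective n in the standard error (>= 1).
#' @param z Normal quantile (default 1.96 for 95%).
#' @param top_k Number of top accuracies whose median is reported in the
#'   confident branch (default 20).
#' @return List with `mean`, `ci_low`, `ci_high`, `reported`.
#' @export
reported_accuracy <- function(accs, n_eff, z = 1.96, top_k = 20L) {
  stopifnot(length(accs) >= 1L, n_eff >= 1)
  a <- mean(accs)
  sdv <- sqrt(a * (1 - a) / n_eff)
  ci_low <- a - z * sdv
  ci_high <- a + z * sdv
  reported <- if (ci_low < 0.5) a else {
    top <- sort(accs, decreasing = TRUE)[seq_len(min(top_k, length(accs)))]
    stats::median(top)
  }
  list(mean = a, ci_low = ci_low, ci_high = ci_high, reported = reported)
}

resolve_n_eff <- function(config, n_repeats, n_test) {
  ne <- config$ci_n_eff
  if (is.numeric(ne)) return(ne)
  switch(ne, repeats = n_repeats, test_size = n_test, one = 1)
}

#' Repeated random-forest prediction of a metabolite's abundance group
#'
#' For each of `rf_repeats_metabolite` repeats: a stratified 70/30
#' train/test split, differential-expression feature selection at `de_alpha`
#' inside the training set, a randomized cross-validated hyperparameter
#' search, a random-forest fit, and a balanced accuracy on the held-out
#' test set. The repeat accuracies are aggregated by [reported_accuracy()].
#'
#' @param expr Patients x genes matrix (a cell type's pseudo-bulk).
#' @param grouping A [discretize_metabolite()] grouping over the same
#'   patients.
#' @param config An [analysis_config()].
#' @param seed Seed for this record's repeats (per-repeat seed = seed +
#'   repeat index).
#' @param cell_type Label stored on the record.
#' @return A `prediction_record` list: `metabolite`, `cell_type`,
#'   `repeat_accuracies`, `mean_acc`, `ci_low`, `ci_high`, `reported_acc`,
#'   `n_test`, `features_per_repeat`, `seed`.
#' @export
repeat_metabolite_prediction <- function(expr, grouping, config = analysis_config(),
                                         seed = config$seed,
                                         cell_type = NA_character_) {
  if (is.null(grouping)) return(NULL)
  stopifnot(inherits(grouping, "metabolite_grouping"))
  y <- grouping$group
  if (length(y) != nrow(expr))
    stopf("repeat_metabolite_prediction: grouping and expression disagree")
  res <- rf_repeat_protocol(expr, y, config, seed,
                            config$rf_repeats_metabolite, "de")
  if (!length(res$accs)) return(NULL)
  n_test <- length(res$runs[[1L]]$test_idx)
  rep_acc <- reported_accuracy(res$accs,
                               resolve_n_eff(config, length(res$accs), n_test))
  structure(list(metabolite = grouping$metabolite_id, cell_type = cell_type,
                 repeat_accuracies = res$accs, mean_acc = rep_acc$mean,
                 ci_low = rep_acc$ci_low, ci_high = rep_acc$ci_high,
                 reported_acc = rep_acc$reported, n_test = n_test,
                 features_per_repeat = res$n_features, seed = seed),
            class = "prediction_record")
}

#' Proportion-confounder baseline prediction
#'
#' The same repeated protocol as [repeat_metabolite_prediction()] but with
#' the patients x cell-types proportion matrix as features and no feature
#' selection — the baseline asking whether a metabolite is explained by cell
#' type composition rather than any single cell type's transcriptome.
#'
#' @param proportions Patients x cell types matrix.
#' @param grouping A [discretize_metabolite()] grouping.
#' @param config An [analysis_config()].
#' @param seed Seed for the repeats.
#' @return A `prediction_record` with `cell_type = "proportions"`.
#' @export
proportion_baseline <- function(proportions, grouping, config = analysis_config(),
                                seed = config$seed) {
  if (is.null(grouping)) return(NULL)
  y <- grouping$group
  res <- rf_repeat_protocol(proportions, y, config, seed,
                            config$rf_repeats_metabolite, "none")
  if (!length(res$accs)) return(NULL)
  n_test <- length(res$runs[[1L]]$test_idx)
  rep_acc <- reported_accuracy(res$accs,
                               resolve_n_eff(config, length(res$accs), n_test))
  structure(list(metabolite = grouping$metabolite_id, cell_type = "proportions",
                 repeat_accuracies = res$accs, mean_acc = rep_acc$mean,
                 ci_low = rep_acc$ci_low, ci_high = rep_acc$ci_high,
                 reported_acc = rep_acc$reported, n_test = n_test,
                 features_per_repeat = res$n_features, seed = seed),
            class = "prediction_record")
}

#' One-sided exact binomial test against a chance rate
#'
#' Upper-tail probability `P(X >= n_correct)` for `X ~ Binomial(n_test, p0)`.
#'
#' @param n_correct Number of correct predictions.
#' @param n_test Test set size.
#' @param p0 Chance success probability (default 0.5).
#' @return The one-sided p-value.
#' @export
binomial_significance <- function(n_correct, n_test, p0 = 0.5) {
  stopifnot(n_correct >= 0, n_correct <= n_test)
  stats::pbinom(n_correct - 1, n_test, p0, lower.tail = FALSE)
}

#' Convert prediction records to a table
#'
#' @param records List of `prediction_record`s.
#' @return data.frame with one row per record.
#' @export
prediction_table <- function(records) {
  records <- Filter(Negate(is.null), records)
  do.call(rbind, lapply(records, function(r) {
    data.frame(metabolite = r$metabolite, cell_type = r$cell_type,
               mean_acc = r$mean_acc, ci_low = r$ci_low, ci_high = r$ci_high,
               reported_acc = r$reported_acc, n_test = r$n_test,
               n_repeats = length(r$repeat_accuracies), seed = r$seed)
  }))
}

#' Link metabolites to cell types from prediction records
#'
#' A metabolite is linked to a cell type when its reported balanced accuracy
#' is at least `link_accuracy_threshold` (0.65). Metabolites linked to
#' `pan_link_min_celltypes` (four) or more cell types are flagged as
#' pan-cell-type. A link is cell-type-specific when it is the only link and
#' every other cell type's accuracy is below `threshold -
#' specific_link_margin`.
#'
#' @param records Table from [prediction_table()] (or a list of records);
#'   rows with `cell_type` `"proportions"`/`"bulk"` are ignored for linking.
#' @param config An [analysis_config()].
#' @return data.frame with one row per metabolite: `metabolite`, `n_links`,
#'   `linked_celltypes` (comma-joined), `pan`, `specific_celltype` (`NA`
#'   unless specific).
#' @export
link_metabolites_to_celltypes <- function(records, config = analysis_config()) {
  d <- if (is.data.frame(records)) records else prediction_table(records)
  d <- d[!d$cell_type %in% c("proportions", "bulk"), ]
  thr <- config$link_accuracy_threshold
  margin <- config$specific_link_margin
  parts <- lapply(split(d, d$metabolite), function(g) {
    linked <- sort(g$cell_type[g$reported_acc >= thr])
    specific <- NA_character_
    if (length(linked) == 1L) {
      others <- g$reported_acc[g$cell_type != linked]
      if (!length(others) || all(others < thr - margin)) specific <- linked
    }
    data.frame(metabolite = g$metabolite[1L], n_links = length(linked),
               linked_celltypes = paste(linked, collapse = ","),
               pan = length(linked) >= config$pan_link_min_celltypes,
               specific_celltype = specific)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$metabolite), ]
}
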