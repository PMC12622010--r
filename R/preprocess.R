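#' Saturate a vector at an upper quantile
#'
#' Values greater than or equal to the q-th quantile are replaced by the
#' quantile value, damping the influence of outliers. The quantile is computed
#' by linear interpolation of order statistics (type 7, the default
#' convention in scientific software).
#'
#' @param values Numeric vector (length >= 2, at least one finite value).
#' @param q Quantile in (0, 1); default 0.95.
#' @return The saturated vector; never larger elementwise than the input.
#' @export
saturate_quantile <- function(values, q = 0.95) {
  stopifnot(is.numeric(values), length(values) >= 2L, q > 0, q < 1)
  if (all(is.na(values))) stopf("saturate_quantile: all values missing")
  cap <- stats::quantile(values, q, na.rm = TRUE, names = FALSE, type = 7)
  pmin(values, cap)
}

#' Standardize the columns of a patients x features matrix
#'
#' Each feature is centered to mean zero and scaled to sample standard
#' deviation one. Zero-variance features are set to all zeros (rather than
#' dropped, preserving the matrix shape) and flagged in the
#' `"zero_variance"` attribute.
#'
#' @param mat Numeric matrix, patients in rows, features in columns.
#' @return The standardized matrix with a logical `"zero_variance"` attribute
#'   (one entry per column).
#' @export
standardize_features <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  centered <- sweep(mat, 2L, mu, "-")
  n <- colSums(!is.na(mat))
  if (any(n < 2L)) stopf("standardize_features: a column has < 2 finite values")
  sdv <- sqrt(colSums(centered^2, na.rm = TRUE) / (n - 1L))
  zero <- sdv < .Machine$double.eps^0.5
  sdv[zero] <- 1
  out <- sweep(centered, 2L, sdv, "/")
  out[, zero] <- 0
  if (any(zero))
    cov_log("WARNING", "standardize_features: %d zero-variance feature(s) set to 0",
            sum(zero))
  attr(out, "zero_variance") <- zero
  out
}

#' Pseudo-bulk averaging of a cell-level expression matrix
#'
#' For every cell type, the expression of each gene is averaged over all
#' cells of that type belonging to a patient, yielding one patients x genes
#' matrix per cell type. (Patient, cell type) combinations with no cells are
#' recorded as `NA` rows and are excluded from downstream testing for that
#' cell type.
#'
#' @param cell_matrix Numeric cells x genes matrix.
#' @param cell_type_labels Character/factor vector, one label per cell (row).
#' @param patient_labels Character vector, one patient id per cell (row).
#' @return Named list mapping cell type to a patients x genes matrix; the
#'   patient axis is the sorted union of patient labels, identical across
#'   cell types.
#' @export
pseudobulk_average <- function(cell_matrix, cell_type_labels, patient_labels) {
  stopifnot(is.matrix(cell_matrix))
  if (nrow(cell_matrix) == 0L) stopf("pseudobulk_average: empty cell matrix")
  if (length(cell_type_labels) != nrow(cell_matrix) ||
      length(patient_labels) != nrow(cell_matrix))
    stopf("pseudobulk_average: labels must align with cell rows")
  cell_type_labels <- as.character(cell_type_labels)
  patient_labels <- as.character(patient_labels)
  patients <- sort(unique(patient_labels))
  types <- sort(unique(cell_type_labels))
  genes <- colnames(cell_matrix) %||% sprintf("g%04d", seq_len(ncol(cell_matrix)))
  out <- vector("list", length(types))
  names(out) <- types
  for (t in types) {
    sel <- cell_type_labels == t
    sums <- rowsum(cell_matrix[sel, , drop = FALSE], patient_labels[sel])
    counts <- as.vector(table(patient_labels[sel])[rownames(sums)])
    avg <- sums / counts
    m <- matrix(NA_real_, length(patients), ncol(cell_matrix),
                dimnames = list(patients, genes))
    m[rownames(avg), ] <- avg
    out[[t]] <- m
  }
  out
}

#' Select the most variable features
#'
#' Plain variance ranking: the `n` features with the largest sample variance
#' across patients are retained, with ties at the cutoff broken
#' lexicographically by feature id so the selection is deterministic. This is
#' a stand-in for upstream highly-variable-feature selectors and should be
#' applied to saturated but not yet standardized values (standardization
#' equalizes all variances).
#'
#' @param mat Patients x features matrix with column names.
#' @param n Number of features to keep.
#' @return Character vector of `n` feature ids, in decreasing-variance order.
#' @export
select_highly_variable <- function(mat, n) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  if (n > ncol(mat))
    stopf("select_highly_variable: n (%d) exceeds feature count (%d)", n, ncol(mat))
  v <- apply(mat, 2L, stats::var, na.rm = TRUE)
  ord <- order(-v, colnames(mat), method = "radix")
  colnames(mat)[ord][seq_len(n)]
}

#' Cell type proportions per patient
#'
#' @param cell_type_labels Character vector of per-cell type labels.
#' @param patient_labels Character vector of per-cell patient ids.
#' @return Patients x cell types matrix of fractions; each row sums to 1.
#' @export
cell_type_proportions <- function(cell_type_labels, patient_labels) {
  stopifnot(length(cell_type_labels) == length(patient_labels),
            length(patient_labels) > 0L)
  tab <- table(as.character(patient_labels), as.character(cell_type_labels))
  m <- unclass(tab)[, , drop = FALSE]
  m <- m[sort(rownames(m)), sort(colnames(m)), drop = FALSE]
  storage.mode(m) <- "double"
  totals <- rowSums(m)
  if (any(totals == 0)) stopf("cell_type_proportions: patient with zero cells")
  m / totals
}

#' Preprocess an omics cohort
#'
#' Applies the canonical preprocessing order to every matrix of the cohort:
#' per-feature saturation at the configured upper quantile, highly-variable
#' feature selection on the saturated (unstandardized) values, then
#' per-feature standardization to mean zero / sd one. Genes are selected on
#' the patient-level bulk average of the per-cell-type matrices; metabolites
#' on the metabolite table.
#'
#' @param cohort An [omics_cohort()].
#' @param config An [analysis_config()].
#' @return The preprocessed cohort, with `hvg_genes` and `hvg_metabolites`
#'   recorded in its `selected` field.
#' @export
preprocess_cohort <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "omics_cohort"))
  sat <- function(m) apply(m, 2L, saturate_quantile, q = config$saturation_quantile)
  sat_na <- function(m) {
    apply(m, 2L, function(col) {
      ok <- !is.na(col)
      if (sum(ok) >= 2L) col[ok] <- saturate_quantile(col[ok], config$saturation_quantile)
      col
    })
  }
  pb_sat <- lapply(cohort$pseudobulk, function(m) {
    out <- sat_na(m)
    dimnames(out) <- dimnames(m)
    out
  })
  # bulk average across cell types (ignoring missing combinations) drives HVG
  bulk <- Reduce(`+`, lapply(pb_sat, function(m) ifelse(is.na(m), 0, m))) /
    Reduce(`+`, lapply(pb_sat, function(m) !is.na(m) + 0))
  n_g <- min(config$n_hvg_genes, ncol(bulk))
  hvg <- select_highly_variable(bulk, n_g)
  met_sat <- sat(cohort$metabolites)
  dimnames(met_sat) <- dimnames(cohort$metabolites)
  n_m <- min(config$n_hvg_metabolites, ncol(met_sat))
  hvm <- select_highly_variable(met_sat, n_m)

  std_na <- function(m) {
    out <- m
    for (j in seq_len(ncol(m))) {
      ok <- !is.na(m[, j])
      x <- m[ok, j]
      s <- stats::sd(x)
      out[ok, j] <- if (s < .Machine$double.eps^0.5) 0 else (x - mean(x)) / s
    }
    out
  }
  cohort$pseudobulk <- lapply(pb_sat, function(m) std_na(m[, hvg, drop = FALSE]))
  cohort$metabolites <- standardize_features(met_sat[, hvm, drop = FALSE])
  cohort$selected <- list(hvg_genes = hvg, hvg_metabolites = hvm)
  cohort$preprocessed <- TRUE
  cov_log("INFO", "preprocess: %d genes, %d metabolites retained", n_g, n_m)
  cohort
}
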