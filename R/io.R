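#' Construct an omics cohort
#'
#' The unit consumed by every analysis stage: per-cell-type pseudo-bulk
#' expression, a bulk metabolite table, cell type proportions and patient
#' metadata, all sharing one patient axis in identical order.
#'
#' @param pseudobulk Named list of patients x genes matrices, one per cell
#'   type (missing patient/cell-type combinations as `NA` rows).
#' @param metabolites Patients x metabolites matrix.
#' @param proportions Patients x cell types matrix of fractions (rows sum
#'   to 1), or `NULL`.
#' @param metadata data.frame with columns `patient_id`, `site`, `sex`,
#'   `kl_grade` (KL grade in \{2, 3, 4\}).
#' @return Object of class `omics_cohort`.
#' @export
omics_cohort <- function(pseudobulk, metabolites, proportions, metadata) {
  stopifnot(is.list(pseudobulk), length(pseudobulk) > 0L, is.matrix(metabolites))
  patients <- rownames(metabolites)
  if (is.null(patients)) stopf("metabolite matrix must have patient rownames")
  for (ct in names(pseudobulk)) {
    m <- pseudobulk[[ct]]
    if (!identical(rownames(m), patients))
      stopf("pseudobulk['%s'] patient axis differs from metabolite table", ct)
  }
  if (!is.null(proportions)) {
    if (!identical(rownames(proportions), patients))
      stopf("proportions patient axis differs from metabolite table")
    bad <- abs(rowSums(proportions) - 1) > 1e-9
    if (any(bad))
      stopf("proportions rows must sum to 1 (patient %s)",
            rownames(proportions)[which(bad)[1L]])
  }
  required <- c("patient_id", "site", "sex", "kl_grade")
  if (!all(required %in% names(metadata)))
    stopf("metadata must have columns %s", paste(required, collapse = ", "))
  metadata <- metadata[match(patients, metadata$patient_id), , drop = FALSE]
  if (anyNA(metadata$patient_id))
    stopf("metadata is missing patients present in the matrices")
  bad_kl <- !metadata$kl_grade %in% c(2L, 3L, 4L)
  if (any(bad_kl))
    stopf("kl_grade outside {2,3,4} for patient %s",
          metadata$patient_id[which(bad_kl)[1L]])
  rownames(metadata) <- NULL
  structure(list(
    patient_ids = patients,
    cell_types = names(pseudobulk),
    pseudobulk = pseudobulk,
    metabolites = metabolites,
    proportions = proportions,
    metadata = metadata,
    preprocessed = FALSE
  ), class = "omics_cohort")
}

#' @export
print.omics_cohort <- function(x, ...) {
  cat(sprintf("<omics_cohort> %d patients, %d cell types, %d genes, %d metabolites%s\n",
              length(x$patient_ids), length(x$cell_types),
              ncol(x$pseudobulk[[1L]]), ncol(x$metabolites),
              if (isTRUE(x$preprocessed)) " (preprocessed)" else ""))
  invisible(x)
}

read_matrix_file <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, sep = "auto")
  ids <- as.character(dt[[1L]])
  dt <- dt[, -1L, with = FALSE]
  for (j in seq_along(dt)) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "" & col != "NA")
      if (length(bad))
        stopf("non-numeric cell in %s at row %d, column '%s': '%s'",
              basename(path), bad[1L], names(dt)[j], col[bad[1L]])
      data.table::set(dt, j = j, value = num)
    }
  }
  m <- as.matrix(dt)
  rownames(m) <- ids
  m
}

#' Read an omics cohort from a directory of delimited tables
#'
#' Expects `expr_<celltype>.tsv` (one per cell type; rows = patients,
#' columns = genes), `metabolites.tsv`, `proportions.tsv` (optional) and
#' `metadata.tsv` (columns `patient_id`, `site`, `sex`, `kl_grade`). Tab- or
#' comma-delimited files are accepted. Patients missing from any table are
#' dropped with a warning; an empty patient intersection is a fatal error.
#'
#' @param dir Directory holding the input tables.
#' @param config An [analysis_config()] (currently unused at read time,
#'   recorded for provenance).
#' @return An [omics_cohort()].
#' @export
read_cohort <- function(dir, config = analysis_config()) {
  if (!dir.exists(dir)) stopf("input directory not found: %s", dir)
  expr_files <- sort(list.files(dir, pattern = "^expr_.*\\.tsv$", full.names = TRUE))
  if (!length(expr_files)) stopf("no expr_<celltype>.tsv files in %s", dir)
  cts <- sub("^expr_(.*)\\.tsv$", "\\1", basename(expr_files))
  pseudobulk <- lapply(expr_files, read_matrix_file)
  names(pseudobulk) <- cts
  metabolites <- read_matrix_file(file.path(dir, "metabolites.tsv"))
  prop_path <- file.path(dir, "proportions.tsv")
  proportions <- if (file.exists(prop_path)) read_matrix_file(prop_path) else NULL
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stopf("input file not found: %s", meta_path)
  metadata <- as.data.frame(data.table::fread(meta_path, sep = "auto"))
  metadata$patient_id <- as.character(metadata$patient_id)

  axes <- c(lapply(pseudobulk, rownames), list(rownames(metabolites)),
            if (!is.null(proportions)) list(rownames(proportions)),
            list(metadata$patient_id))
  common <- Reduce(intersect, axes)
  if (!length(common)) stopf("empty intersection of patient ids across tables")
  all_ids <- unique(unlist(axes))
  dropped <- setdiff(all_ids, common)
  if (length(dropped)) {
    warning(sprintf("dropping %d patient(s) missing from some table: %s",
                    length(dropped), paste(utils::head(dropped, 5L), collapse = ", ")),
            call. = FALSE)
    cov_log("WARNING", "read_cohort: dropped %d unaligned patient(s)", length(dropped))
  }
  common <- sort(common)
  pseudobulk <- lapply(pseudobulk, function(m) m[common, , drop = FALSE])
  metabolites <- metabolites[common, , drop = FALSE]
  if (!is.null(proportions)) proportions <- proportions[common, , drop = FALSE]
  metadata <- metadata[match(common, metadata$patient_id), , drop = FALSE]
  omics_cohort(pseudobulk, metabolites, proportions, metadata)
}

write_matrix_file <- function(m, path) {
  dt <- data.table::data.table(patient_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
}

#' Write an omics cohort to a directory
#'
#' Emits the exact file set [read_cohort()] consumes.
#'
#' @param cohort An [omics_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in cohort$cell_types)
    write_matrix_file(cohort$pseudobulk[[ct]], file.path(dir, sprintf("expr_%s.tsv", ct)))
  write_matrix_file(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  if (!is.null(cohort$proportions))
    write_matrix_file(cohort$proportions, file.path(dir, "proportions.tsv"))
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}

#' Write result tables and a JSON summary
#'
#' Each table is written as a TSV with a header row; a machine-readable
#' `summary.json` of key statistics is written alongside. Output is
#' byte-identical across runs with identical inputs and seed.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param summary Named list of key statistics for `summary.json`.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, out_dir, summary = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  if (file.access(out_dir, 2L) != 0L) stopf("output directory %s not writable", out_dir)
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    data.table::fwrite(as.data.frame(tables[[nm]]), path, sep = "\t",
                       quote = FALSE, na = "NA")
    files <- c(files, path)
  }
  if (!is.null(summary)) {
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, path)
  }
  cov_log("INFO", "write_results: %d file(s) -> %s", length(files), out_dir)
  invisible(files)
}
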