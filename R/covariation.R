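#' Discretize a metabolite into high/low abundance groups
#'
#' Patients with abundance greater than or equal to the q-th quantile
#' (default the 75th percentile, linear-interpolation convention) form
#' Group 1; the rest form Group 2. Metabolites for which either group would
#' have fewer than `min_group` patients are skipped (returns `NULL` with a
#' logged reason) — in particular constant metabolites, whose Group 2 is
#' empty.
#'
#' @param abundance Numeric vector over patients.
#' @param q Split quantile in (0, 1).
#' @param min_group Minimum patients required on each side.
#' @param id Optional metabolite id used in log messages.
#' @return A `metabolite_grouping` (list with `metabolite_id`, `group`
#'   (integer 1/2 per patient), `threshold_value`, `q`, `n1`, `n2`), or
#'   `NULL` if skipped.
#' @export
discretize_metabolite <- function(abundance, q = 0.75, min_group = 5L, id = NULL) {
  stopifnot(is.numeric(abundance), q > 0, q < 1)
  thr <- stats::quantile(abundance, q, names = FALSE, type = 7, na.rm = TRUE)
  group <- ifelse(abundance >= thr, 1L, 2L)
  n1 <- sum(group == 1L, na.rm = TRUE)
  n2 <- sum(group == 2L, na.rm = TRUE)
  if (n1 < min_group || n2 < min_group) {
    cov_log("DEBUG", "discretize_metabolite[%s]: skipped (groups %d/%d < %d)",
            id %||% "?", n1, n2, min_group)
    return(NULL)
  }
  structure(list(metabolite_id = id, group = group, threshold_value = thr,
                 q = q, n1 = n1, n2 = n2),
            class = "metabolite_grouping")
}

#' Pooled two-sample t-test
#'
#' Student's two-sided t-test with pooled variance (Welch's form available via
#' `welch = TRUE`). A zero pooled variance yields `(t = 0, p = 1,
#' direction = 0)` with `flag = TRUE` rather than an error.
#'
#' @param x1,x2 Numeric vectors (each length >= 2).
#' @param welch Use Welch's unequal-variance form.
#' @return List with `t_stat`, `p`, `direction` (sign of `mean(x1) -
#'   mean(x2)`), `df` and `flag`.
#' @export
two_sample_t <- function(x1, x2, welch = FALSE) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stopf("two_sample_t: each group needs >= 2 values")
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- vp * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (!is.finite(se2) || se2 < .Machine$double.eps) {
    return(list(t_stat = 0, p = 1, direction = 0L, df = df, flag = TRUE))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_stat = t_stat, p = p, direction = as.integer(sign(m1 - m2)),
       df = df, flag = FALSE)
}

# Vectorized pooled/Welch t-tests of every column of X between the patients
# indexed by idx1 and idx2. Returns a list of per-gene vectors.
col_t_stats <- function(X, idx1, idx2, welch = FALSE) {
  n1 <- length(idx1); n2 <- length(idx2)
  X1 <- X[idx1, , drop = FALSE]; X2 <- X[idx2, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X2^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- vp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, ncol(X))
  }
  zero <- !is.finite(se2) | se2 < .Machine$double.eps
  t_stat <- (m1 - m2) / sqrt(se2)
  t_stat[zero] <- 0
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[zero] <- 1
  dirn <- as.integer(sign(m1 - m2))
  dirn[zero] <- 0L
  list(t_stat = t_stat, p = p, direction = dirn, flag = zero)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (a thin wrapper around
#' [stats::p.adjust()] kept as the single adjustment entry point of the
#' pipeline). Applied within each cell type by [build_association_map()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
adjust_bh <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Build the per-cell-type gene-metabolite association map
#'
#' For every metabolite, patients are split at the configured quantile of the
#' metabolite's (standardized) abundance; every gene in every cell type is
#' then tested for differential pseudo-bulk expression between the two
#' patient groups with a pooled two-sample t-test. A pair is "associated"
#' when its nominal p-value is <= `assoc_alpha`. BH-adjusted p-values are
#' computed within each cell type. Patients with a missing pseudo-bulk entry
#' for a cell type are excluded from that cell type's tests; metabolites
#' whose grouping leaves fewer than `min_group` patients on either side are
#' skipped and logged.
#'
#' @param cohort A preprocessed [omics_cohort()].
#' @param config An [analysis_config()].
#' @return A data.frame of class `association_map` with columns `cell_type`,
#'   `gene`, `metabolite`, `t`, `p`, `p_adj`, `direction`, `n1`, `n2`, and
#'   attributes `genes`, `metabolites`, `cell_types`, `alpha`.
#' @export
build_association_map <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "omics_cohort"))
  q <- config$metabolite_split_quantile
  genes <- colnames(cohort$pseudobulk[[1L]])
  mets <- colnames(cohort$metabolites)
  out <- vector("list", length(cohort$cell_types))
  names(out) <- cohort$cell_types
  n_skipped <- 0L
  for (ct in cohort$cell_types) {
    X <- cohort$pseudobulk[[ct]]
    present <- stats::complete.cases(X)
    Xc <- X[present, , drop = FALSE]
    M <- cohort$metabolites[present, , drop = FALSE]
    blocks <- vector("list", length(mets))
    for (k in seq_along(mets)) {
      grp <- discretize_metabolite(M[, k], q = q, min_group = config$min_group,
                                   id = mets[k])
      if (is.null(grp)) { n_skipped <- n_skipped + 1L; next }
      idx1 <- which(grp$group == 1L); idx2 <- which(grp$group == 2L)
      tt <- col_t_stats(Xc, idx1, idx2, welch = config$welch)
      blocks[[k]] <- data.table::data.table(
        cell_type = ct, gene = genes, metabolite = mets[k],
        t = tt$t_stat, p = tt$p, direction = tt$direction,
        n1 = grp$n1, n2 = grp$n2)
    }
    dt <- data.table::rbindlist(blocks)
    if (nrow(dt)) dt[, "p_adj" := adjust_bh(dt$p)]
    out[[ct]] <- dt
  }
  map <- as.data.frame(data.table::rbindlist(out, use.names = TRUE, fill = TRUE))
  cols <- c("cell_type", "gene", "metabolite", "t", "p", "p_adj",
            "direction", "n1", "n2")
  if (!nrow(map)) {
    map <- data.frame(cell_type = character(), gene = character(),
                      metabolite = character(), t = numeric(), p = numeric(),
                      p_adj = numeric(), direction = integer(),
                      n1 = integer(), n2 = integer())
  }
  map <- map[, cols]
  if (n_skipped)
    cov_log("INFO", "build_association_map: %d (metabolite, cell type) grouping(s) skipped",
            n_skipped)
  structure(map, class = c("association_map", "data.frame"),
            genes = genes, metabolites = mets,
            cell_types = cohort$cell_types, alpha = config$assoc_alpha)
}

map_alpha <- function(map, alpha = NULL) alpha %||% attr(map, "alpha") %||% 0.005

#' Per-entity association counts (degrees)
#'
#' Counts, for every gene and every metabolite in every cell type, the number
#' of partners associated at the given threshold. Entities with zero
#' associations are retained with count 0.
#'
#' @param map An association map from [build_association_map()].
#' @param alpha Significance threshold (default: the map's `assoc_alpha`).
#' @return data.frame with columns `kind` ("gene"/"metabolite"), `id`,
#'   `cell_type`, `count`; carries the map's entity universe as attributes.
#' @export
compute_degrees <- function(map, alpha = NULL) {
  alpha <- map_alpha(map, alpha)
  genes <- attr(map, "genes"); mets <- attr(map, "metabolites")
  cts <- attr(map, "cell_types")
  sig <- map[map$p <= alpha, c("cell_type", "gene", "metabolite")]
  grid_counts <- function(ids, col) {
    full <- data.table::CJ(id = ids, cell_type = cts)
    if (nrow(sig)) {
      dt <- data.table::as.data.table(sig)
      cnt <- dt[, list(count = .N), by = c(col, "cell_type")]
      data.table::setnames(cnt, col, "id")
      out <- merge(full, cnt, by = c("id", "cell_type"), all.x = TRUE)
    } else {
      out <- full
      out[, "count" := NA_integer_]
    }
    out$count[is.na(out$count)] <- 0L
    out
  }
  g <- grid_counts(genes, "gene"); g[, "kind" := "gene"]
  m <- grid_counts(mets, "metabolite"); m[, "kind" := "metabolite"]
  deg <- as.data.frame(data.table::rbindlist(list(g, m)))
  deg <- deg[, c("kind", "id", "cell_type", "count")]
  structure(deg, class = c("degree_table", "data.frame"),
            genes = genes, metabolites = mets, cell_types = cts, alpha = alpha)
}

degree_matrix <- function(degrees, kind) {
  d <- degrees[degrees$kind == kind, ]
  ids <- sort(unique(d$id)); cts <- sort(unique(d$cell_type))
  m <- matrix(0L, length(ids), length(cts), dimnames = list(ids, cts))
  m[cbind(match(d$id, ids), match(d$cell_type, cts))] <- d$count
  m
}

#' Select per-cell-type hub sets
#'
#' The top `n_hub_metabolites` metabolites (by number of associated genes)
#' and top `n_hub_genes` genes (by number of associated metabolites) in each
#' cell type, ties at the cutoff broken lexicographically by entity id.
#'
#' @param degrees A [compute_degrees()] table.
#' @param config An [analysis_config()].
#' @return Named list per cell type, each with `hub_genes` and
#'   `hub_metabolites` character vectors of the configured sizes.
#' @export
select_hub_sets <- function(degrees, config = analysis_config()) {
  top_n <- function(kind, n) {
    m <- degree_matrix(degrees, kind)
    if (nrow(m) < n)
      stopf("select_hub_sets: only %d %ss available, %d requested", nrow(m), kind, n)
    lapply(as.data.frame(m), function(cnt) {
      ord <- order(-cnt, rownames(m), method = "radix")
      rownames(m)[ord][seq_len(n)]
    })
  }
  hg <- top_n("gene", config$n_hub_genes)
  hm <- top_n("metabolite", config$n_hub_metabolites)
  cts <- names(hg)
  out <- lapply(cts, function(ct) list(hub_genes = hg[[ct]],
                                       hub_metabolites = hm[[ct]]))
  names(out) <- cts
  out
}

#' Cell-type specificity scores
#'
#' For entity e and cell type i the score is `count_i(e) - mean_{j != i}
#' count_j(e)`: the excess of associations in that cell type over the average
#' of the remaining cell types.
#'
#' @param degrees A [compute_degrees()] table (>= 2 cell types).
#' @return data.frame with columns `kind`, `id`, `cell_type`, `count`,
#'   `score`.
#' @export
specificity_scores <- function(degrees) {
  cts <- unique(degrees$cell_type)
  if (length(cts) < 2L) stopf("specificity_scores: need >= 2 cell types")
  out <- lapply(c("gene", "metabolite"), function(kind) {
    m <- degree_matrix(degrees, kind)
    if (nrow(m) == 0L) return(NULL)
    C <- ncol(m)
    others <- (rowSums(m) - m) / (C - 1)
    s <- m - others
    data.frame(kind = kind,
               id = rep(rownames(m), C),
               cell_type = rep(colnames(m), each = nrow(m)),
               count = as.vector(m),
               score = as.vector(s))
  })
  do.call(rbind, out)
}

#' Top cell-type-specific hubs
#'
#' @param scores Output of [specificity_scores()].
#' @param n Hubs per cell type (default 10).
#' @param kind "gene" or "metabolite".
#' @return data.frame of the top `n` entities per cell type, sorted by
#'   descending specificity score (ties by id).
#' @export
top_specific_hubs <- function(scores, n = 10L, kind = c("gene", "metabolite")) {
  kind <- match.arg(kind)
  s <- scores[scores$kind == kind, ]
  parts <- lapply(split(s, s$cell_type), function(d) {
    d <- d[order(-d$score, d$id, method = "radix"), ]
    utils::head(d, n)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Pan-cell-type hub ranking by geometric-mean ranks
#'
#' Entities are ranked within each cell type by association count (rank 1 =
#' most associations, average ranks on ties); the per-cell-type ranks are
#' combined by their geometric mean and the `n` entities with the smallest
#' combined rank are returned. Geometric-mean ties are broken by the smaller
#' minimum rank, then by id.
#'
#' @param degrees A [compute_degrees()] table.
#' @param n Number of pan-cell-type hubs.
#' @param kind "gene" or "metabolite".
#' @return data.frame with columns `id`, `gm_rank`, `min_rank`, ordered by
#'   combined rank.
#' @export
pan_celltype_ranks <- function(degrees, n = 50L, kind = c("gene", "metabolite")) {
  kind <- match.arg(kind)
  m <- degree_matrix(degrees, kind)
  ranks <- apply(m, 2L, function(cnt) rank(-cnt, ties.method = "average"))
  gm <- exp(rowMeans(log(ranks)))
  mn <- apply(ranks, 1L, min)
  ord <- order(gm, mn, rownames(m), method = "radix")
  out <- data.frame(id = rownames(m)[ord], gm_rank = unname(gm[ord]),
                    min_rank = unname(mn[ord]))
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Bipartite association density between two node sets
#'
#' The fraction of realized edges (pairs associated at `alpha`) among all
#' `|genes| x |metabolites|` possible pairs within one cell type.
#'
#' @param map An association map.
#' @param genes,metabolites Nonempty id sets.
#' @param cell_type Cell type to evaluate.
#' @param alpha Significance threshold (default the map's).
#' @return A fraction in \[0, 1\].
#' @export
bipartite_density <- function(map, genes, metabolites, cell_type, alpha = NULL) {
  if (!length(genes) || !length(metabolites))
    stopf("bipartite_density: empty node set")
  alpha <- map_alpha(map, alpha)
  sel <- map$cell_type == cell_type & map$p <= alpha &
    map$gene %in% genes & map$metabolite %in% metabolites
  sum(sel) / (length(genes) * length(metabolites))
}

#' Permutation test for hub-hub interconnection density
#'
#' Compares the observed density between hub genes and hub metabolites with
#' the densities of `n_perm` random draws of equally many non-hub genes and
#' non-hub metabolites (sampled without replacement). The p-value is the
#' fraction of draws whose density strictly exceeds the observed one
#' (resolution `1/n_perm`).
#'
#' @param map An association map.
#' @param hub_genes,hub_metabolites Hub id sets.
#' @param cell_type Cell type to evaluate.
#' @param n_perm Number of random draws (default 200).
#' @param seed Seed for the draws.
#' @param alpha Significance threshold (default the map's).
#' @return List with `observed` density, `p`, and the vector `perm_densities`.
#' @export
density_permutation_pvalue <- function(map, hub_genes, hub_metabolites,
                                       cell_type, n_perm = 200L, seed = 1L,
                                       alpha = NULL) {
  alpha <- map_alpha(map, alpha)
  genes <- attr(map, "genes"); mets <- attr(map, "metabolites")
  non_g <- setdiff(genes, hub_genes)
  non_m <- setdiff(mets, hub_metabolites)
  if (length(non_g) < length(hub_genes) || length(non_m) < length(hub_metabolites))
    stopf("density_permutation_pvalue: not enough non-hub entities to sample")
  observed <- bipartite_density(map, hub_genes, hub_metabolites, cell_type, alpha)
  # precompute the cell type's significant edge list once
  sig <- map[map$cell_type == cell_type & map$p <= alpha, c("gene", "metabolite")]
  set.seed(derive_seed(seed, paste0("density_perm:", cell_type)))
  perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample_ids(non_g, length(hub_genes))
    m <- sample_ids(non_m, length(hub_metabolites))
    sum(sig$gene %in% g & sig$metabolite %in% m) /
      (length(g) * length(m))
  }, numeric(1))
  list(observed = observed, p = mean(perm > observed), perm_densities = perm)
}

#' Null distribution for hub sharing across cell types
#'
#' The binomial probability mass function Binomial(`n_celltypes`, `p`) used
#' as the null for the number of cell types in which an entity is a hub
#' (p = 0.05, the hub fraction, for 17 cell types in the study).
#'
#' @param n_celltypes Number of cell types.
#' @param p Per-cell-type hub probability in (0, 1).
#' @return Numeric vector of length `n_celltypes + 1` with the pmf over
#'   0..n_celltypes.
#' @export
hub_sharing_null_pmf <- function(n_celltypes, p = 0.05) {
  stopifnot(p > 0, p < 1, n_celltypes >= 1)
  stats::dbinom(0:n_celltypes, n_celltypes, p)
}

#' Observed hub-sharing counts
#'
#' For each entity appearing in at least one per-cell-type hub set, the
#' number of cell types for which it is a hub — the observed histogram that
#' [hub_sharing_null_pmf()] is overlaid against.
#'
#' @param hub_sets Output of [select_hub_sets()].
#' @param kind "gene" or "metabolite".
#' @return Named integer vector (entity -> number of cell types).
#' @export
hub_sharing_counts <- function(hub_sets, kind = c("gene", "metabolite")) {
  kind <- match.arg(kind)
  field <- if (kind == "gene") "hub_genes" else "hub_metabolites"
  all_ids <- unlist(lapply(hub_sets, `[[`, field), use.names = FALSE)
  table_out <- table(all_ids)
  out <- as.integer(table_out)
  names(out) <- names(table_out)
  sort(out, decreasing = TRUE)
}
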