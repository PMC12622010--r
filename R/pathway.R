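#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (set name, description, member ids per
#'   line, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway-metabolite membership table
#'
#' @param path TSV with columns `pathway_id`, `metabolite_id`.
#' @return data.frame with those two columns.
#' @export
read_pathway_metabolites <- function(path) {
  if (!file.exists(path)) stopf("membership file not found: %s", path)
  d <- as.data.frame(data.table::fread(path, sep = "auto"))
  if (!all(c("pathway_id", "metabolite_id") %in% names(d)))
    stopf("membership file must have columns pathway_id, metabolite_id")
  d$pathway_id <- as.character(d$pathway_id)
  d$metabolite_id <- as.character(d$metabolite_id)
  d
}

#' Build the high-confidence pathway-co-membership map
#'
#' Filters the association map to quadruplets (metabolite, gene, cell type,
#' pathway) where the pair is associated at `alpha` and the gene and the
#' metabolite are members of the same metabolic pathway. A pair co-occurring
#' in k pathways yields k quadruplets.
#'
#' @param map An association map.
#' @param gene_sets Named list: pathway -> gene members (e.g. [read_gmt()]).
#' @param metabolite_membership data.frame (`pathway_id`, `metabolite_id`).
#' @param alpha Significance threshold (default the map's).
#' @return data.frame with columns `metabolite`, `gene`, `cell_type`,
#'   `pathway`, `direction`, `p`.
#' @export
build_high_confidence_map <- function(map, gene_sets, metabolite_membership,
                                      alpha = NULL) {
  alpha <- map_alpha(map, alpha)
  sig <- map[map$p <= alpha, , drop = FALSE]
  empty <- data.frame(metabolite = character(), gene = character(),
                      cell_type = character(), pathway = character(),
                      direction = integer(), p = numeric())
  if (!nrow(sig)) return(empty)
  pw_genes <- data.frame(
    pathway = rep(names(gene_sets), lengths(gene_sets)),
    gene = unlist(gene_sets, use.names = FALSE))
  pw_mets <- data.frame(pathway = metabolite_membership$pathway_id,
                        metabolite = metabolite_membership$metabolite_id)
  hc <- merge(sig[, c("metabolite", "gene", "cell_type", "direction", "p")],
              pw_genes, by = "gene")
  hc <- merge(hc, pw_mets, by = c("pathway", "metabolite"))
  if (!nrow(hc)) return(empty)
  hc <- hc[order(hc$pathway, hc$metabolite, hc$gene, hc$cell_type,
                 method = "radix"),
           c("metabolite", "gene", "cell_type", "pathway", "direction", "p")]
  rownames(hc) <- NULL
  hc
}

#' Rank entities by high-confidence frequency
#'
#' Counts how often each metabolite, gene or pathway appears in the
#' high-confidence map, aggregated across cell types, in descending order
#' (ties broken by id). By default quadruplets are counted; set
#' `distinct_pairs = TRUE` to count distinct (gene, metabolite, cell type)
#' triples instead.
#'
#' @param hc A [build_high_confidence_map()] table.
#' @param axis One of "metabolite", "gene", "pathway".
#' @param distinct_pairs Count distinct triples rather than quadruplets.
#' @return data.frame with columns `id`, `count`.
#' @export
rank_by_frequency <- function(hc, axis = c("metabolite", "gene", "pathway"),
                              distinct_pairs = FALSE) {
  axis <- match.arg(axis)
  if (!nrow(hc)) return(data.frame(id = character(), count = integer()))
  d <- if (distinct_pairs)
    hc[!duplicated(hc[, c("metabolite", "gene", "cell_type")]), ] else hc
  tab <- table(d[[axis]])
  out <- data.frame(id = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Fraction of high-confidence pairs with inverse gene-metabolite trend
#'
#' Reports the share of quadruplets in which the gene is expressed *higher*
#' in the low-metabolite patient group — i.e. higher enzyme expression
#' accompanying lower metabolite abundance. Direction convention: the map's
#' `direction` is the sign of (mean expression in Group 1 high-abundance
#' patients) minus (mean in Group 2), so this is the fraction with
#' `direction == -1`.
#'
#' @param hc A [build_high_confidence_map()] table.
#' @return Fraction in \[0, 1\] (`NaN` for an empty map).
#' @export
direction_of_effect_summary <- function(hc) {
  mean(hc$direction == -1L)
}

#' Hypergeometric over-representation of gene sets
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query and the set within the universe:
#' `P(X >= k)` with population `|universe|`, successes `|set ∩ universe|`
#' and draws `|query|`. BH-adjusted p-values are included.
#'
#' @param query Gene id set (must be contained in `universe`).
#' @param gene_sets Named list of gene sets.
#' @param universe Background gene ids (nonempty).
#' @return data.frame with columns `set`, `overlap`, `set_size`,
#'   `query_size`, `p`, `p_adj`, ordered by increasing `p`.
#' @export
set_enrichment <- function(query, gene_sets, universe) {
  if (!length(universe)) stopf("set_enrichment: empty universe")
  if (!all(query %in% universe))
    stopf("set_enrichment: query must be a subset of the universe")
  N <- length(unique(universe)); n <- length(unique(query))
  res <- lapply(names(gene_sets), function(nm) {
    K <- length(intersect(gene_sets[[nm]], universe))
    k <- length(intersect(gene_sets[[nm]], query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_bh(out$p)
  out <- out[order(out$p, out$set, method = "radix"), ]
  rownames(out) <- NULL
  out
}
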