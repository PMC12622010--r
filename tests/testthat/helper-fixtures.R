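# Shared fixture builders; everything is generated in code at test time.

# analysis config scaled to desk-size problems (small RF search budgets)
small_cfg <- function(...) {
  defaults <- list(rf_repeats_metabolite = 10L, rf_repeats_severity = 8L,
                   rf_tune_candidates = 2L, rf_cv_folds = 2L,
                   n_density_perms = 50L)
  do.call(analysis_config, utils::modifyList(defaults, list(...)))
}

# hand-built association map with the attributes build_association_map sets
make_map <- function(df, genes, metabolites, cell_types, alpha = 0.005) {
  need <- c("cell_type", "gene", "metabolite", "t", "p", "p_adj",
            "direction", "n1", "n2")
  for (col in setdiff(need, names(df))) {
    df[[col]] <- switch(col, t = 0, p_adj = df$p, direction = 1L,
                        n1 = 10L, n2 = 30L)
  }
  structure(df[, need], class = c("association_map", "data.frame"),
            genes = genes, metabolites = metabolites,
            cell_types = cell_types, alpha = alpha)
}

# edge list -> map rows: given edges (gene, metabolite, cell_type) make them
# significant (p = 1e-6) and all other combinations non-significant (p = 0.5)
full_map_from_edges <- function(edges, genes, metabolites, cell_types) {
  grid <- expand.grid(gene = genes, metabolite = metabolites,
                      cell_type = cell_types, stringsAsFactors = FALSE)
  key <- function(d) paste(d$gene, d$metabolite, d$cell_type)
  grid$p <- ifelse(key(grid) %in% key(edges), 1e-6, 0.5)
  make_map(grid, genes, metabolites, cell_types)
}

# tiny deterministic cohort written straight from matrices
toy_cohort <- function(n = 12L, n_genes = 6L, n_mets = 4L, n_ct = 2L,
                       seed = 42L) {
  set.seed(seed)
  patients <- sprintf("P%02d", seq_len(n))
  genes <- sprintf("G%02d", seq_len(n_genes))
  mets <- sprintf("M%02d", seq_len(n_mets))
  cts <- paste0("ct", LETTERS[seq_len(n_ct)])
  pb <- lapply(stats::setNames(cts, cts), function(ct) {
    m <- matrix(rnorm(n * n_genes), n, n_genes, dimnames = list(patients, genes))
    m
  })
  mets_m <- matrix(exp(rnorm(n * n_mets)), n, n_mets,
                   dimnames = list(patients, mets))
  prop <- matrix(runif(n * n_ct), n, n_ct, dimnames = list(patients, cts))
  prop <- prop / rowSums(prop)
  meta <- data.frame(patient_id = patients,
                     site = rep(c("site1", "site2"), length.out = n),
                     sex = rep(c("F", "M"), length.out = n),
                     kl_grade = rep(c(2L, 3L, 4L), length.out = n))
  omics_cohort(pb, mets_m, prop, meta)
}
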