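# Shared fixtures and independent oracles. Worlds used by the acceptance
# suite live here so each world is defined exactly once.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent all-pairs AUROC oracle: count wins + half-ties over every
# (member, non-member) pair, using signed scores (ties share a score).
brute_auroc <- function(set, ranking) {
  member <- ranking$gene %in% set
  sm <- ranking$score[member]
  sn <- ranking$score[!member]
  wins <- 0
  for (a in sm) for (b in sn)
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  wins / (length(sm) * length(sn))
}

# Step-up Benjamini-Hochberg oracle, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Ranking with given scores (already sorted by caller or not).
make_ranking <- function(genes, scores) {
  ord <- order(-scores, genes)
  out <- data.frame(gene = genes[ord], score = scores[ord],
                    position = seq_along(genes), stringsAsFactors = FALSE)
  class(out) <- c("age_ranking", "data.frame")
  out
}

# Random (set, ranking) instance for property tests; allows score ties.
random_instance <- function(seed, max_n = 50) {
  set.seed(seed)
  n <- sample(3:max_n, 1)
  genes <- sprintf("g%03d", seq_len(n))
  scores <- sample(round(rnorm(n), sample(0:2, 1)))  # coarse rounding -> ties
  n1 <- sample(seq_len(n - 1), 1)
  list(ranking = make_ranking(genes, scores), set = sample(genes, n1))
}

# Hand-built permutation_null object (for exact-control unit tests).
fake_null <- function(A, tau = 2, seed = 0L) {
  structure(list(auroc = A, types = colnames(A), B = nrow(A),
                 seed = seed, tau = tau),
            class = "permutation_null")
}

# --- Stated worlds for the acceptance criteria ------------------------------

# Full null: no planted effects anywhere; many small types plus a sparse
# baseline so permutation-derived sets are non-empty, and observed labels
# are exactly exchangeable with shuffles.
null_world_cfg <- function(seed) {
  simulation_config(n_types = 25, cells_per_type = 4, n_genes = 2000,
                    markers_per_type = 0, marker_effect = 0, noise_sd = 1,
                    baseline_mean = 0, baseline_sd = 2, seed = seed)
}

# Power world: one cell type's 300 markers shifted up by 1 SD in the age
# statistic; 10,000 genes.
power_world_cfg <- function(seed) {
  simulation_config(n_types = 20, cells_per_type = 4, n_genes = 10000,
                    markers_per_type = 300, marker_effect = 4, noise_sd = 1,
                    baseline_mean = 0, baseline_sd = 2,
                    injected_up_types = "type01", set_shift = 1, seed = seed)
}

# Inflated-baseline world: cell-type structure but NO per-set signal; the
# only planted effect is a down-shift of all non-marker genes. The denser
# baseline keeps permutation-derived sets marker-dominated (the paper's
# mechanism: an enriched set cannot contain non-specific genes).
baseline_world_cfg <- function(seed) {
  simulation_config(n_types = 40, cells_per_type = 3, n_genes = 5000,
                    markers_per_type = 100, marker_effect = 4, noise_sd = 1,
                    baseline_mean = 1.5, baseline_sd = 1,
                    set_shift = 0, nonspecific_shift = -0.5, seed = seed)
}

# Recoverable-marker world (paper-like type-count geometry): used wherever
# a test needs high planted-marker recovery.
recovery_world_cfg <- function(seed, marker_effect = 4) {
  simulation_config(n_types = 20, cells_per_type = 4, n_genes = 1000,
                    markers_per_type = 30, marker_effect = marker_effect,
                    noise_sd = 1, baseline_mean = 0, baseline_sd = 2,
                    seed = seed)
}

# One full pipeline pass on a simulated world: returns observed AUROCs,
# the permutation null and the empirical p/q table.
world_enrichment <- function(cfg, B, null_seed) {
  sim <- simulate_single_cell(cfg)
  z <- standardize_expression(filter_zero_genes(sim$expr))
  tabl <- simulate_age_table(sim$truth, cfg)
  ranking <- build_signed_ranking(tabl[tabl$gene %in% rownames(z), ])
  map <- identity_map(rownames(z))
  catalog <- map_sets(derive_gene_sets(type_profile(z, sim$labels), 2), map)
  observed <- suppressWarnings(observed_aurocs(catalog, ranking))
  null <- permutation_null(z, sim$labels, ranking, map, tau = 2,
                           B = B, seed = null_seed)
  pq <- empirical_pq(observed[!is.na(observed)], null)
  list(sim = sim, z = z, ranking = ranking, catalog = catalog,
       observed = observed, null = null, pq = pq)
}
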