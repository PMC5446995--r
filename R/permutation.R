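# Label-permutation empirical null and min-p FDR.
#
# Shuffling the cell -> type assignment and re-deriving the gene sets from
# scratch captures everything the thresholding step does to the null: set
# sizes are emergent per shuffle, and the non-specific set participates as
# an extra "type". The empirical p-value is two-sided by distance from the
# permuted mean, because in real data the permuted baseline sits above 0.5
# for enriched sets (broadly expressed genes are consistently age-down-
# regulated, and by construction cannot enter an enriched set), so extreme-
# ness must be measured relative to the permuted average, not 0.5.

#' Label-permutation null for cell-type set AUROCs
#'
#' For each of `B` seeded shuffles of the cell-to-type assignment the full
#' derivation is recomputed: per-type average standardized expression,
#' strict-threshold enriched sets and non-specific set, ortholog mapping,
#' then the AUROC of every set against the (already homolog-restricted)
#' ranking. Shuffles that produce a degenerate set record `NA`.
#'
#' @param z standardized matrix from [standardize_expression()] (mouse
#'   symbols as rownames).
#' @param ann named cell -> type annotation covering every column of `z`.
#' @param ranking an `age_ranking` in human symbols, already restricted with
#'   [restrict_ranking()] if an ortholog map is in play.
#' @param map an [ortholog_map()]; use [identity_map()] when mouse and human
#'   symbols coincide (synthetic data).
#' @param tau enrichment threshold (default 2).
#' @param B number of permutations (>= 1; the study default is 10000).
#' @param seed master seed; the full set of shuffles is drawn from it up
#'   front, so runs are reproducible and permutations independent of B order.
#' @param engine `"cpp"` (default) or `"r"` — the plain-R reference
#'   implementation, kept for verification.
#' @return an object of class `permutation_null`: list with `auroc`
#'   (B x (types + 1) matrix, last column `"nonspecific"`), `types`, `B`,
#'   `seed`, `tau`.
#' @export
permutation_null <- function(z, ann, ranking, map, tau = 2, B = 10000,
                             seed = 1L, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  B <- assert_count(B, "B", lower = 1L)
  validate_annotation(z, ann)
  stopifnot(inherits(ranking, "age_ranking"))
  lab <- as.character(ann[colnames(z)])
  types <- sort(unique(lab))
  lab_int <- match(lab, types) - 1L

  revrank <- ranking_gene_revrank(rownames(z), ranking, map)

  set.seed(seed)
  n <- ncol(z)
  shuffles <- vapply(seq_len(B), function(b) sample(lab_int), integer(n))
  shuffles <- matrix(shuffles, nrow = n)

  A <- if (engine == "cpp") {
    cpp_perm_auroc(z, shuffles, length(types), revrank, tau)
  } else {
    r_perm_auroc(z, shuffles, length(types), revrank, tau)
  }
  colnames(A) <- c(types, "nonspecific")
  structure(list(auroc = A, types = types, B = B, seed = seed, tau = tau),
            class = "permutation_null")
}

# Reverse midranks of the ranking, pulled back to the mouse gene universe
# through the ortholog map; NA for genes that are unmapped or absent from
# the ranking. The ranking is first restricted to the images of the assayed
# genes (the study's background rule: human genes with a homolog mapping
# from the genes assayed in the single-cell data), so observed and permuted
# AUROCs share one universe and midranks are internally consistent. This is
# where map_sets() collapses to a lookup: with a one-to-one map, deriving a
# set in mouse symbols and translating it is the same as reading the set's
# human revranks directly.
ranking_gene_revrank <- function(genes, ranking, map) {
  human <- setNames(map$human, map$mouse)[genes]
  sub <- ranking[ranking$gene %in% human, , drop = FALSE]
  if (nrow(sub) == 0)
    stop_config("no expression gene maps into the ranking; check the ortholog map")
  class(sub) <- c("age_ranking", "data.frame")
  rr <- ranking_revrank(sub)
  unname(rr[human])
}

# Plain-R reference for the permutation engine; same contract as
# cpp_perm_auroc. Quadratic-ish and only meant for small verification runs.
r_perm_auroc <- function(z, shuffles, n_types, revrank, tau) {
  G <- nrow(z); n <- ncol(z); B <- ncol(shuffles); C <- n_types
  inr <- !is.na(revrank)
  Nrank <- sum(inr)
  rr <- ifelse(inr, revrank, 0)
  out <- matrix(NA_real_, B, C + 1)
  for (b in seq_len(B)) {
    fac <- factor(shuffles[, b], levels = 0:(C - 1))
    counts <- as.integer(table(fac))
    prof <- t(rowsum(t(z), fac)) / rep(counts, each = G)
    idx_ns <- apply(abs(prof), 1, max) < tau & inr
    for (c in seq_len(C + 1)) {
      idx <- if (c <= C) (prof[, c] > tau) & inr else idx_ns
      n1 <- sum(idx); n2 <- Nrank - n1
      if (n1 > 0 && n2 > 0) {
        U <- sum(rr[idx]) - n1 * (n1 + 1) / 2
        out[b, c] <- U / (n1 * n2)
      }
    }
  }
  out
}

#' Empirical p- and q-values from a permutation null
#'
#' For each type `c` with permuted AUROCs `A_bc` (mean `m_c`), the p-value
#' is the proportion of shuffles at least as far from the permuted mean as
#' the observed value, `p_c = #\{b : |A_bc - m_c| >= |obs_c - m_c|\} / B`,
#' floored at `1/B` (ties count as extreme — the conservative choice). The
#' q-value is the empirical min-p FDR: within each shuffle the same p-value
#' rule is applied to every type against its own null (plug-in, Westfall-
#' Young style), and `q_c` is the proportion of shuffles whose minimum
#' per-type p-value is at most `p_c`. `NA` entries (degenerate sets in some
#' shuffles) are dropped column-wise; the effective `B` per type is
#' reported.
#'
#' @param observed named numeric vector of observed AUROCs; names must be a
#'   subset of the null's columns (include `"nonspecific"` to test the
#'   non-specific set).
#' @param null a [permutation_null()].
#' @return data.frame with columns `type`, `auroc`, `permuted_mean`,
#'   `empirical_p`, `empirical_q`, `B_effective`, sorted by `empirical_p`.
#' @export
empirical_pq <- function(observed, null) {
  stopifnot(inherits(null, "permutation_null"))
  if (is.null(names(observed)))
    stop_config("'observed' must be a named vector of AUROCs")
  A <- null$auroc
  missing <- setdiff(names(observed), colnames(A))
  if (length(missing) > 0)
    stop_config("type(s) absent from the permutation null: %s",
                paste(missing, collapse = ", "))
  eps <- 1e-12

  # per-column permuted means and within-null p of every permuted value
  m <- colMeans(A, na.rm = TRUE)
  P <- A
  for (j in seq_len(ncol(A))) {
    v <- A[, j]
    ok <- !is.na(v)
    Bj <- sum(ok)
    if (Bj == 0) { P[, j] <- NA_real_; next }
    d <- abs(v[ok] - m[j])
    # ties.method = "min" makes count_ge include all tied values
    P[ok, j] <- (Bj - rank(d, ties.method = "min") + 1) / Bj
    P[!ok, j] <- NA_real_
  }
  minp <- suppressWarnings(apply(P, 1, min, na.rm = TRUE))
  minp[!is.finite(minp)] <- NA_real_

  rows <- lapply(names(observed), function(ty) {
    v <- A[, ty]
    ok <- !is.na(v)
    Bj <- sum(ok)
    if (Bj == 0 || is.na(observed[[ty]]))
      return(data.frame(type = ty, auroc = observed[[ty]],
                        permuted_mean = NA_real_, empirical_p = NA_real_,
                        empirical_q = NA_real_, B_effective = Bj,
                        stringsAsFactors = FALSE))
    d_obs <- abs(observed[[ty]] - m[ty])
    p <- max(sum(abs(v[ok] - m[ty]) >= d_obs - eps) / Bj, 1 / Bj)
    q <- mean(minp[!is.na(minp)] <= p + eps)
    data.frame(type = ty, auroc = observed[[ty]], permuted_mean = m[[ty]],
               empirical_p = p, empirical_q = q, B_effective = Bj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$empirical_p, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed AUROCs for every set of a catalog
#'
#' Scores each enriched set and the non-specific set of a (human-symbol)
#' catalog against a ranking; degenerate sets give `NA` with a warning.
#'
#' @param catalog a `gene_set_catalog` in ranking symbols.
#' @param ranking an `age_ranking`.
#' @return named numeric vector (types plus `"nonspecific"`).
#' @export
observed_aurocs <- function(catalog, ranking) {
  stopifnot(inherits(catalog, "gene_set_catalog"))
  sets <- c(catalog$enriched, list(nonspecific = catalog$nonspecific))
  vapply(names(sets), function(nm) {
    res <- tryCatch(as.numeric(auroc(sets[[nm]], ranking)),
                    error = function(e) NA_real_)
    if (is.na(res)) warning(sprintf("set '%s' is degenerate in this ranking", nm))
    res
  }, numeric(1))
}
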