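# Age-association rankings: a total order over genes from most significantly
# age-up-regulated to most significantly age-down-regulated, built from per-
# gene (p-value, direction) rows. The signed score is s = sign * (-log10 p),
# up = +, so p = 1 maps to s = 0 for either direction and such genes sit at
# the up/down boundary inside a tie region. Ties (equal s) are stored in
# lexicographic gene order; downstream statistics use midranks, so the
# stored within-tie order never affects results.

#' Build a signed up-to-down age ranking
#'
#' @param table data.frame with columns `gene`, `p` (in (0, 1]), `direction`
#'   (`"up"` or `"down"`); one row per gene.
#' @return an object of class `age_ranking`: data.frame with columns `gene`,
#'   `score` (signed, non-increasing), `position` (1 = most up-regulated).
#' @export
build_signed_ranking <- function(table) {
  need <- c("gene", "p", "direction")
  if (!all(need %in% names(table)))
    stop_config("ranking table needs columns: %s", paste(need, collapse = ", "))
  gene <- as.character(table$gene)
  dup <- unique(gene[duplicated(gene)])
  if (length(dup) > 0)
    stop_config("duplicate gene(s) in ranking table: %s",
                paste(head(dup, 5), collapse = ", "))
  p <- as.numeric(table$p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_config("p-values must lie in (0, 1]")
  dir <- as.character(table$direction)
  if (!all(dir %in% c("up", "down")))
    stop_config("direction must be 'up' or 'down'")
  s <- ifelse(dir == "up", 1, -1) * (-log10(p))
  ord <- order(-s, gene)  # ties lexicographic by symbol
  out <- data.frame(gene = gene[ord], score = s[ord],
                    position = seq_along(gene), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("age_ranking", "data.frame")
  out
}

#' Merge direction-split association tables
#'
#' Some meta-analyses report up- and down-regulation tests separately. For
#' each gene the row with the strictly smaller p-value wins; genes present
#' in only one table pass through. A gene with an exact p tie between
#' directions has no defensible direction, so it is excluded; excluded
#' genes are counted in attribute `n_tie_excluded`.
#'
#' @param up_table,down_table data.frames with columns `gene`, `p`.
#' @return data.frame with columns `gene`, `p`, `direction`, ready for
#'   [build_signed_ranking()].
#' @export
merge_directional <- function(up_table, down_table) {
  up <- data.frame(gene = as.character(up_table$gene),
                   p = as.numeric(up_table$p),
                   direction = "up", stringsAsFactors = FALSE)
  down <- data.frame(gene = as.character(down_table$gene),
                     p = as.numeric(down_table$p),
                     direction = "down", stringsAsFactors = FALSE)
  if (anyDuplicated(up$gene) || anyDuplicated(down$gene))
    stop_config("tables must be keyed by gene (one row per gene)")
  both <- intersect(up$gene, down$gene)
  pu <- setNames(up$p, up$gene)[both]
  pd <- setNames(down$p, down$gene)[both]
  tie <- both[pu == pd]
  rows <- rbind(
    up[!(up$gene %in% both), , drop = FALSE],
    down[!(down$gene %in% both), , drop = FALSE],
    data.frame(gene = both[pu < pd], p = unname(pu[pu < pd]),
               direction = "up", stringsAsFactors = FALSE),
    data.frame(gene = both[pd < pu], p = unname(pd[pd < pu]),
               direction = "down", stringsAsFactors = FALSE)
  )
  rows <- rows[order(rows$gene), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "n_tie_excluded") <- length(tie)
  rows
}

#' Spearman comparison of two rankings
#'
#' Correlates the two orders over their common genes, using midranks for
#' tie groups (genes with equal signed scores).
#'
#' @param r1,r2 `age_ranking` objects.
#' @return list with `rho` and `n_common`.
#' @export
spearman_compare <- function(r1, r2) {
  stopifnot(inherits(r1, "age_ranking"), inherits(r2, "age_ranking"))
  common <- intersect(r1$gene, r2$gene)
  if (length(common) < 3)
    stop_config("need at least 3 common genes (got %d)", length(common))
  s1 <- setNames(r1$score, r1$gene)[common]
  s2 <- setNames(r2$score, r2$gene)[common]
  # position increases as score decreases: correlate -score with midranks
  rho <- cor(rank(-s1), rank(-s2))
  list(rho = unname(rho), n_common = length(common))
}

#' Midranks of an age ranking, counted from the down-regulated end
#'
#' Internal workhorse for AUROC computations: returns for each ranking gene
#' its "reverse midrank" — genes nearest the up-regulated end get the
#' largest values, and tie groups (equal signed score) share their average.
#' AUROC of a set is then `(sum(revrank[set]) - n1 (n1 + 1) / 2) / (n1 n2)`.
#'
#' @param ranking an `age_ranking`.
#' @return named numeric vector (gene -> reverse midrank in 1..N).
#' @keywords internal
ranking_revrank <- function(ranking) {
  n <- nrow(ranking)
  mid <- rank(-ranking$score, ties.method = "average")
  setNames(n + 1 - mid, ranking$gene)
}
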