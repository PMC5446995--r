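# Threshold-free gene-set enrichment in a signed ranking. The statistic is
# the AUROC: the probability that a set member outranks (sits nearer the
# up-regulated end than) a non-member, with ties counted one half via
# midranks — Mann-Whitney U divided by n1 * n2.

set_rank_stats <- function(set, ranking) {
  rr <- ranking_revrank(ranking)
  members <- intersect(unique(as.character(set)), names(rr))
  n1 <- length(members)
  n2 <- length(rr) - n1
  if (n1 == 0)
    stop_config("no set member is present in the ranking (empty effective set)")
  if (n2 == 0)
    stop_config("set covers the whole ranking (empty complement)")
  list(rr = rr, members = members, n1 = n1, n2 = n2,
       U = sum(rr[members]) - n1 * (n1 + 1) / 2,
       n_dropped = length(setdiff(unique(as.character(set)), names(rr))))
}

#' AUROC of a gene set in an age ranking
#'
#' @param set character vector of gene symbols; members absent from the
#'   ranking are dropped first (their count is attached as attribute
#'   `n_dropped`).
#' @param ranking an `age_ranking`.
#' @return AUROC in \[0, 1\]; values above 0.5 mean the set is shifted toward
#'   the age-up-regulated end.
#' @export
auroc <- function(set, ranking) {
  st <- set_rank_stats(set, ranking)
  out <- st$U / (st$n1 * st$n2)
  attr(out, "n_dropped") <- st$n_dropped
  out
}

#' Mann-Whitney p-value of a gene set in an age ranking
#'
#' Normal approximation with tie correction and continuity correction.
#' Two-sided by default; `sides = "one"` tests the side the observed U
#' falls on.
#'
#' @inheritParams auroc
#' @param sides `"two"` (default) or `"one"`.
#' @return p-value in (0, 1\].
#' @export
mw_pvalue <- function(set, ranking, sides = c("two", "one")) {
  sides <- match.arg(sides)
  st <- set_rank_stats(set, ranking)
  n1 <- st$n1; n2 <- st$n2; N <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(ranking$score)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(st$U - mu) - 0.5) / sqrt(sigma2)  # continuity correction
  z <- max(z, 0)
  p <- if (sides == "two") 2 * pnorm(-z) else pnorm(-z)
  min(p, 1)
}

#' Test fixed external gene sets against a ranking
#'
#' For supplied gene sets (e.g. published top-marker lists or housekeeping
#' genes) computes the AUROC and a two-sided Mann-Whitney p-value, then a
#' Bonferroni adjustment over the sets actually tested in this ranking.
#' Sets with an empty intersection with the ranking are skipped with a
#' warning and excluded from the correction count `m`.
#'
#' @param sets named list of character vectors.
#' @param ranking an `age_ranking`.
#' @param correction only `"bonferroni"` is implemented: `p_adj = min(1, m p)`.
#' @return data.frame with columns `name`, `n_genes_tested`, `auroc`, `p`,
#'   `p_adj`, and attribute `m` (number of tests).
#' @export
fixed_set_test <- function(sets, ranking, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  if (length(sets) == 0 || is.null(names(sets)))
    stop_config("'sets' must be a non-empty named list")
  rows <- lapply(names(sets), function(nm) {
    present <- intersect(unique(as.character(sets[[nm]])), ranking$gene)
    if (length(present) == 0 || length(present) == nrow(ranking)) {
      warning(sprintf("set '%s' skipped: %s", nm,
                      if (length(present) == 0) "empty intersection with ranking"
                      else "covers whole ranking"))
      return(NULL)
    }
    data.frame(name = nm, n_genes_tested = length(present),
               auroc = as.numeric(auroc(present, ranking)),
               p = mw_pvalue(present, ranking), stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop_config("no set could be tested in this ranking")
  m <- nrow(rows)
  rows$p_adj <- pmin(1, m * rows$p)
  rownames(rows) <- NULL
  attr(rows, "m") <- m
  rows
}
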