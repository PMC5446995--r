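# GO-group dissection inside cell-type enriched gene sets: rank only the
# set's genes by their age association, then ask whether a GO group's genes
# pile up at either end of that sub-ranking. This can flag a molecular
# process changing with age in one cell type even when the cell type's full
# set is not age-associated.

validate_go_annotations <- function(ann) {
  need <- c("gene", "term_id")
  if (!all(need %in% names(ann)))
    stop_config("annotations need columns: %s", paste(need, collapse = ", "))
  ann$gene <- as.character(ann$gene)
  ann$term_id <- as.character(ann$term_id)
  ann[!duplicated(ann[c("gene", "term_id")]), , drop = FALSE]
}

#' Sub-ranking restricted to a gene set
#'
#' @param set character vector of gene symbols.
#' @param ranking an `age_ranking`.
#' @return an `age_ranking` containing exactly the set's genes, relative
#'   order preserved, positions recomputed. Errors when fewer than 2 set
#'   genes are in the ranking.
#' @export
within_set_ranking <- function(set, ranking) {
  stopifnot(inherits(ranking, "age_ranking"))
  keep <- ranking$gene %in% set
  if (sum(keep) < 2)
    stop_config("need at least 2 set genes in the ranking (got %d)", sum(keep))
  out <- ranking[keep, , drop = FALSE]
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("age_ranking", "data.frame")
  out
}

#' GO-group AUROC scan within cell-type enriched sets
#'
#' For every (cell-type set, GO term) pair: intersect the term's genes with
#' the set and the ranking; if the intersection size `n` satisfies
#' `size_bounds[1] < n < size_bounds[2]` (strict on both ends), compute the
#' term's AUROC and two-sided Mann-Whitney p within the set's sub-ranking.
#' Benjamini-Hochberg q-values are computed once across all performed
#' type-by-term tests jointly. The non-specific set is scanned as one of
#' the "types".
#'
#' @param catalog a `gene_set_catalog` in ranking symbols.
#' @param ranking an `age_ranking`.
#' @param annotations data.frame with columns `gene`, `term_id` and
#'   optionally `term_name`.
#' @param size_bounds strict (lower, upper) bounds on the intersection size;
#'   default `c(10, 200)`.
#' @return data.frame with columns `type`, `term_id`, `term_name`,
#'   `n_intersection`, `auroc`, `p`, `q`, sorted by `q` then `p`. Empty
#'   (with a warning) when no test passes the size filter.
#' @export
go_auroc_scan <- function(catalog, ranking, annotations,
                          size_bounds = c(10, 200)) {
  stopifnot(inherits(catalog, "gene_set_catalog"),
            inherits(ranking, "age_ranking"))
  if (length(size_bounds) != 2 || size_bounds[1] >= size_bounds[2])
    stop_config("size_bounds must be an increasing pair")
  ann <- validate_go_annotations(annotations)
  term_genes <- split(ann$gene, ann$term_id)
  term_names <- if ("term_name" %in% names(ann))
    vapply(split(as.character(ann$term_name), ann$term_id), `[`, character(1), 1)
  else setNames(names(term_genes), names(term_genes))

  sets <- c(catalog$enriched, list(nonspecific = catalog$nonspecific))
  rows <- list()
  for (ty in names(sets)) {
    present <- intersect(sets[[ty]], ranking$gene)
    if (length(present) < 2) next
    sub <- within_set_ranking(present, ranking)
    for (tid in names(term_genes)) {
      hits <- intersect(term_genes[[tid]], sub$gene)
      n <- length(hits)
      if (n <= size_bounds[1] || n >= size_bounds[2]) next
      if (n == nrow(sub)) next  # term covers the whole sub-ranking
      rows[[length(rows) + 1L]] <- data.frame(
        type = ty, term_id = tid, term_name = unname(term_names[tid]),
        n_intersection = n,
        auroc = as.numeric(auroc(hits, sub)),
        p = mw_pvalue(hits, sub),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    warning("no (type, term) pair passed the size filter")
    return(data.frame(type = character(), term_id = character(),
                      term_name = character(), n_intersection = integer(),
                      auroc = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$type, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
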