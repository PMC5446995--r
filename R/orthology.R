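# Orthology: convert mouse gene sets to human symbols and restrict ranking
# backgrounds to mapped genes. Raw homolog tables may be many-to-many; only
# genes whose homology group yields exactly one mouse and one human symbol
# are kept, which prevents set inflation and mirrors Homologene-group
# semantics.

#' Build a one-to-one mouse-to-human ortholog map
#'
#' Accepts either a Homologene-dialect table with columns
#' `homology_group_id`, `taxon`, `symbol` (taxon 10090 = mouse,
#' 9606 = human) or a pre-flattened two-column (`mouse`, `human`) table.
#' Symbols are whitespace-trimmed; comparison stays case-sensitive. Groups
#' (or flattened rows) that are not one mouse symbol to one human symbol,
#' and symbols appearing in more than one retained pair, are dropped; the
#' number of dropped pairs is recorded in attribute `n_dropped`.
#'
#' @param table a data.frame in either dialect.
#' @return an object of class `ortholog_map`: data.frame with columns
#'   `mouse`, `human`, one-to-one in both directions.
#' @export
ortholog_map <- function(table) {
  if (all(c("homology_group_id", "taxon", "symbol") %in% names(table))) {
    table$symbol <- trimws(as.character(table$symbol))
    mouse <- table[table$taxon == 10090, c("homology_group_id", "symbol")]
    human <- table[table$taxon == 9606, c("homology_group_id", "symbol")]
    m_by_g <- split(unique(mouse)$symbol, unique(mouse)$homology_group_id)
    h_by_g <- split(unique(human)$symbol, unique(human)$homology_group_id)
    groups <- intersect(names(m_by_g), names(h_by_g))
    ok <- groups[lengths(m_by_g[groups]) == 1L & lengths(h_by_g[groups]) == 1L]
    pairs <- data.frame(mouse = unlist(m_by_g[ok], use.names = FALSE),
                        human = unlist(h_by_g[ok], use.names = FALSE),
                        stringsAsFactors = FALSE)
    n_raw <- length(groups)
  } else if (all(c("mouse", "human") %in% names(table))) {
    pairs <- data.frame(mouse = trimws(as.character(table$mouse)),
                        human = trimws(as.character(table$human)),
                        stringsAsFactors = FALSE)
    pairs <- unique(pairs)
    n_raw <- nrow(pairs)
  } else {
    stop_config("homolog table must have columns (homology_group_id, taxon, symbol) or (mouse, human)")
  }
  # enforce one-to-one in both directions
  pairs <- pairs[!(pairs$mouse %in% pairs$mouse[duplicated(pairs$mouse)]), , drop = FALSE]
  pairs <- pairs[!(pairs$human %in% pairs$human[duplicated(pairs$human)]), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "n_dropped") <- n_raw - nrow(pairs)
  class(pairs) <- c("ortholog_map", "data.frame")
  pairs
}

#' Identity ortholog map
#'
#' Synthetic-data convenience: maps each symbol to itself, which isolates
#' orthology handling from the rest of the pipeline.
#'
#' @param genes character vector of symbols.
#' @return an `ortholog_map`.
#' @export
identity_map <- function(genes) {
  genes <- unique(as.character(genes))
  out <- data.frame(mouse = genes, human = genes, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- 0L
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Map a gene set catalog from mouse to human symbols
#'
#' Each set is replaced by the images of its mappable members; unmapped
#' genes are dropped and counted in attribute `n_unmapped` (a named vector
#' over sets). The threshold `tau` is carried over.
#'
#' @param catalog a `gene_set_catalog` in mouse symbols.
#' @param map an [ortholog_map()].
#' @return a `gene_set_catalog` in human symbols.
#' @export
map_sets <- function(catalog, map) {
  stopifnot(inherits(catalog, "gene_set_catalog"))
  if (nrow(map) == 0) warning("empty ortholog map: all sets will be empty")
  lookup <- setNames(map$human, map$mouse)
  translate <- function(set) unname(lookup[intersect(set, names(lookup))])
  enriched <- lapply(catalog$enriched, translate)
  nonspecific <- translate(catalog$nonspecific)
  dropped <- c(vapply(seq_along(catalog$enriched),
                      function(i) length(catalog$enriched[[i]]) - length(enriched[[i]]),
                      integer(1)),
               length(catalog$nonspecific) - length(nonspecific))
  names(dropped) <- c(names(catalog$enriched), "nonspecific")
  out <- structure(list(enriched = enriched, nonspecific = nonspecific,
                        tau = catalog$tau),
                   class = "gene_set_catalog")
  attr(out, "n_unmapped") <- dropped
  out
}

#' Restrict an age ranking to genes present in an ortholog map
#'
#' Keeps exactly the ranking genes whose (human) symbol appears in the map,
#' preserving relative order and recomputing positions.
#'
#' @param ranking an `age_ranking` in human symbols.
#' @param map an [ortholog_map()].
#' @return the restricted `age_ranking`.
#' @export
restrict_ranking <- function(ranking, map) {
  stopifnot(inherits(ranking, "age_ranking"))
  keep <- ranking$gene %in% map$human
  if (!any(keep))
    stop_config("no ranking gene has an ortholog mapping; empty intersection")
  out <- ranking[keep, , drop = FALSE]
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("age_ranking", "data.frame")
  out
}
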