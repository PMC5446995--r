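# Plain-text IO for the formats the pipeline exchanges: expression as
# Matrix Market + gene/cell sidecars or dense TSV, labels / rankings /
# annotations / homolog tables as TSV, gene sets as GMT, ground truth and
# run manifests as JSON.

#' Read an expression matrix
#'
#' `path` may be a dense TSV (genes in rows, first column gene symbol, one
#' column per cell) or a Matrix Market `.mtx` file with `<path>.genes.tsv`
#' and `<path>.cells.tsv` sidecars (one id per line).
#'
#' @param path file path.
#' @return dense genes x cells numeric matrix.
#' @export
read_expression <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".genes.tsv"))
    cells <- readLines(paste0(path, ".cells.tsv"))
    dimnames(m) <- list(genes, cells)
    return(m)
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as Matrix Market plus sidecars
#'
#' @param expr genes x cells matrix.
#' @param path output `.mtx` path; `<path>.genes.tsv` and `<path>.cells.tsv`
#'   are written alongside.
#' @export
write_expression_mtx <- function(expr, path) {
  Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), path)
  writeLines(rownames(expr), paste0(path, ".genes.tsv"))
  writeLines(colnames(expr), paste0(path, ".cells.tsv"))
  invisible(path)
}

#' Read / write cell labels
#'
#' Two-column TSV `cell_id`, `type`.
#' @param path file path.
#' @return named character vector (cell id -> type).
#' @export
read_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_labels
#' @param labels named vector as returned by [read_labels()].
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(cell_id = names(labels), type = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an age-association table
#'
#' TSV with columns `gene`, `p`, `direction`; other dialects are reduced to
#' this form with `column_map`, a named character vector mapping the three
#' required names to the file's column names.
#'
#' @param path file path.
#' @param column_map optional named character vector, e.g.
#'   `c(gene = "symbol", p = "P", direction = "dir")`.
#' @return data.frame with columns `gene`, `p`, `direction`.
#' @export
read_age_table <- function(path, column_map = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(df))
        stop_config("column '%s' not found in %s", column_map[[std]], path)
      df[[std]] <- df[[column_map[[std]]]]
    }
  }
  df[c("gene", "p", "direction")]
}

#' Write an age ranking as TSV (position, gene, score)
#'
#' @param ranking an `age_ranking`.
#' @param path file path.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking[c("position", "gene", "score")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @return `read_ranking()` returns an `age_ranking`.
#' @export
read_ranking <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(gene = as.character(df$gene), score = df$score,
                    position = df$position, stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("age_ranking", "data.frame")
  out
}

#' Read / write gene sets in GMT format
#'
#' One line per set: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) if (length(x) > 2) x[-(1:2)] else character())
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector (recycled).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("ctenrich", length(sets))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene set catalog as GMT
#'
#' Enriched sets keep their type names; the non-specific set is written as
#' `nonspecific`. The threshold is recorded in the description field.
#'
#' @param catalog a `gene_set_catalog`.
#' @param path file path.
#' @export
write_catalog_gmt <- function(catalog, path) {
  sets <- c(catalog$enriched, list(nonspecific = catalog$nonspecific))
  write_gmt(sets, path, descriptions = sprintf("tau=%g", catalog$tau))
}

#' Read GO annotations from TSV or GAF 2.x
#'
#' TSV needs columns `gene`, `term_id` and optionally `term_name`; GAF
#' files (detected by a `!gaf-version` header or `.gaf` extension) use
#' DB Object Symbol (column 3), GO ID (column 5) and Aspect (column 9).
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `term_id`, `term_name` (and
#'   `domain` for GAF input), duplicates removed.
#' @export
read_go_annotations <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\\.gaf(\\.|$)", path) || startsWith(first, "!")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(gene = vapply(parts, `[`, character(1), 3),
                     term_id = vapply(parts, `[`, character(1), 5),
                     term_name = vapply(parts, `[`, character(1), 5),
                     domain = vapply(parts, `[`, character(1), 9),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!"term_name" %in% names(df)) df$term_name <- df$term_id
    df <- df[intersect(c("gene", "term_id", "term_name", "domain"), names(df))]
  }
  validate_go_annotations(df)
}

#' Read a homolog table (Homologene dialect or flattened) into a 1:1 map
#'
#' @param path TSV path; see [ortholog_map()] for accepted columns.
#' @return an `ortholog_map`.
#' @export
read_homolog_table <- function(path) {
  ortholog_map(read.delim(path, stringsAsFactors = FALSE))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
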