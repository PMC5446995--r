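# Cell-type profiles: from a genes x cells expression matrix to per-type
# average standardized expression and threshold-derived gene sets.

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_config("expression must be a numeric genes x cells matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_config("expression must carry gene symbols as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(expr)))
    stop_config("duplicate gene symbols in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop_config("duplicate cell ids in expression matrix")
  if (any(!is.finite(expr)) || any(expr < 0))
    stop_config("expression values must be finite and non-negative")
  invisible(expr)
}

#' Remove genes with zero reads in every cell
#'
#' @param expr non-negative genes x cells matrix with gene symbols as
#'   rownames and cell ids as colnames.
#' @return the matrix restricted to genes with at least one positive value;
#'   the number of removed genes is recorded in attribute `n_zero_removed`.
#'   Errors if no gene survives.
#' @export
filter_zero_genes <- function(expr) {
  validate_expression(expr)
  keep <- rowSums(expr > 0) > 0
  if (!any(keep)) stop_config("all genes have zero reads in every cell; nothing to analyze")
  out <- expr[keep, , drop = FALSE]
  attr(out, "n_zero_removed") <- sum(!keep)
  out
}

#' Standardize log expression per gene
#'
#' Computes `z = (y - mean(y)) / sd(y)` per gene, where `y = log(x + 1)`
#' (natural log) and `sd` is the sample standard deviation (n - 1
#' denominator). Genes whose log values are constant across cells get a zero
#' row and are flagged; they can never be called enriched, and fall in the
#' non-specific category — the conservative outcome.
#'
#' @param expr expression matrix, all-zero genes already removed.
#' @param sd_denominator `"n-1"` (default, sample SD) or `"n"` (population
#'   SD); standardization is scale-invariant downstream, the toggle exists
#'   for reproducing intermediates.
#' @return genes x cells z matrix with attribute `constant_genes` (character
#'   vector of flagged genes).
#' @export
standardize_expression <- function(expr, sd_denominator = c("n-1", "n")) {
  validate_expression(expr)
  sd_denominator <- match.arg(sd_denominator)
  n <- ncol(expr)
  if (n < 2) stop_config("standardization needs at least 2 cells (got %d)", n)
  y <- log1p(expr)
  mu <- rowMeans(y)
  centered <- y - mu
  ss <- rowSums(centered^2)
  denom <- if (sd_denominator == "n-1") n - 1 else n
  s <- sqrt(ss / denom)
  constant <- s == 0
  s[constant] <- 1  # zero rows stay zero
  z <- centered / s
  z[constant, ] <- 0
  attr(z, "constant_genes") <- rownames(expr)[constant]
  z
}

validate_annotation <- function(z, ann) {
  if (is.null(names(ann)))
    stop_config("cell annotation must be a named vector (cell id -> type label)")
  missing <- setdiff(colnames(z), names(ann))
  if (length(missing) > 0)
    stop_config("cells without a type label: %s",
                paste(head(missing, 5), collapse = ", "))
  invisible(ann)
}

#' Average standardized expression per cell type
#'
#' Groups cells by type and averages the z values; the profile columns are
#' ordered lexicographically by label so results are deterministic.
#' Annotation levels with zero cells in the matrix are dropped with a
#' warning. Because each gene's z values have mean zero over all cells, the
#' cell-count-weighted row sums of the profile are zero.
#'
#' @param z standardized matrix from [standardize_expression()].
#' @param ann named vector or factor, cell id -> type label; every column of
#'   `z` must be labeled.
#' @return genes x types matrix of average standardized expression, with
#'   attribute `n_cells` (named integer vector of cells per type).
#' @export
type_profile <- function(z, ann) {
  validate_annotation(z, ann)
  lab <- as.character(ann[colnames(z)])
  if (is.factor(ann)) {
    unused <- setdiff(levels(ann), lab)
    if (length(unused) > 0)
      warning(sprintf("dropping label(s) with zero cells: %s",
                      paste(unused, collapse = ", ")))
  }
  types <- sort(unique(lab))
  fac <- factor(lab, levels = types)
  counts <- as.integer(table(fac))
  # rowsum() aggregates cells (rows of t(z)) by type in one pass
  sums <- t(rowsum(t(z), fac))
  profile <- sweep(sums, 2, counts, "/")
  dimnames(profile) <- list(rownames(z), types)
  attr(profile, "n_cells") <- setNames(counts, types)
  profile
}

#' Derive enriched and non-specific gene sets from a profile
#'
#' A gene is enriched in type `c` when its average standardized expression
#' there is strictly greater than `tau`; it is non-specific when its
#' absolute average standardized expression is strictly less than `tau` in
#' every type. Both inequalities are strict, so a gene sitting exactly at
#' the threshold is in neither category. A gene may be enriched in several
#' types; the non-specific set is disjoint from every enriched set by
#' construction.
#'
#' @param profile genes x types matrix from [type_profile()].
#' @param tau positive threshold in SD units (default 2).
#' @return an object of class `gene_set_catalog`: list with `enriched`
#'   (type -> character vector), `nonspecific` (character vector) and `tau`.
#' @export
derive_gene_sets <- function(profile, tau = 2) {
  assert_scalar_number(tau, "tau", lower = 0, strict = TRUE)
  if (!is.matrix(profile) || nrow(profile) == 0 || ncol(profile) == 0)
    stop_config("profile must be a non-empty genes x types matrix")
  genes <- rownames(profile)
  enriched <- lapply(seq_len(ncol(profile)),
                     function(j) genes[profile[, j] > tau])
  names(enriched) <- colnames(profile)
  maxabs <- apply(abs(profile), 1, max)
  structure(list(enriched = enriched,
                 nonspecific = genes[maxabs < tau],
                 tau = tau),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  sizes <- lengths(x$enriched)
  cat(sprintf("gene_set_catalog: %d enriched sets (sizes %s), %d non-specific genes, tau = %g\n",
              length(x$enriched),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "0",
              length(x$nonspecific), x$tau))
  invisible(x)
}
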