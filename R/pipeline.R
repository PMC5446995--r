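# End-to-end orchestration: validate a run configuration, execute every
# stage with one master seed, and emit result tables, a log and a
# machine-readable manifest.

#' Run configuration
#'
#' Exactly one of two modes must be active: real-data paths (`expression`,
#' `labels`, `age_table`, optionally `homology` and `annotations`) or
#' synthetic mode (`synthetic` = a [simulation_config()]).
#'
#' @param expression,labels,age_table,homology,annotations input file paths
#'   (real-data mode). `age_table_column_map` is passed to
#'   [read_age_table()].
#' @param synthetic a [simulation_config()] (synthetic mode).
#' @param tau enrichment threshold (study default 2).
#' @param B permutation count (study default 10000).
#' @param size_bounds strict GO intersection-size bounds (study default
#'   10 and 200).
#' @param n_go_terms,go_size_range synthetic-mode GO annotation shape.
#' @param seed master seed for the whole run.
#' @param out_dir output directory (created if missing).
#' @param age_table_column_map optional named vector for foreign dialects.
#' @return a validated `run_config`.
#' @export
run_config <- function(expression = NULL, labels = NULL, age_table = NULL,
                       homology = NULL, annotations = NULL, synthetic = NULL,
                       tau = 2, B = 10000, size_bounds = c(10, 200),
                       n_go_terms = 50, go_size_range = c(20, 80),
                       seed = 1L, out_dir = tempfile("ctenrich_run_"),
                       age_table_column_map = NULL) {
  real <- !is.null(expression) || !is.null(labels) || !is.null(age_table)
  synth <- !is.null(synthetic)
  if (real && synth)
    stop_config("config error: both real-data paths and synthetic mode supplied; choose one")
  if (!real && !synth)
    stop_config("config error: neither real-data paths nor synthetic mode supplied")
  if (real && (is.null(expression) || is.null(labels) || is.null(age_table)))
    stop_config("real-data mode needs expression, labels and age_table paths")
  if (synth && !inherits(synthetic, "sim_config"))
    stop_config("'synthetic' must be a simulation_config()")
  structure(list(expression = expression, labels = labels,
                 age_table = age_table, homology = homology,
                 annotations = annotations, synthetic = synthetic,
                 tau = assert_scalar_number(tau, "tau", lower = 0, strict = TRUE),
                 B = assert_count(B, "B", lower = 1L),
                 size_bounds = size_bounds,
                 n_go_terms = assert_count(n_go_terms, "n_go_terms", lower = 1L),
                 go_size_range = go_size_range,
                 seed = assert_count(seed, "seed"),
                 out_dir = out_dir,
                 age_table_column_map = age_table_column_map),
            class = "run_config")
}

#' Run the full analysis
#'
#' Stages: load or simulate inputs; remove all-zero genes; standardize;
#' per-type profile; derive enriched and non-specific sets; ortholog-map
#' sets and restrict the ranking; build the signed ranking; observed
#' AUROCs; label-permutation null; empirical p/q; GO scan. Results are
#' written under `cfg$out_dir` and also returned.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with `enrichment` (data.frame), `go_scan`
#'   (data.frame), `catalog`, `ranking`, `null`, `manifest`, `out_dir`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("ctenrich")),
                   seed = cfg$seed, tau = cfg$tau, B = cfg$B,
                   size_bounds = cfg$size_bounds,
                   mode = if (is.null(cfg$synthetic)) "real" else "synthetic")

  if (!is.null(cfg$synthetic)) {
    sim <- stage("simulate", {
      sim <- simulate_single_cell(cfg$synthetic)
      sim$age_table <- simulate_age_table(sim$truth, cfg$synthetic)
      genes <- sort(unique(sim$age_table$gene))
      sim$annotations <- simulate_go_annotations(
        genes, cfg$n_go_terms, cfg$go_size_range, seed = cfg$synthetic$seed + 2L)
      sim
    })
    expr <- sim$expr; labels <- sim$labels
    age_table <- sim$age_table; annotations <- sim$annotations
    map <- identity_map(rownames(expr))
    stage("write inputs", {
      write_expression_mtx(expr, file.path(cfg$out_dir, "expression.mtx"))
      write_labels(labels, file.path(cfg$out_dir, "labels.tsv"))
      write_tsv(age_table, file.path(cfg$out_dir, "age_table.tsv"))
      write_tsv(annotations, file.path(cfg$out_dir, "annotations.tsv"))
      jsonlite::write_json(
        list(marker_map = sim$truth$marker_map,
             nonspecific_genes = sim$truth$nonspecific_genes),
        file.path(cfg$out_dir, "ground_truth.json"))
    })
    logf("simulated %d genes x %d cells, %d types", nrow(expr), ncol(expr),
         cfg$synthetic$n_types)
  } else {
    expr <- stage("read expression", read_expression(cfg$expression))
    labels <- stage("read labels", read_labels(cfg$labels))
    age_table <- stage("read age table",
                       read_age_table(cfg$age_table, cfg$age_table_column_map))
    annotations <- if (!is.null(cfg$annotations))
      stage("read annotations", read_go_annotations(cfg$annotations)) else NULL
    map <- if (!is.null(cfg$homology))
      stage("read homology", read_homolog_table(cfg$homology))
    else identity_map(rownames(expr))
  }

  expr <- stage("filter zero genes", filter_zero_genes(expr))
  manifest$n_zero_removed <- attr(expr, "n_zero_removed")
  logf("removed %d all-zero genes; %d genes retained",
       manifest$n_zero_removed, nrow(expr))

  z <- stage("standardize", standardize_expression(expr))
  manifest$n_constant_genes <- length(attr(z, "constant_genes"))
  profile <- stage("type profile", type_profile(z, labels))
  catalog <- stage("derive gene sets", derive_gene_sets(profile, cfg$tau))
  catalog_h <- stage("map sets", map_sets(catalog, map))
  manifest$n_unmapped <- as.list(attr(catalog_h, "n_unmapped"))

  ranking <- stage("build ranking", build_signed_ranking(age_table))
  # background rule: ranking genes must be images of assayed genes
  assayed_map <- map[map$mouse %in% rownames(expr), , drop = FALSE]
  class(assayed_map) <- c("ortholog_map", "data.frame")
  ranking <- stage("restrict ranking", restrict_ranking(ranking, assayed_map))
  manifest$n_ranking_genes <- nrow(ranking)

  observed <- stage("observed AUROCs",
                    suppressWarnings(observed_aurocs(catalog_h, ranking)))
  null <- stage("permutation null",
                permutation_null(z, labels, ranking, map, tau = cfg$tau,
                                 B = cfg$B, seed = cfg$seed))
  enrichment <- stage("empirical p/q",
                      empirical_pq(observed[!is.na(observed)], null))
  n_cells <- attr(profile, "n_cells")
  enrichment$cell_count <- unname(n_cells[enrichment$type])
  enrichment$gene_count <- vapply(enrichment$type, function(ty) {
    if (ty == "nonspecific") length(catalog_h$nonspecific)
    else length(catalog_h$enriched[[ty]])
  }, integer(1))
  enrichment <- enrichment[c("type", "cell_count", "gene_count",
                             "permuted_mean", "auroc", "empirical_p",
                             "empirical_q", "B_effective")]
  manifest$n_sets_skipped <- sum(is.na(observed))

  go_scan <- if (!is.null(annotations)) {
    stage("GO scan", suppressWarnings(
      go_auroc_scan(catalog_h, ranking, annotations, cfg$size_bounds)))
  } else {
    data.frame()
  }

  stage("write results", {
    write_tsv(enrichment, file.path(cfg$out_dir, "enrichment.tsv"))
    if (nrow(go_scan) > 0 || !is.null(annotations))
      write_tsv(go_scan, file.path(cfg$out_dir, "go_scan.tsv"))
    write_ranking(ranking, file.path(cfg$out_dir, "ranking.tsv"))
    write_catalog_gmt(catalog_h, file.path(cfg$out_dir, "gene_sets.gmt"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  logf("run complete: %d sets tested, %d GO rows", nrow(enrichment), nrow(go_scan))

  invisible(list(enrichment = enrichment, go_scan = go_scan,
                 catalog = catalog_h, ranking = ranking, null = null,
                 manifest = manifest, out_dir = cfg$out_dir))
}

#' ROC-style ordered-overlap curve of a set in a ranking
#'
#' Walks the ranking from the up-regulated end; tie groups (equal signed
#' score) advance diagonally in one step, so the trapezoid area under the
#' emitted points equals the midrank AUROC exactly.
#'
#' @param set character vector of gene symbols.
#' @param ranking an `age_ranking`.
#' @return data.frame with columns `fpr` (non-member fraction passed) and
#'   `tpr` (member fraction passed), starting at (0, 0), ending at (1, 1).
#' @export
roc_curve_table <- function(set, ranking) {
  member <- ranking$gene %in% set
  n1 <- sum(member); n2 <- sum(!member)
  if (n1 == 0 || n2 == 0)
    stop_config("degenerate set: needs members and non-members in the ranking")
  groups <- factor(ranking$score, levels = unique(ranking$score))
  tp <- cumsum(tapply(member, groups, sum))
  fp <- cumsum(tapply(!member, groups, sum))
  data.frame(fpr = c(0, unname(fp) / n2), tpr = c(0, unname(tp) / n1))
}

#' Human-readable run report
#'
#' Summarizes significant cell types, top GO rows, and writes one ROC-style
#' curve table per tested set (the tabular analogue of the study's ROC
#' figure). The report references only numbers computed in `results`.
#'
#' @param results the list returned by [run_full_analysis()].
#' @param path output file (default `report.txt` in the run's out_dir).
#' @param q_cutoff significance cutoff on the empirical q (default 0.05).
#' @return (invisibly) the report path.
#' @export
write_report <- function(results, path = file.path(results$out_dir, "report.txt"),
                         q_cutoff = 0.05) {
  enr <- results$enrichment
  if (is.null(enr) || nrow(enr) == 0) {
    warning("empty results; writing stub report")
    writeLines("ctenrich report: no results to summarize", path)
    return(invisible(path))
  }
  lines <- c("ctenrich run report", strrep("=", 60))
  sig <- enr[!is.na(enr$empirical_q) & enr$empirical_q < q_cutoff, , drop = FALSE]
  lines <- c(lines, sprintf("significant cell types (empirical q < %g): %d",
                            q_cutoff, nrow(sig)))
  fmt_row <- function(r) sprintf("  %-20s AUROC %.3f  permuted %.3f  p %.4g  q %.4g",
                                 r$type, r$auroc, r$permuted_mean,
                                 r$empirical_p, r$empirical_q)
  for (i in seq_len(nrow(sig))) lines <- c(lines, fmt_row(sig[i, ]))
  lines <- c(lines, "", "all sets by empirical p:")
  for (i in seq_len(nrow(enr))) lines <- c(lines, fmt_row(enr[i, ]))
  if (!is.null(results$go_scan) && nrow(results$go_scan) > 0) {
    top <- head(results$go_scan, 10)
    lines <- c(lines, "", "top GO rows (by q):")
    lines <- c(lines, sprintf("  %-14s %-12s n %-4d AUROC %.3f  p %.4g  q %.4g",
                              top$type, top$term_id, top$n_intersection,
                              top$auroc, top$p, top$q))
  }
  curve_dir <- file.path(dirname(path), "curves")
  dir.create(curve_dir, showWarnings = FALSE)
  sets <- c(results$catalog$enriched,
            list(nonspecific = results$catalog$nonspecific))
  for (nm in names(sets)) {
    tab <- tryCatch(roc_curve_table(sets[[nm]], results$ranking),
                    error = function(e) NULL)
    if (!is.null(tab))
      write_tsv(tab, file.path(curve_dir, paste0("curve_", nm, ".tsv")))
  }
  lines <- c(lines, "", sprintf("ROC-style curve tables: %s/", curve_dir))
  writeLines(lines, path)
  invisible(path)
}
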