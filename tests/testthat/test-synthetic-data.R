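test_that("configuration validation names the violated constraint", {
  expect_error(simulation_config(n_types = 10, markers_per_type = 300,
                                 n_genes = 1000),
               "markers_per_type \\* n_types")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(injected_up_types = "nosuch"),
               "injected type")
  expect_error(simulation_config(n_types = 2, injected_up_types = "type01",
                                 injected_down_types = "type01"),
               "both up and down")
})

test_that("simulation is deterministic and planted structure is honored", {
  cfg <- simulation_config(n_types = 4, cells_per_type = 5, n_genes = 200,
                           markers_per_type = 10, seed = 11)
  a <- simulate_single_cell(cfg)
  b <- simulate_single_cell(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$labels, b$labels)
  expect_true(all(a$expr >= 0))
  # marker sets pairwise disjoint, nonspecific disjoint from all markers
  all_markers <- unlist(a$truth$marker_map)
  expect_false(anyDuplicated(all_markers) > 0)
  expect_length(intersect(all_markers, a$truth$nonspecific_genes), 0)
  # markers elevated in exactly their own type (on mean log expression)
  y <- log1p(a$expr)
  for (t in names(a$truth$marker_map)) {
    own <- rowMeans(y[a$truth$marker_map[[t]], a$labels == t, drop = FALSE])
    other <- rowMeans(y[a$truth$marker_map[[t]], a$labels != t, drop = FALSE])
    expect_gt(min(own - other), 0)
  }
})

test_that("one type means a zero profile and no enriched genes", {
  cfg <- simulation_config(n_types = 1, cells_per_type = 10, n_genes = 50,
                           markers_per_type = 5, seed = 2)
  sim <- simulate_single_cell(cfg)
  z <- standardize_expression(filter_zero_genes(sim$expr))
  prof <- type_profile(z, sim$labels)
  expect_lt(max(abs(prof)), 1e-9)
  expect_identical(lengths(derive_gene_sets(prof, 2)$enriched),
                   c(type01 = 0L))
})

test_that("zero marker effect gives chance-level recovery", {
  # planted markers with no expression effect cannot be preferentially
  # recovered: average capture stays below 20% of each type's planted set
  recov <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_types = 8, cells_per_type = 4, n_genes = 400,
                             markers_per_type = 20, marker_effect = 0,
                             seed = 100 + s)
    sim <- simulate_single_cell(cfg)
    z <- standardize_expression(filter_zero_genes(sim$expr))
    marker_recovery(derive_gene_sets(type_profile(z, sim$labels), 2),
                    sim$truth)
  }, numeric(1))
  expect_lt(mean(recov), 0.20)
})

test_that("balanced few-type designs cannot cross tau = 2: the z-bar bound", {
  # For a gene elevated in one of C equal types (k of n cells), the average
  # standardized expression is bounded by sqrt((n-k)/k) * sqrt((n-1)/n),
  # which is 1.99 < 2 for 5 types of 20 cells: recovery is structurally 0
  # at tau = 2 no matter how large the effect. (Real data escapes the bound
  # through many small types.)
  cfg <- simulation_config(n_types = 5, cells_per_type = 20, n_genes = 1000,
                           markers_per_type = 50, marker_effect = 3,
                           noise_sd = 1, seed = 7)
  sim <- simulate_single_cell(cfg)
  z <- standardize_expression(filter_zero_genes(sim$expr))
  prof <- type_profile(z, sim$labels)
  bound <- sqrt(80 / 20) * sqrt(99 / 100)
  expect_lt(max(prof), bound + 1e-9)
  expect_identical(marker_recovery(derive_gene_sets(prof, 2), sim$truth), 0)
})

test_that("paper-like type geometry recovers >= 90% of planted markers", {
  cfg <- recovery_world_cfg(seed = 7)
  sim <- simulate_single_cell(cfg)
  z <- standardize_expression(filter_zero_genes(sim$expr))
  rec <- marker_recovery(derive_gene_sets(type_profile(z, sim$labels), 2),
                         sim$truth)
  expect_gte(rec, 0.90)
})

test_that("recovery is monotone in marker effect", {
  mean_recovery <- function(effect) {
    mean(vapply(1:20, function(s) {
      cfg <- recovery_world_cfg(seed = 300 + s, marker_effect = effect)
      sim <- simulate_single_cell(cfg)
      z <- standardize_expression(filter_zero_genes(sim$expr))
      marker_recovery(derive_gene_sets(type_profile(z, sim$labels), 2),
                      sim$truth)
    }, numeric(1)))
  }
  rec <- vapply(c(0, 2, 4), mean_recovery, numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_lt(rec[1], 0.2)
  expect_gt(rec[3], 0.9)
})

test_that("age table carries planted shifts into p and direction", {
  cfg <- simulation_config(n_types = 4, cells_per_type = 5, n_genes = 400,
                           markers_per_type = 50, seed = 5,
                           injected_up_types = "type02",
                           injected_down_types = "type03",
                           set_shift = 3, nonspecific_shift = -1)
  sim <- simulate_single_cell(cfg)
  tab <- simulate_age_table(sim$truth, cfg)
  expect_setequal(tab$gene, rownames(sim$expr))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  stat <- attr(tab, "statistic")
  up <- sim$truth$marker_map$type02
  down <- sim$truth$marker_map$type03
  neutral <- sim$truth$marker_map$type01
  expect_gt(mean(stat[up]), mean(stat[neutral]) + 1)
  expect_lt(mean(stat[down]), mean(stat[neutral]) - 1)
  expect_lt(mean(stat[sim$truth$nonspecific_genes]), -0.5)
  # determinism
  expect_identical(tab, simulate_age_table(sim$truth, cfg))
})

test_that("single-gene truth yields a one-row valid table", {
  truth <- list(marker_map = list(), nonspecific_genes = "G1")
  cfg <- simulation_config(n_types = 1, cells_per_type = 2, n_genes = 1,
                           markers_per_type = 0, seed = 9)
  tab <- simulate_age_table(truth, cfg)
  expect_identical(nrow(tab), 1L)
  expect_true(tab$p > 0 && tab$p <= 1)
  expect_true(tab$direction %in% c("up", "down"))
})

test_that("GO annotation generator honors sizes, seed and empty input", {
  g <- sprintf("g%02d", 1:30)
  one <- simulate_go_annotations(g, n_terms = 1, size_range = c(5, 5), seed = 3)
  expect_identical(nrow(one), 5L)
  expect_identical(length(unique(one$term_id)), 1L)
  a <- simulate_go_annotations(g, 10, c(3, 8), seed = 42)
  expect_identical(a, simulate_go_annotations(g, 10, c(3, 8), seed = 42))
  sizes <- table(a$term_id)
  expect_true(all(sizes >= 3 & sizes <= 8))
  expect_identical(nrow(simulate_go_annotations(character(), 3, c(1, 2))), 0L)
  expect_error(simulate_go_annotations(g, 3, c(8, 3)), "inverted")
  expect_error(simulate_go_annotations(g, 3, c(1, 99)), "size_range")
})
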