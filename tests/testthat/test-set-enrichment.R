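test_that("auroc handles the canonical hand cases", {
  r <- make_ranking(letters[1:6], 6:1)
  # perfect separation
  expect_equal(as.numeric(auroc(letters[1:3], r)), 1)
  # positions {1,3,4} of 6 -> 7/9 by all-pairs enumeration
  expect_equal(as.numeric(auroc(letters[c(1, 3, 4)], r)), 7 / 9,
               tolerance = 1e-12)
  # symmetry under ranking reversal
  rev_r <- make_ranking(letters[1:6], 1:6)
  expect_equal(as.numeric(auroc(letters[c(1, 3, 4)], rev_r)),
               1 - 7 / 9, tolerance = 1e-12)
  # set members absent from the ranking are dropped and counted
  a <- auroc(c("a", "c", "d", "nothere"), r)
  expect_equal(as.numeric(a), 7 / 9, tolerance = 1e-12)
  expect_identical(attr(a, "n_dropped"), 1L)
  # errors distinguish empty set from empty complement
  expect_error(auroc("nothere", r), "empty effective set")
  expect_error(auroc(letters[1:6], r), "empty complement")
})

test_that("auroc equals the brute-force all-pairs oracle on random instances", {
  for (s in 1:200) {
    inst <- random_instance(s)
    expect_equal(as.numeric(auroc(inst$set, inst$ranking)),
                 brute_auroc(inst$set, inst$ranking), tolerance = 1e-12)
  }
})

test_that("complement swap sums to one for tie-free rankings", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    r <- make_ranking(sprintf("g%02d", 1:n), sample(n))  # distinct scores
    set <- sample(r$gene, sample(n - 1, 1))
    comp <- setdiff(r$gene, set)
    expect_equal(as.numeric(auroc(set, r)) + as.numeric(auroc(comp, r)), 1,
                 tolerance = 1e-12)
  }
})

test_that("mw_pvalue approximates exact enumeration and oracle wilcox.test", {
  r <- make_ranking(letters[1:6], 6:1)
  # exhaustive C(6,3) oracle for the {1,3,4} placement
  combos <- combn(6, 3)
  obs_a <- brute_auroc(letters[c(1, 3, 4)], r)
  null_a <- apply(combos, 2, function(ix) brute_auroc(letters[ix], r))
  exact_two_sided <- mean(abs(null_a - 0.5) >= abs(obs_a - 0.5) - 1e-12)
  expect_equal(exact_two_sided, 0.4)  # sanity on the oracle itself
  p <- mw_pvalue(letters[c(1, 3, 4)], r)
  expect_lt(abs(p - exact_two_sided), 0.15)  # documented tiny-n tolerance

  # null center: AUROC = 0.5 exactly at large n -> p ~ 1
  big <- make_ranking(sprintf("g%04d", 1:1000), 1000:1)
  balanced <- big$gene[c(seq(1, 999, by = 2))]
  expect_equal(as.numeric(auroc(balanced, big)), 0.5, tolerance = 3e-3)
  expect_gt(mw_pvalue(balanced, big), 0.9)

  # planted strong set: all members in the top decile of N = 1000
  strong <- big$gene[1:100]
  expect_lt(mw_pvalue(strong, big), 1e-10)

  # agreement with stats::wilcox.test (normal approximation, corrected)
  set.seed(55)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    r2 <- make_ranking(sprintf("g%02d", 1:n), sample(n))
    set <- sample(r2$gene, sample(5:(n - 5), 1))
    rr <- setNames(n + 1 - r2$position, r2$gene)
    w <- wilcox.test(rr[set], rr[setdiff(r2$gene, set)],
                     exact = FALSE, correct = TRUE)
    expect_equal(mw_pvalue(set, r2), w$p.value, tolerance = 1e-9)
  }
})

test_that("permutation null is reproducible and the two engines agree", {
  cfg <- simulation_config(n_types = 6, cells_per_type = 4, n_genes = 300,
                           markers_per_type = 10, marker_effect = 3,
                           seed = 5)
  sim <- simulate_single_cell(cfg)
  z <- standardize_expression(filter_zero_genes(sim$expr))
  tab <- simulate_age_table(sim$truth, cfg)
  r <- build_signed_ranking(tab[tab$gene %in% rownames(z), ])
  map <- identity_map(rownames(z))
  a <- permutation_null(z, sim$labels, r, map, tau = 1.5, B = 50, seed = 3)
  b <- permutation_null(z, sim$labels, r, map, tau = 1.5, B = 50, seed = 3)
  expect_identical(a$auroc, b$auroc)
  d <- permutation_null(z, sim$labels, r, map, tau = 1.5, B = 50, seed = 4)
  expect_false(identical(a$auroc, d$auroc))
  rr <- permutation_null(z, sim$labels, r, map, tau = 1.5, B = 50, seed = 3,
                         engine = "r")
  expect_equal(a$auroc, rr$auroc, tolerance = 1e-12)
  expect_identical(colnames(a$auroc), c(sort(unique(sim$labels)), "nonspecific"))
  # an unreachable threshold produces NA columns, not a crash
  high <- permutation_null(z, sim$labels, r, map, tau = 50, B = 5, seed = 1)
  expect_true(all(is.na(high$auroc[, 1:6])))
  expect_error(permutation_null(z, sim$labels, r, map, B = 0), "B")
})

test_that("rankings carrying unassayed genes are restricted to the assayed universe", {
  # regression: the ranking may contain genes absent from the (zero-
  # filtered) expression matrix; midranks must be recomputed on the shared
  # universe, or permuted AUROCs leave [0, 1]
  cfg <- simulation_config(n_types = 6, cells_per_type = 4, n_genes = 300,
                           markers_per_type = 10, marker_effect = 4,
                           baseline_mean = -1, baseline_sd = 2, seed = 19)
  sim <- simulate_single_cell(cfg)
  expr <- filter_zero_genes(sim$expr)
  expect_lt(nrow(expr), 300)  # some genes were all-zero and dropped
  z <- standardize_expression(expr)
  tab <- simulate_age_table(sim$truth, cfg)  # full 300-gene table
  r <- build_signed_ranking(tab)
  map <- identity_map(rownames(sim$expr))
  null <- permutation_null(z, sim$labels, r, map, tau = 1.5, B = 30, seed = 4)
  ok <- null$auroc[!is.na(null$auroc)]
  expect_true(all(ok >= 0 & ok <= 1))
  # identical to passing the pre-restricted ranking explicitly
  r_sub <- build_signed_ranking(tab[tab$gene %in% rownames(z), ])
  null2 <- permutation_null(z, sim$labels, r_sub, map, tau = 1.5, B = 30,
                            seed = 4)
  expect_identical(null$auroc, null2$auroc)
})

test_that("empirical p hits the 1/B floor and respects the two-sided rule", {
  set.seed(8)
  A <- matrix(rnorm(20 * 2, mean = 0.5, sd = 0.05), 20, 2,
              dimnames = list(NULL, c("t1", "t2")))
  null <- fake_null(A)
  # observed beyond every permuted value -> floor 1/B
  pq <- empirical_pq(c(t1 = 0.99, t2 = 0.5), null)
  expect_equal(pq$empirical_p[pq$type == "t1"], 1 / 20)
  # observed at the permuted mean -> every shuffle is at least as extreme
  m2 <- mean(A[, "t2"])
  pq2 <- empirical_pq(c(t2 = m2), null)
  expect_equal(pq2$empirical_p, 1)
  # hand-computed two-sided count
  obs <- 0.54
  m1 <- mean(A[, "t1"])
  want <- max(mean(abs(A[, "t1"] - m1) >= abs(obs - m1)), 1 / 20)
  pq3 <- empirical_pq(c(t1 = obs), null)
  expect_equal(pq3$empirical_p, want)
  expect_error(empirical_pq(c(nosuch = 0.5), null), "absent from")
  expect_error(empirical_pq(0.5, null), "named")
})

test_that("q reduces to p for a single type and is monotone in p", {
  set.seed(13)
  A <- matrix(rnorm(200, 0.5, 0.05), ncol = 1, dimnames = list(NULL, "only"))
  null <- fake_null(A)
  for (obs in c(0.62, 0.55, 0.51)) {
    pq <- empirical_pq(c(only = obs), null)
    expect_equal(pq$empirical_q, pq$empirical_p, tolerance = 1 / 200 + 1e-12)
  }
  # monotonicity across types on a multi-type null
  A2 <- matrix(rnorm(500 * 6, 0.5, 0.05), 500, 6,
               dimnames = list(NULL, paste0("t", 1:6)))
  null2 <- fake_null(A2)
  obs <- setNames(c(0.70, 0.62, 0.55, 0.52, 0.50, 0.45), paste0("t", 1:6))
  pq <- empirical_pq(obs, null2)
  expect_true(all(diff(pq$empirical_p) >= 0))
  expect_true(all(diff(pq$empirical_q) >= -1e-12))
})

test_that("min-p FDR matches the independence expectation with 49 types", {
  # With C independent types and an observed p at the 1/B floor, q is the
  # chance a shuffle attains the floor anywhere: about 1 - (1 - 1/B)^C.
  set.seed(99)
  B <- 2000; C <- 49
  A <- matrix(rnorm(B * C, 0.5, 0.05), B, C,
              dimnames = list(NULL, paste0("t", 1:C)))
  null <- fake_null(A)
  pq <- empirical_pq(setNames(c(0.999, rep(0.5, C - 1)), colnames(A)), null)
  q_floor <- pq$empirical_q[pq$type == "t1"]
  expect_equal(pq$empirical_p[pq$type == "t1"], 1 / B)
  expect_gt(q_floor, 0.012)
  expect_lt(q_floor, 0.038)  # analytic expectation ~ 0.0242
})

test_that("NA permutations are dropped column-wise with effective B", {
  A <- matrix(c(rnorm(40, 0.5, 0.03), rep(NA, 10), rnorm(30, 0.5, 0.03)),
              ncol = 2, dimnames = list(NULL, c("a", "b")))
  null <- fake_null(A)
  pq <- empirical_pq(c(a = 0.9, b = 0.9), null)
  expect_identical(pq$B_effective[order(pq$type)], c(40L, 30L))
  expect_equal(sort(pq$empirical_p), sort(c(1 / 40, 1 / 30)))
})

test_that("fixed_set_test applies Bonferroni over the sets actually tested", {
  set.seed(41)
  r <- make_ranking(sprintf("g%04d", 1:500), sample(500))
  sets <- c(lapply(1:5, function(i) sample(r$gene, 30)),
            list(sample(r$gene, 25)))
  names(sets) <- paste0("s", 1:6)
  res <- fixed_set_test(sets, r)
  expect_identical(attr(res, "m"), 6L)
  expect_equal(res$p_adj, pmin(1, 6 * res$p), tolerance = 1e-12)
  # a set with no ranking overlap is skipped and excluded from m
  sets$ghost <- c("zz1", "zz2")
  expect_warning(res2 <- fixed_set_test(sets, r), "skipped")
  expect_identical(attr(res2, "m"), 6L)
  expect_false("ghost" %in% res2$name)
})

test_that("a planted down-shifted housekeeping-like set is detected", {
  # effect 0.5 SD, |set| = 200, N = 10,000 (one fixed seed)
  set.seed(2024)
  n <- 10000
  genes <- sprintf("g%05d", 1:n)
  stat <- rnorm(n)
  hk <- sample(genes, 200)
  stat[genes %in% hk] <- stat[genes %in% hk] - 0.5
  r <- make_ranking(genes, stat)
  res <- fixed_set_test(list(housekeeping = hk, decoy = sample(genes, 200)), r)
  row <- res[res$name == "housekeeping", ]
  expect_lt(row$auroc, 0.5)
  expect_lt(row$p_adj, 0.05)
})
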