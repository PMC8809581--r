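test_that("gbi_swap performs the forced checkerboard swap", {
  gbi <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                dimnames = list(c("f1", "f2"), c("a", "b")))
  set.seed(1)
  out <- gbi_swap(gbi)
  expect_true(attr(out, "swapped"))
  expect_equal(unname(out[1, ]), c(0L, 1L))
  expect_equal(unname(out[2, ]), c(1L, 0L))
})

test_that("swaps preserve row and column sums over a long chain", {
  sim <- small_sim(seed = 8, n_flocks = 100)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  rs <- rowSums(gbi); cs <- colSums(gbi)
  set.seed(99)
  g <- gbi
  for (i in 1:10000) {
    g <- gbi_swap(g)
    if (i %% 500 == 0) {
      expect_identical(rowSums(g), rs)
      expect_identical(colSums(g), cs)
    }
  }
  expect_identical(rowSums(g), rs)
  expect_identical(colSums(g), cs)
  expect_false(identical(g, gbi))
})

test_that("degenerate matrices are flagged and returned unchanged", {
  same_rows <- matrix(1L, 3, 3,
                      dimnames = list(paste0("f", 1:3), letters[1:3]))
  set.seed(2)
  out <- gbi_swap(same_rows)
  expect_false(attr(out, "swapped"))
  expect_equal(unclass(out)[, ], same_rows[, ])
})

test_that("a swap-invariant statistic yields a degenerate null", {
  sim <- small_sim(seed = 14, n_flocks = 40)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  res <- serial_permutation_test(gbi, statistic = sum, n_swaps = 50, seed = 4)
  expect_true(all(res$null_values == sum(gbi)))
  expect_equal(res$p_value, 1)           # every chain value >= empirical
  expect_equal(res$p_corrected, 1)
  expect_equal(res$n_iterations, 50)
})

test_that("serial test is bit-reproducible and matches the generic path", {
  sim <- small_sim(seed = 16, n_flocks = 60)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  r1 <- serial_permutation_test(gbi, NULL, n_swaps = 30, seed = 7)
  r2 <- serial_permutation_test(gbi, NULL, n_swaps = 30, seed = 7)
  expect_identical(r1$null_values, r2$null_values)
  # generic R path with the equivalent statistic reproduces the fast chain
  r3 <- serial_permutation_test(
    gbi, statistic = function(g) flocknet:::gbi_modularity_stat(g, TRUE),
    n_swaps = 30, seed = 7)
  expect_equal(r1$null_values, r3$null_values, tolerance = 1e-12)
  expect_equal(r1$empirical, r3$empirical)
})

test_that("serial modularity test detects planted structure", {
  sim <- small_sim(seed = 31)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  res <- serial_permutation_test(gbi, NULL, n_swaps = 200, seed = 32)
  expect_lte(res$p_value, 0.05)
})

test_that("node-label permutations preserve the label multiset", {
  sim <- small_sim(seed = 6, n_flocks = 60)
  net <- build_flock_network(filter_individuals(build_gbi(sim$observations), 3),
                             sim_attributes(sim))
  res <- node_label_permutation_test(
    net, statistic = function(net, labels) sum(labels == "CACH"),
    n_perm = 40, seed = 3)
  expect_true(all(res$null_values == res$empirical))

  one_label <- stats::setNames(rep("A", nrow(net$nodes)), net$nodes$id)
  expect_error(node_label_permutation_test(net, one_label), "2 distinct")
})

test_that("assortativity permutation test flags strongly assorted networks", {
  sim <- small_sim(seed = 18, species_coupling = 0.8, p_conspecific_bias = 2)
  net <- build_flock_network(filter_individuals(build_gbi(sim$observations), 3),
                             sim_attributes(sim))
  res <- node_label_permutation_test(net, n_perm = 200, seed = 19)
  expect_lte(res$p_value, 0.01)
})

test_that("bootstrap replicates resample rows with columns frozen", {
  sim <- small_sim(seed = 12, n_flocks = 50)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  reps <- bootstrap_flocks(gbi, n_boot = 20, seed = 5)
  expect_length(reps, 20)
  for (r in reps[1:3]) {
    expect_equal(nrow(r), nrow(gbi))
    expect_identical(colnames(r), colnames(gbi))
  }
  single <- gbi[1, , drop = FALSE]
  reps1 <- bootstrap_flocks(single, n_boot = 5, seed = 1)
  for (r in reps1) expect_identical(unname(r), unname(single))
})

test_that("bootstrap modularity concentrates near the empirical value", {
  sim <- small_sim(seed = 25)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  emp <- flocknet:::gbi_modularity_stat(gbi, TRUE)
  reps <- bootstrap_flocks(gbi, n_boot = 60, seed = 26)
  boot_q <- vapply(reps, flocknet:::gbi_modularity_stat, numeric(1),
                   weighted = TRUE)
  expect_lt(abs(mean(boot_q) - emp), 0.1)
})

test_that("r_community is exactly 1 for perfectly repeatable partitions", {
  sim <- small_sim(seed = 33, p_within = 0.95)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  net <- build_flock_network(gbi)
  part <- girvan_newman(net)
  expect_gte(part$n_communities, 2)
  # identical replicates reproduce the empirical partition every time
  reps <- rep(list(gbi), 5)
  expect_equal(r_community(part, reps), 1)
})

test_that("r_community is near zero when replicate labels are random", {
  # co-membership under uniformly random equal-split relabelling carries no
  # information about the empirical communities
  set.seed(44)
  n <- 20
  ids <- sprintf("B%02d", 1:n)
  emp <- rep(0:1, each = n / 2)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    lab <- sample(rep(0:1, each = n / 2))
    P <- P + outer(lab, lab, "==")
  }
  P <- P / n_rep
  diag(P) <- 1
  r <- flocknet:::assortativity_from_matrix(P, emp)
  expect_lt(abs(r), 0.1)
})

test_that("r_community is high on strongly modular synthetic data", {
  sim <- small_sim(seed = 55, p_within = 0.92)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  net <- build_flock_network(gbi)
  part <- girvan_newman(net)
  reps <- bootstrap_flocks(gbi, n_boot = 100, seed = 56)
  expect_gte(r_community(part, reps), 0.6)
  expect_error(r_community(part, reps[1]), "2 bootstrap")
})

test_that("comembership matrix is a valid co-assignment distribution", {
  sim <- small_sim(seed = 61, n_flocks = 60)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  P <- comembership_matrix(bootstrap_flocks(gbi, 30, seed = 62))
  expect_equal(P, t(P))
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(diag(P) == 1))
})

test_that("bootstrap-vs-null comparison separates structured data", {
  sim <- small_sim(seed = 71)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  cmp <- modularity_bootstrap_vs_null(gbi, n_boot = 50, n_swaps = 50, seed = 72)
  expect_gte(cmp$dominance, 0.95)
  expect_length(cmp$boot_q, 50)
  expect_length(cmp$null_q, 50)
  # degenerate single-iteration call still returns both distributions
  cmp1 <- modularity_bootstrap_vs_null(gbi, n_boot = 1, n_swaps = 1, seed = 73)
  expect_length(cmp1$boot_q, 1)
  expect_length(cmp1$null_q, 1)
})

test_that("resampling results expose tidy/glance summaries", {
  sim <- small_sim(seed = 81, n_flocks = 40)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  res <- serial_permutation_test(gbi, NULL, n_swaps = 20, seed = 82)
  td <- tidy(res)
  expect_equal(nrow(td), 20)
  gl <- glance(res)
  expect_equal(gl$n_iterations, 20)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
  expect_equal(gl$p_corrected,
               (sum(res$null_values >= res$empirical) + 1) / 21)
  expect_s3_class(autoplot(res), "ggplot")
})
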