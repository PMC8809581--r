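test_that("generator config validates its invariants", {
  expect_error(flock_generator_config(species_proportions = c(A = 0.5, B = 0.4)))
  expect_error(flock_generator_config(flock_size_min = 1))
  expect_error(flock_generator_config(p_within = 1.2))
  expect_error(flock_generator_config(n_communities = 40))
  # infeasible: strict within-community flocks larger than the community
  expect_error(
    flock_generator_config(n_individuals = 12, n_communities = 6,
                           flock_size_min = 3, p_within = 1),
    "infeasible"
  )
  cfg <- flock_generator_config()
  expect_equal(sum(cfg$community_sizes), cfg$n_individuals)
})

test_that("simulation is bit-reproducible under a seed", {
  s1 <- small_sim(seed = 42)
  s2 <- small_sim(seed = 42)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$truth, s2$truth)
  s3 <- small_sim(seed = 43)
  expect_false(identical(s1$observations, s3$observations))
})

test_that("emitted observations satisfy the GBI invariants", {
  sim <- small_sim(seed = 10)
  gbi <- build_gbi(sim$observations)
  expect_true(all(gbi %in% 0:1))
  expect_true(all(rowSums(gbi) >= 1))
  expect_true(all(colnames(gbi) %in% sim$truth$id))
  sizes <- table(sim$observations$flock_id)
  expect_true(mean(sizes) > 2 && mean(sizes) < 6)
})

test_that("default sampling effort sights virtually every bird 3+ times", {
  ok <- vapply(1:10, function(s) {
    sim <- small_sim(seed = s)
    counts <- table(sim$observations$individual_id)
    length(counts) == sim$config$n_individuals && all(counts >= 3)
  }, logical(1))
  expect_gte(mean(ok), 0.95 - 0.2)  # >95% expected; allow binomial noise at n=10
})

test_that("strict cohesion forces zero between-community association", {
  cfg <- flock_generator_config(n_individuals = 24, n_communities = 4,
                                p_within = 1, floater_rate = 0,
                                detection_prob = 1, n_flocks = 120,
                                flock_size_mean = 4, flock_size_sd = 1,
                                seed = 3)
  sim <- simulate_flocks(cfg)
  gbi <- build_gbi(sim$observations)
  S <- sri_matrix(gbi)
  comm <- stats::setNames(sim$truth$planted_community, sim$truth$id)
  cross <- outer(comm[rownames(S)], comm[colnames(S)], "!=")
  expect_true(all(S[cross] == 0))
  # the planted partition maximises Q among a family of competitors
  net <- build_flock_network(gbi)
  q_planted <- modularity_q(net, comm[net$nodes$id])
  set.seed(9)
  for (i in 1:20) {
    q_rand <- modularity_q(net, sample(comm)[net$nodes$id])
    expect_gte(q_planted, q_rand)
  }
})

test_that("exchangeable regime spreads association evenly across communities", {
  cfg <- flock_generator_config(p_within = 1 / 5, p_conspecific_bias = 1,
                                seed = 77)
  sim <- simulate_flocks(cfg)
  gbi <- build_gbi(sim$observations)
  S <- sri_matrix(gbi)
  comm <- stats::setNames(sim$truth$planted_community, sim$truth$id)
  same <- outer(comm[rownames(S)], comm[colnames(S)], "==")
  diag(same) <- NA
  within_mean <- mean(S[which(same)])
  cross_mean <- mean(S[which(!same)])
  expect_lt(abs(within_mean - cross_mean) / cross_mean, 0.25)
})

test_that("species assortativity rises with the conspecific bias", {
  grid <- c(1, 2.5, 6)
  means <- vapply(grid, function(b) {
    mean(vapply(1:20, function(s) {
      sim <- small_sim(seed = s, p_conspecific_bias = b, n_flocks = 120)
      net <- build_flock_network(
        filter_individuals(build_gbi(sim$observations), 3),
        sim_attributes(sim))
      tryCatch(species_assortativity(net), error = function(e) NA_real_)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("site presets carry the published population structure", {
  high <- emulate_site("high")
  expect_equal(high$n_individuals, 29)
  expect_equal(round(high$species_proportions * 29), c(CACH = 16, TUTI = 13))
  mid <- emulate_site("mid")
  expect_equal(mid$n_individuals, 31)
  expect_equal(round(mid$species_proportions * 31), c(CACH = 19, TUTI = 12))
  low <- emulate_site("low")
  expect_equal(low$n_individuals, 22)
  expect_equal(round(low$species_proportions * 22), c(CACH = 15, TUTI = 7))
  expect_equal(high$n_communities, 6)
  expect_equal(mid$n_communities, 4)
  expect_equal(low$n_communities, 7)
})

test_that("ground truth sidecar writes and matches the population", {
  sim <- small_sim(seed = 2, n_flocks = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), sim$config$n_individuals)
  expect_setequal(back$id, sim$truth$id)
})
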