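log_stage <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [flocknet] ", ...)
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full per-site social-network analysis
#'
#' Orchestrates the whole pipeline on one site's observations: read/accept
#' observations, filter transients, build the SRI network, summarise it,
#' detect communities (Girvan-Newman, modularity maximization), test Q
#' against the serial group-membership-swap null, bootstrap the flocks for
#' `r_community` and the bootstrap-vs-null comparison, test community
#' assortativity and species assortativity with node-label permutations.
#'
#' When the input is a precomputed association matrix rather than flock
#' observations, the GBI-dependent stages (swap null, bootstrap,
#' `r_community`) cannot run; they are reported as unavailable with a
#' warning.
#'
#' @param observations Long observation tibble, path to an observation CSV,
#'   or a `flock_network` / association-matrix CSV path (see
#'   `input_type`).
#' @param attributes Attribute tibble or CSV path (`id`, `species`, `site`);
#'   optional for association-matrix input.
#' @param input_type `"observations"` (default) or `"association_matrix"`.
#' @param min_sightings Minimum sighting count (transient filter).
#' @param exclude_ids Ids excluded regardless of sighting count.
#' @param weighted Weighting convention for community detection and
#'   assortativity.
#' @param n_swaps,n_boot,n_perm Iteration counts for the serial null, the
#'   flock bootstrap and the node-label permutations.
#' @param alternative Tail for the permutation tests.
#' @param seed Integer seed (mandatory; child seeds for each resampling
#'   stage are derived deterministically from it).
#' @param out_dir Optional directory; when given, writes `summary.json`,
#'   `membership.csv`, `edges.csv` and null-distribution CSVs.
#' @return A `site_report` list; see [glance.site_report()].
#' @export
run_site_analysis <- function(observations, attributes = NULL,
                              input_type = c("observations", "association_matrix"),
                              min_sightings = 3, exclude_ids = character(),
                              weighted = TRUE, n_swaps = 1000, n_boot = 1000,
                              n_perm = 1000,
                              alternative = "greater", seed,
                              out_dir = NULL) {
  input_type <- match.arg(input_type)
  stopifnot(n_swaps >= 1, n_boot >= 1, n_perm >= 1)
  if (missing(seed)) stop("seed is mandatory for the resampling stages",
                          call. = FALSE)
  seeds <- derive_seeds(seed, 4)

  if (is.character(attributes)) attributes <- read_attributes(attributes)

  gbi <- NULL
  if (input_type == "observations") {
    log_stage("stage read: observations")
    if (is.character(observations)) {
      observations <- read_flock_observations(observations)
    }
    log_stage("stage filter: min_sightings = ", min_sightings, ", ",
              length(exclude_ids), " explicit exclusions")
    gbi <- filter_individuals(build_gbi(observations), min_sightings, exclude_ids)
    log_stage("stage network: ", nrow(gbi), " flocks x ", ncol(gbi), " birds")
    net <- build_flock_network(gbi, attributes)
  } else {
    log_stage("stage read: association matrix")
    net <- if (is.character(observations)) {
      read_association_matrix(observations, attributes)
    } else observations
    warning("association-matrix input: permutation null, bootstrap and ",
            "r_community are unavailable: requires flock-level data",
            call. = FALSE)
  }

  log_stage("stage summary")
  summary_row <- network_summary(net)

  log_stage("stage communities (weighted = ", weighted, ")")
  partition <- girvan_newman(net, weighted = weighted)

  has_species <- length(unique(stats::na.omit(net$nodes$species))) >= 2

  if (!is.null(gbi)) {
    log_stage("stage serial permutation null: ", n_swaps, " swaps, seed ",
              seeds[1])
    q_test <- serial_permutation_test(gbi, NULL, n_swaps = n_swaps,
                                      alternative = alternative,
                                      seed = seeds[1], weighted = weighted)
    log_stage("stage bootstrap: ", n_boot, " replicates, seed ", seeds[2])
    replicates <- bootstrap_flocks(gbi, n_boot = n_boot, seed = seeds[2])
    boot_q <- vapply(replicates, gbi_modularity_stat, numeric(1),
                     weighted = weighted)
    r_com <- if (partition$n_communities >= 2) {
      r_community(partition, replicates, weighted = weighted)
    } else NA_real_
  } else {
    q_test <- NULL
    boot_q <- NULL
    r_com <- NA_real_
  }

  log_stage("stage community assortativity test: seed ", seeds[3])
  comm_labels <- stats::setNames(partition$membership$community,
                                 partition$membership$id)
  comm_assort <- if (partition$n_communities >= 2) {
    assortativity_categorical(net, comm_labels, weighted)
  } else NA_real_
  comm_assort_test <- if (partition$n_communities >= 2) {
    node_label_permutation_test(net, comm_labels, n_perm = n_perm,
                                alternative = alternative, seed = seeds[3])
  } else NULL

  log_stage("stage species assortativity test: seed ", seeds[4])
  sp_assort <- if (has_species) species_assortativity(net, weighted) else NA_real_
  sp_assort_test <- if (has_species) {
    node_label_permutation_test(net, n_perm = n_perm,
                                alternative = alternative, seed = seeds[4])
  } else NULL

  report <- structure(
    list(
      schema_version = "1.0",
      network = net,
      summary = summary_row,
      partition = partition,
      modularity_test = q_test,
      bootstrap_q = boot_q,
      r_community = r_com,
      community_assortativity = comm_assort,
      community_assortativity_test = comm_assort_test,
      species_assortativity = sp_assort,
      species_assortativity_test = sp_assort_test,
      unavailable_stages = if (is.null(gbi)) {
        c("modularity_test", "bootstrap", "r_community")
      } else character(0),
      settings = list(min_sightings = min_sightings, weighted = weighted,
                      n_swaps = n_swaps, n_boot = n_boot, n_perm = n_perm,
                      alternative = alternative, seed = seed)
    ),
    class = "site_report"
  )

  if (!is.null(out_dir)) {
    log_stage("stage write: ", out_dir)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report_to_list(report),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = 6,
      pretty = TRUE)
    write_membership(partition, net, file.path(out_dir, "membership.csv"))
    write_edge_list(net, file.path(out_dir, "edges.csv"))
    if (!is.null(q_test)) {
      write_null_distribution(q_test, file.path(out_dir, "null_modularity.csv"))
    }
    if (!is.null(boot_q)) {
      readr::write_csv(tibble::tibble(value = boot_q),
                       file.path(out_dir, "bootstrap_modularity.csv"),
                       progress = FALSE)
    }
    if (!is.null(sp_assort_test)) {
      write_null_distribution(sp_assort_test,
                              file.path(out_dir, "null_species_assortativity.csv"))
    }
  }
  report
}

report_to_list <- function(report) {
  list(
    schema_version = report$schema_version,
    summary = as.list(report$summary),
    n_communities = report$partition$n_communities,
    modularity = report$partition$q,
    modularity_p = if (!is.null(report$modularity_test))
      report$modularity_test$p_value else NA,
    modularity_p_corrected = if (!is.null(report$modularity_test))
      report$modularity_test$p_corrected else NA,
    r_community = report$r_community,
    community_assortativity = report$community_assortativity,
    community_assortativity_p = if (!is.null(report$community_assortativity_test))
      report$community_assortativity_test$p_value else NA,
    species_assortativity = report$species_assortativity,
    species_assortativity_p = if (!is.null(report$species_assortativity_test))
      report$species_assortativity_test$p_value else NA,
    unavailable_stages = report$unavailable_stages,
    settings = report$settings
  )
}

#' @export
print.site_report <- function(x, ...) {
  cat("<site_report>\n")
  print(glance(x))
  invisible(x)
}

#' One-row summary of a site analysis
#'
#' @param x A `site_report` from [run_site_analysis()].
#' @param ... Unused.
#' @return A one-row tibble with the headline network statistics, Q and its
#'   permutation p, `r_community`, and the assortativity coefficients.
#' @export
glance.site_report <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    tibble::tibble(
      n_communities = x$partition$n_communities,
      modularity = x$partition$q,
      modularity_p = if (!is.null(x$modularity_test))
        x$modularity_test$p_value else NA_real_,
      r_community = x$r_community,
      community_assortativity = x$community_assortativity,
      species_assortativity = x$species_assortativity,
      species_assortativity_p = if (!is.null(x$species_assortativity_test))
        x$species_assortativity_test$p_value else NA_real_
    )
  )
}

#' Validation suite over replicated synthetic datasets
#'
#' Replicated-simulation checks of the inferential machinery, each scored
#' over independently generated datasets:
#' type-I error of the serial modularity test on exchangeable populations
#' (`p_within = 1/n_communities`, no species bias), power along a
#' `p_within` grid, recovery of planted communities (adjusted Rand index),
#' and `r_community` on strongly modular data.
#'
#' @param n_datasets Datasets per condition (>= 50 recommended for
#'   calibration claims).
#' @param seed Integer seed; per-dataset seeds are derived from it.
#' @param alpha Nominal test level.
#' @param n_swaps Serial-chain length per dataset.
#' @param n_boot Bootstrap replicates for the `r_community` calibration.
#' @param config Base generator config for the power/recovery conditions.
#' @param p_within_grid Grid for the power curve.
#' @param null_config Generator config for the exchangeable (null)
#'   condition; defaults to `config` with `p_within = 1/n_communities` and
#'   no species bias.
#' @return A `validation_report` list of tibbles: `type1`, `power`,
#'   `recovery`, `rcom`.
#' @export
run_validation_suite <- function(n_datasets = 200, seed = 1, alpha = 0.05,
                                 n_swaps = 500, n_boot = 100,
                                 config = flock_generator_config(),
                                 p_within_grid = c(0.4, 0.6, 0.85),
                                 null_config = NULL) {
  if (is.null(null_config)) {
    null_config <- flock_generator_config(
      n_individuals = config$n_individuals,
      species_proportions = config$species_proportions,
      n_communities = config$n_communities,
      n_flocks = config$n_flocks,
      flock_size_mean = config$flock_size_mean,
      flock_size_sd = config$flock_size_sd,
      flock_size_min = config$flock_size_min,
      p_within = 1 / config$n_communities,
      p_conspecific_bias = 1,
      detection_prob = config$detection_prob
    )
  }
  seeds <- derive_seeds(seed, 4)

  clone_config <- function(base, ...) {
    args <- utils::modifyList(
      base[c("n_individuals", "species_proportions", "n_communities",
             "n_flocks", "flock_size_mean", "flock_size_sd", "flock_size_min",
             "p_within", "p_conspecific_bias", "detection_prob")],
      list(...))
    do.call(flock_generator_config, args)
  }

  one_p <- function(cfg, ds_seed) {
    cfg$seed <- ds_seed
    sim <- simulate_flocks(cfg)
    gbi <- filter_individuals(build_gbi(sim$observations), 1)
    serial_permutation_test(gbi, NULL, n_swaps = n_swaps,
                            seed = ds_seed + 1L)$p_value
  }

  log_stage("validation: type-I error, ", n_datasets, " null datasets")
  t1_seeds <- derive_seeds(seeds[1], n_datasets)
  p_null <- vapply(t1_seeds, function(s) one_p(null_config, s), numeric(1))
  rej <- mean(p_null <= alpha)
  ci <- stats::binom.test(round(alpha * n_datasets), n_datasets)$conf.int
  type1 <- tibble::tibble(
    n_datasets = n_datasets, alpha = alpha, rejection_rate = rej,
    ci_lower = ci[1], ci_upper = ci[2],
    calibrated = rej >= ci[1] & rej <= ci[2]
  )

  log_stage("validation: power grid")
  n_power <- max(20L, ceiling(n_datasets / 10))
  power <- purrr::map_dfr(p_within_grid, function(pw) {
    cfg <- clone_config(config, p_within = pw)
    pw_seeds <- derive_seeds(seeds[2] + round(1000 * pw), n_power)
    p <- vapply(pw_seeds, function(s) one_p(cfg, s), numeric(1))
    tibble::tibble(p_within = pw, n_datasets = n_power,
                   power = mean(p <= alpha))
  })

  log_stage("validation: planted-community recovery")
  n_rec <- max(20L, ceiling(n_datasets / 10))
  rec_seeds <- derive_seeds(seeds[3], n_rec)
  recovery <- purrr::map_dfr(rec_seeds, function(s) {
    cfg <- clone_config(config)
    cfg$seed <- s
    sim <- simulate_flocks(cfg)
    gbi <- filter_individuals(build_gbi(sim$observations), 1)
    net <- build_flock_network(gbi, sim_attributes(sim))
    part <- girvan_newman(net)
    truth <- stats::setNames(sim$truth$planted_community, sim$truth$id)
    ari <- mclust::adjustedRandIndex(
      part$membership$community, truth[part$membership$id])
    tibble::tibble(seed = s, ari = ari, q = part$q,
                   n_communities = part$n_communities)
  })

  log_stage("validation: r_community calibration")
  n_rc <- max(10L, ceiling(n_datasets / 20))
  rc_seeds <- derive_seeds(seeds[4], n_rc)
  rcom <- purrr::map_dfr(rc_seeds, function(s) {
    cfg <- clone_config(config, p_within = 0.92)
    cfg$seed <- s
    sim <- simulate_flocks(cfg)
    gbi <- filter_individuals(build_gbi(sim$observations), 1)
    net <- build_flock_network(gbi, sim_attributes(sim))
    part <- girvan_newman(net)
    reps <- bootstrap_flocks(gbi, n_boot = n_boot, seed = s + 2L)
    tibble::tibble(seed = s,
                   r_community = r_community(part, reps),
                   n_communities = part$n_communities)
  })

  structure(list(type1 = type1, power = power, recovery = recovery,
                 rcom = rcom, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n\nType-I error:\n")
  print(x$type1)
  cat("\nPower (p_within grid):\n")
  print(x$power)
  cat("\nRecovery: mean ARI = ", format(mean(x$recovery$ari), digits = 3),
      "; prop ARI >= 0.8 = ", format(mean(x$recovery$ari >= 0.8), digits = 3),
      "\n", sep = "")
  cat("r_community: mean = ", format(mean(x$rcom$r_community), digits = 3),
      "\n", sep = "")
  invisible(x)
}
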