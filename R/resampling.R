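compute_p <- function(null_values, empirical, alternative) {
  n <- length(null_values)
  ge <- sum(null_values >= empirical)
  le <- sum(null_values <= empirical)
  p <- switch(alternative,
    greater = ge / n,
    less = le / n,
    two_sided = min(1, 2 * min(ge, le) / n)
  )
  p_corr <- switch(alternative,
    greater = (ge + 1) / (n + 1),
    less = (le + 1) / (n + 1),
    two_sided = min(1, 2 * min(ge + 1, le + 1) / (n + 1))
  )
  list(p = p, p_corrected = p_corr)
}

new_resampling_result <- function(statistic_name, empirical, null_values,
                                  alternative, seed, extra = list()) {
  pp <- compute_p(null_values, empirical, alternative)
  structure(
    c(list(
      statistic_name = statistic_name,
      empirical = empirical,
      null_values = null_values,
      p_value = pp$p,
      p_corrected = pp$p_corrected,
      n_iterations = length(null_values),
      alternative = alternative,
      seed = seed
    ), extra),
    class = "resampling_result"
  )
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("<resampling_result> ", x$statistic_name, ": empirical = ",
      format(x$empirical, digits = 4), ", p = ", format(x$p_value, digits = 3),
      " (corrected ", format(x$p_corrected, digits = 3), ", ",
      x$alternative, ", n = ", x$n_iterations, ")\n", sep = "")
  invisible(x)
}

#' @rdname serial_permutation_test
#' @param x A `resampling_result`.
#' @param ... Unused.
#' @export
tidy.resampling_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$null_values), value = x$null_values)
}

#' @rdname serial_permutation_test
#' @export
glance.resampling_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic_name,
    empirical = x$empirical,
    p_value = x$p_value,
    p_corrected = x$p_corrected,
    n_iterations = x$n_iterations,
    alternative = x$alternative,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' @rdname serial_permutation_test
#' @param object A `resampling_result`.
#' @export
autoplot.resampling_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$empirical, colour = "purple",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic_name,
      y = "count",
      title = sprintf("%s: empirical vs null (p = %.3g)",
                      object$statistic_name, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' One group-membership checkerboard swap
#'
#' Performs a single valid swap: two flocks and two individuals such that
#' each individual is in exactly one of the two flocks are located, and the
#' two memberships are exchanged. Row sums (flock sizes) and column sums
#' (individual sighting counts) are preserved exactly, so chains of swaps
#' randomize who associates with whom while controlling for gregariousness
#' and sampling effort. Candidate quadruples are drawn uniformly with
#' rejection; if `max_attempts` rejections occur, all valid swaps are
#' enumerated and one is drawn uniformly (or, if none exists, the matrix is
#' returned unchanged with attribute `swapped = FALSE`).
#'
#' @param gbi GBI matrix with at least 2 rows and 2 columns.
#' @param max_attempts Rejection-sampling cap before exhaustive enumeration.
#' @return The swapped GBI matrix, with attribute `swapped` (logical).
#' @export
gbi_swap <- function(gbi, max_attempts = 10000) {
  stopifnot(nrow(gbi) >= 2, ncol(gbi) >= 2)
  res <- cpp_gbi_swap(gbi, as.integer(max_attempts))
  out <- res$gbi
  dimnames(out) <- dimnames(gbi)
  attr(out, "swapped") <- res$swapped
  out
}

# Default test statistic for the datastream null: maximum modularity found
# by Girvan-Newman on the SRI network of a GBI matrix.
gbi_modularity_stat <- function(gbi, weighted = TRUE) {
  e <- cpp_sri_edges(gbi)
  cpp_girvan_newman(ncol(gbi), e$from, e$to, e$weight, weighted, FALSE)$q
}

#' Serial datastream permutation test
#'
#' The serial method: starting from the empirical GBI matrix, checkerboard
#' swaps are applied sequentially and the test statistic is recomputed after
#' every swap, accumulating the null distribution along a single chain. The
#' empirical statistic is compared against that trajectory: for
#' `alternative = "greater"`, `p` is the proportion of chain values at least
#' as large as the empirical value. The raw `count / n` p-value is reported
#' together with the `(count + 1) / (n + 1)` correction.
#'
#' The default statistic is the Girvan-Newman maximum modularity of the SRI
#' network (computed in compiled code); any function of a GBI matrix can be
#' supplied instead.
#'
#' @param gbi GBI matrix.
#' @param statistic Function `gbi -> value`, or `NULL` for the fast built-in
#'   modularity statistic.
#' @param n_swaps Number of sequential swaps (chain length).
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @param seed Optional integer seed.
#' @param weighted Weighting convention for the built-in statistic.
#' @param burn_in Swaps applied before recording begins (default 0: the
#'   chain starts at the empirical matrix, per the serial method).
#' @param max_attempts Per-swap rejection cap, see [gbi_swap()].
#' @return A `resampling_result`.
#' @export
serial_permutation_test <- function(gbi, statistic = NULL, n_swaps = 1000,
                                    alternative = c("greater", "less", "two_sided"),
                                    seed = NULL, weighted = TRUE, burn_in = 0,
                                    max_attempts = 10000) {
  alternative <- match.arg(alternative)
  stopifnot(n_swaps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(statistic)) {
    empirical <- gbi_modularity_stat(gbi, weighted)
    chain <- cpp_serial_q_chain(gbi, as.integer(burn_in + n_swaps), weighted,
                                as.integer(max_attempts))
    null_values <- chain$q[(burn_in + 1):(burn_in + n_swaps)]
    n_failed <- sum(!chain$swapped)
    stat_name <- "modularity"
  } else {
    empirical <- statistic(gbi)
    null_values <- numeric(n_swaps)
    g <- gbi
    n_failed <- 0L
    for (s in seq_len(burn_in + n_swaps)) {
      g <- gbi_swap(g, max_attempts)
      if (!attr(g, "swapped")) n_failed <- n_failed + 1L
      if (s > burn_in) {
        null_values[s - burn_in] <- tryCatch(
          statistic(g),
          error = function(e) stop("statistic failed at chain index ",
                                   s - burn_in, ": ", conditionMessage(e),
                                   call. = FALSE)
        )
      }
    }
    stat_name <- "statistic"
  }
  if (n_failed > 0) {
    warning(n_failed, " swap step(s) found no valid swap (degenerate matrix)",
            call. = FALSE)
  }
  new_resampling_result(stat_name, empirical, null_values, alternative, seed,
                        extra = list(n_swaps = n_swaps, burn_in = burn_in,
                                     n_failed_swaps = n_failed))
}

#' Node-label permutation test
#'
#' Shuffles node labels uniformly (preserving the label multiset) while
#' keeping the network structure fixed; each iteration is an independent
#' draw, not a chain. Used to test whether a label-dependent statistic
#' (species assortativity by default) exceeds what random labelling yields.
#'
#' @param net A `flock_network`.
#' @param labels Label per node (tibble or named vector); defaults to the
#'   network's species attribute.
#' @param statistic Function `(net, labels) -> value`; defaults to weighted
#'   categorical assortativity.
#' @param n_perm Number of permutations.
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @param seed Optional integer seed.
#' @return A `resampling_result`.
#' @export
node_label_permutation_test <- function(net, labels = NULL, statistic = NULL,
                                        n_perm = 1000,
                                        alternative = c("greater", "less", "two_sided"),
                                        seed = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(labels)) {
    labels <- stats::setNames(net$nodes$species, net$nodes$id)
  }
  m <- as_membership(net, if (is.data.frame(labels) && !"community" %in% names(labels))
    stats::setNames(labels[[2]], labels[[1]]) else labels)
  if (length(unique(as.character(m))) < 2) {
    stop("node-label permutation needs at least 2 distinct labels", call. = FALSE)
  }
  if (is.null(statistic)) {
    statistic <- function(net, labels) assortativity_categorical(net, labels, TRUE)
  }
  if (!is.null(seed)) set.seed(seed)
  empirical <- statistic(net, m)
  ids <- names(m)
  null_values <- vapply(seq_len(n_perm), function(i) {
    statistic(net, stats::setNames(sample(m), ids))
  }, numeric(1))
  new_resampling_result("assortativity", empirical, null_values, alternative,
                        seed)
}

#' Bootstrap flock observations
#'
#' Resamples the observed flocks (GBI rows) with replacement; the individual
#' set (columns) stays fixed to the empirical network, so replicate networks
#' remain comparable node-for-node. Individuals are deliberately not
#' re-filtered inside replicates even if their resampled sighting count
#' drops below the original threshold.
#'
#' @param gbi GBI matrix with at least one flock.
#' @param n_boot Number of replicates.
#' @param seed Optional integer seed.
#' @return List of GBI matrices, each with as many rows as the original.
#' @export
bootstrap_flocks <- function(gbi, n_boot = 1000, seed = NULL) {
  stopifnot(nrow(gbi) >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_boot), function(i) {
    gbi[sample.int(nrow(gbi), nrow(gbi), replace = TRUE), , drop = FALSE]
  })
}

#' Bootstrap co-membership matrix
#'
#' Runs community detection on every bootstrap replicate and records, for
#' each pair of individuals, the proportion of replicates (in which both
#' were sighted at least once) that assigned them to the same community.
#' Pairs never co-present score 0.
#'
#' @param replicates List of GBI matrices from [bootstrap_flocks()].
#' @param weighted Weighting convention passed to community detection.
#' @return Symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
comembership_matrix <- function(replicates, weighted = TRUE) {
  stopifnot(length(replicates) >= 1)
  ids <- colnames(replicates[[1]])
  n <- length(ids)
  same <- matrix(0, n, n)
  both <- matrix(0, n, n)
  for (g in replicates) {
    e <- cpp_sri_edges(g)
    memb <- cpp_girvan_newman(n, e$from, e$to, e$weight, weighted, FALSE)$membership
    present <- colSums(g) > 0
    pres_out <- outer(present, present, "&")
    both <- both + pres_out
    same <- same + (outer(memb, memb, "==") & pres_out)
  }
  P <- ifelse(both > 0, same / both, 0)
  diag(P) <- 1
  dimnames(P) <- list(ids, ids)
  P
}

#' Robustness of community assignment (r_community)
#'
#' Quantifies how stable a community partition is under resampling of the
#' observed flocks. The bootstrap co-membership matrix is treated as a fully
#' connected weighted graph and its categorical assortativity with respect
#' to the *empirical* community labels is returned: 1 when every replicate
#' reproduces the empirical partition, near 0 when replicate communities are
#' unrelated to the empirical ones. Comparison is by co-membership, never by
#' label identity, because community labels are arbitrary across replicates.
#'
#' @param partition The empirical `community_partition` (at least 2
#'   communities).
#' @param replicates List of GBI matrices from [bootstrap_flocks()] (at
#'   least 2).
#' @param weighted Weighting convention for replicate community detection.
#' @return `r_community` coefficient.
#' @export
r_community <- function(partition, replicates, weighted = TRUE) {
  if (length(replicates) < 2) {
    stop("r_community needs at least 2 bootstrap replicates", call. = FALSE)
  }
  if (partition$n_communities < 2) {
    stop("r_community needs at least 2 empirical communities", call. = FALSE)
  }
  P <- comembership_matrix(replicates, weighted)
  ids <- colnames(P)
  labels <- stats::setNames(partition$membership$community,
                            partition$membership$id)[ids]
  if (anyNA(labels)) {
    stop("partition does not cover all individuals in the replicates",
         call. = FALSE)
  }
  assortativity_from_matrix(P, labels)
}

#' Bootstrap versus permutation-null modularity distributions
#'
#' Draws the modularity distribution under flock bootstrapping (sampling
#' error around the empirical network) and under the serial
#' group-membership-swap null (no association preference), and summarises
#' their separation as the proportion of bootstrap values exceeding the null
#' median. Community structure clearly above chance shows as near-complete
#' separation of the two box distributions.
#'
#' @param gbi GBI matrix.
#' @param n_boot Bootstrap replicates.
#' @param n_swaps Serial-chain length.
#' @param weighted Weighting convention.
#' @param seed Optional integer seed.
#' @return A `modularity_comparison`: empirical Q, both distributions, and
#'   `dominance` (proportion of bootstrap Q above the null median).
#' @export
modularity_bootstrap_vs_null <- function(gbi, n_boot = 1000, n_swaps = 1000,
                                         weighted = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  empirical <- gbi_modularity_stat(gbi, weighted)
  boot_q <- vapply(bootstrap_flocks(gbi, n_boot),
                   gbi_modularity_stat, numeric(1), weighted = weighted)
  chain <- cpp_serial_q_chain(gbi, as.integer(n_swaps), weighted, 10000L)
  structure(
    list(
      empirical = empirical,
      boot_q = boot_q,
      null_q = as.numeric(chain$q),
      dominance = mean(boot_q > stats::median(chain$q)),
      seed = seed
    ),
    class = "modularity_comparison"
  )
}

#' @export
print.modularity_comparison <- function(x, ...) {
  cat("<modularity_comparison> empirical Q = ", format(x$empirical, digits = 4),
      "; bootstrap median = ", format(stats::median(x$boot_q), digits = 4),
      "; null median = ", format(stats::median(x$null_q), digits = 4),
      "; dominance = ", format(x$dominance, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname modularity_bootstrap_vs_null
#' @param x,object A `modularity_comparison`.
#' @param ... Unused.
#' @export
tidy.modularity_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(source = "bootstrap", value = x$boot_q),
    tibble::tibble(source = "null", value = x$null_q)
  )
}

#' @rdname modularity_bootstrap_vs_null
#' @export
autoplot.modularity_comparison <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$source, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = object$empirical, colour = "purple",
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "modularity Q",
                  title = "Bootstrap vs datastream-null modularity") +
    ggplot2::theme_minimal()
}

#' Write a null distribution to CSV
#'
#' One value per line; convenient for external plotting of permutation or
#' bootstrap distributions.
#'
#' @param result A `resampling_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(result, path) {
  readr::write_csv(tibble::tibble(value = result$null_values), path,
                   progress = FALSE)
  invisible(path)
}
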