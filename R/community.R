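# Accept membership as a tibble (id, community) or a named vector; return a
# named integer vector over exactly the network's nodes, labels as given.
as_membership <- function(net, membership) {
  if (is.data.frame(membership)) {
    m <- stats::setNames(membership$community, membership$id)
  } else {
    m <- membership
  }
  ids <- net$nodes$id
  missing_ids <- setdiff(ids, names(m))
  if (length(missing_ids) > 0) {
    stop("membership misses node(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  m[ids]
}

#' Modularity of a partition
#'
#' Newman's modularity `Q = sum_c (e_cc - a_c^2)`: the proportion of edge
#' weight falling within communities minus the proportion expected if
#' associations attached at random in proportion to each community's share
#' of total strength. `Q = 0` for the trivial one-community partition; the
#' theoretical range is \[-0.5, 1\].
#'
#' @param net A `flock_network`.
#' @param membership Tibble (`id`, `community`) or named vector covering all
#'   nodes.
#' @param weighted Use SRI weights (default) or binary edges.
#' @return Modularity Q.
#' @export
modularity_q <- function(net, membership, weighted = TRUE) {
  m <- as_membership(net, membership)
  labs <- as.integer(factor(m)) - 1L
  ei <- edge_index(net)
  q <- cpp_modularity(ei$n, ei$from, ei$to, ei$weight, labs, weighted)
  stopifnot(q >= -0.5 - 1e-9, q <= 1 + 1e-9)
  q
}

#' Mixing matrix of a labelled network
#'
#' Fraction of (weighted) edge ends joining each pair of label classes;
#' symmetric with entries summing to 1. Houses the `e_ii` and `a_i` terms
#' of modularity and categorical assortativity.
#'
#' @param net A `flock_network`.
#' @param labels Tibble (`id`, `community`)/(named vector) label per node.
#' @param weighted Use SRI weights (default) or binary edges.
#' @return List with `e` (matrix) and `a` (row sums).
#' @export
mixing_matrix <- function(net, labels, weighted = TRUE) {
  m <- as_membership(net, if (is.data.frame(labels) && !"community" %in% names(labels))
    stats::setNames(labels[[2]], labels[[1]]) else labels)
  classes <- sort(unique(as.character(m)))
  k <- length(classes)
  e <- matrix(0, k, k, dimnames = list(classes, classes))
  if (nrow(net$edges) > 0) {
    w <- if (weighted) net$edges$weight else rep(1, nrow(net$edges))
    la <- as.character(m[net$edges$from])
    lb <- as.character(m[net$edges$to])
    for (i in seq_along(w)) {
      e[la[i], lb[i]] <- e[la[i], lb[i]] + w[i]
      e[lb[i], la[i]] <- e[lb[i], la[i]] + w[i]
    }
    e <- e / sum(e)
  }
  list(e = e, a = rowSums(e))
}

# Assortativity from an arbitrary symmetric weight matrix (diagonal ignored)
# and a label per row/column. Used both for network assortativity and for
# the bootstrap co-membership robustness coefficient.
assortativity_from_matrix <- function(W, labels) {
  stopifnot(nrow(W) == ncol(W), length(labels) == nrow(W))
  diag(W) <- 0
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) {
    stop("assortativity is undefined for a single label class", call. = FALSE)
  }
  total <- sum(W)
  if (total <= 0) {
    stop("assortativity is undefined for a network with no edge weight",
         call. = FALSE)
  }
  lab <- factor(as.character(labels), levels = classes)
  # e[i, j] = share of edge weight between classes i and j
  M <- stats::model.matrix(~ lab - 1)
  e <- t(M) %*% W %*% M / total
  a <- rowSums(e)
  denom <- 1 - sum(a * a)
  if (abs(denom) < 1e-12) {
    stop("assortativity denominator is zero (degenerate mixing)", call. = FALSE)
  }
  as.numeric((sum(diag(e)) - sum(a * a)) / denom)
}

#' Categorical assortativity coefficient
#'
#' Degree to which edge weight concentrates between nodes sharing a label
#' (species or community): the coefficient equals
#' `(sum_i e_ii - sum_i a_i^2) / (1 - sum_i a_i^2)` from the weighted mixing
#' matrix; 1 for perfect assortment, negative for disassortative mixing.
#'
#' @param net A `flock_network`.
#' @param labels Label per node: tibble (`id`, label) or named vector. For
#'   species assortativity pass the network's species column.
#' @param weighted Use SRI weights (default) or binary edges.
#' @return Assortativity coefficient `r`.
#' @export
assortativity_categorical <- function(net, labels, weighted = TRUE) {
  m <- as_membership(net, if (is.data.frame(labels) && !"community" %in% names(labels))
    stats::setNames(labels[[2]], labels[[1]]) else labels)
  if (anyNA(m[unique(c(net$edges$from, net$edges$to))])) {
    stop("label missing for an edge endpoint", call. = FALSE)
  }
  W <- as_adjacency(net, binary = !weighted)
  assortativity_from_matrix(W, m[net$nodes$id])
}

#' Species assortativity of a network
#'
#' Convenience wrapper: [assortativity_categorical()] on the network's own
#' species attribute, answering whether conspecifics associate more than
#' heterospecifics.
#'
#' @param net A `flock_network` whose nodes carry species labels.
#' @param weighted Use SRI weights (default) or binary edges.
#' @return Assortativity coefficient.
#' @export
species_assortativity <- function(net, weighted = TRUE) {
  assortativity_categorical(
    net, stats::setNames(net$nodes$species, net$nodes$id), weighted)
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the highest edge betweenness,
#' recomputing betweenness after every removal (Brandes accumulation), and
#' records the partition into connected components at each step. The
#' partition with maximal modularity Q over the whole removal sequence is
#' returned. With `weighted = TRUE` betweenness treats weights as costs
#' (distance `1/SRI`, so strong associations are short paths) while Q uses
#' the raw SRI weights as strengths - the standard reconciliation of the two
#' conventions; `weighted = FALSE` binarizes throughout. Ties in betweenness
#' are broken toward the lexicographically first `(from, to)` edge, making
#' the algorithm deterministic.
#'
#' @param net A `flock_network`.
#' @param weighted Weighting convention (see Details).
#' @param keep_steps Keep the membership at every removal step (for
#'   diagnostics); memory grows with edge count.
#' @return A `community_partition`: membership tibble (`id`, `community`,
#'   labels contiguous from 0), modularity `q`, number of communities, and
#'   the Q trajectory `q_steps`.
#' @export
girvan_newman <- function(net, weighted = TRUE, keep_steps = FALSE) {
  ei <- edge_index(net)
  if (ei$n == 0) {
    stop("community detection needs at least one node", call. = FALSE)
  }
  res <- cpp_girvan_newman(ei$n, ei$from, ei$to, ei$weight, weighted, keep_steps)
  membership <- tibble::tibble(
    id = net$nodes$id,
    community = as.integer(res$membership)
  )
  out <- structure(
    list(
      membership = membership,
      q = res$q,
      n_communities = length(unique(membership$community)),
      weighted = weighted,
      q_steps = res$q_steps,
      best_step = res$step,
      removal_order = res$removal_order + 1L  # row index into net$edges
    ),
    class = "community_partition"
  )
  if (keep_steps) out$memb_steps <- res$memb_steps
  out
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", x$n_communities, " communities, Q = ",
      format(x$q, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn girvan_newman `tidy()` returns the membership tibble.
#' @param x A `community_partition`.
#' @param ... Unused.
#' @export
tidy.community_partition <- function(x, ...) {
  x$membership
}

#' @describeIn girvan_newman `glance()` returns a one-row summary.
#' @export
glance.community_partition <- function(x, ...) {
  tibble::tibble(
    n_communities = x$n_communities,
    q = x$q,
    weighted = x$weighted
  )
}

#' Write a community membership table to CSV
#'
#' Columns `id`, `species`, `community`, `site`.
#'
#' @param partition A `community_partition`.
#' @param net The network it was computed on (for species/site columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(partition, net, path) {
  out <- partition$membership |>
    dplyr::left_join(net$nodes, by = "id") |>
    dplyr::select("id", "species", "community", "site")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Edge betweenness of every edge
#'
#' Brandes-style accumulation over shortest paths; with `weighted = TRUE`
#' edge weights are interpreted as costs `1/SRI`.
#'
#' @param net A `flock_network`.
#' @param weighted Interpret SRI weights as inverse distances.
#' @return The edge tibble with a `betweenness` column appended.
#' @export
edge_betweenness <- function(net, weighted = TRUE) {
  ei <- edge_index(net)
  b <- cpp_edge_betweenness(ei$n, ei$from, ei$to, ei$weight, weighted)
  dplyr::mutate(net$edges, betweenness = as.numeric(b))
}
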