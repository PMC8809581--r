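#' Network density
#'
#' The number of realized associations relative to the number of possible
#' associations: `2 * n_edges / (n_nodes * (n_nodes - 1))`. Density ignores
#' SRI weights (an association either exists or not) and counts isolated
#' nodes in the denominator.
#'
#' @param net A `flock_network`.
#' @return Proportion in \[0, 1\].
#' @export
network_density <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) stop("density needs at least 2 nodes", call. = FALSE)
  2 * nrow(net$edges) / (n * (n - 1))
}

#' Connected component sizes
#'
#' Components of the binarized graph; a component is a maximal set of
#' mutually reachable individuals, disconnected from the rest of the network.
#'
#' @param net A `flock_network`.
#' @return Integer vector of component sizes, descending. Sums to the number
#'   of nodes (isolates are size-1 components).
#' @export
network_components <- function(net) {
  ei <- edge_index(net)
  lab <- cpp_components(ei$n, ei$from, ei$to)
  sort(as.integer(table(lab)), decreasing = TRUE)
}

#' Average shortest path length
#'
#' Mean shortest-path distance over all unordered pairs of individuals,
#' where distance counts the minimum number of edges traversed (SRI weights
#' are ignored). Pairs in different components are unreachable and are
#' excluded from the mean, so a finite value is reported even for
#' fragmented networks.
#'
#' Distances are found by iterating the boolean adjacency product: the
#' distance of a pair is the first power of the reachability relation that
#' connects it.
#'
#' @param net A `flock_network`.
#' @return Mean distance (>= 1 for any network with an edge).
#' @export
average_path_length <- function(net) {
  if (nrow(net$edges) == 0) {
    stop("average path length is undefined for an edgeless network", call. = FALSE)
  }
  A <- as_adjacency(net, binary = TRUE) > 0
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A] <- 1
  reach <- A
  k <- 1L
  repeat {
    k <- k + 1L
    reach_new <- (reach %*% A) > 0
    fresh <- reach_new & !is.finite(D)
    if (!any(fresh)) break
    D[fresh] <- k
    reach <- reach | reach_new
  }
  up <- D[upper.tri(D)]
  mean(up[is.finite(up)])
}

#' Summary statistics of an association network
#'
#' One row per network with node/edge counts, per-species node counts,
#' density, component structure and average path length (NA for an edgeless
#' network).
#'
#' @param net A `flock_network`.
#' @return A one-row tibble.
#' @export
network_summary <- function(net) {
  comp <- network_components(net)
  sp <- table(net$nodes$species, useNA = "no")
  tibble::tibble(
    n_nodes = nrow(net$nodes),
    n_species = length(sp),
    species_counts = paste(sprintf("%s=%d", names(sp), sp), collapse = ";"),
    n_edges = nrow(net$edges),
    density = if (nrow(net$nodes) >= 2) network_density(net) else NA_real_,
    n_components = length(comp),
    component_sizes = paste(comp, collapse = ";"),
    avg_path_length = if (nrow(net$edges) > 0) average_path_length(net) else NA_real_
  )
}

#' @describeIn network_summary `glance()` method; identical to
#'   `network_summary()`.
#' @param x A `flock_network`.
#' @param ... Unused.
#' @export
glance.flock_network <- function(x, ...) {
  network_summary(x)
}

#' Plot an association network
#'
#' Nodes are laid out by classical multidimensional scaling of shortest-path
#' distances (disconnected components are offset), coloured by an optional
#' grouping and shaped by species. Edge width is proportional to SRI.
#'
#' @param object A `flock_network`.
#' @param colour_by Optional named vector (id -> group) used for node colour,
#'   e.g. a community membership.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flock_network <- function(object, colour_by = NULL, ...) {
  ids <- object$nodes$id
  n <- length(ids)
  A <- as_adjacency(object, binary = TRUE) > 0
  D <- matrix(Inf, n, n); diag(D) <- 0; D[A] <- 1
  reach <- A; k <- 1
  while (TRUE) {
    k <- k + 1
    reach_new <- (reach %*% A) > 0
    fresh <- reach_new & !is.finite(D)
    if (!any(fresh)) break
    D[fresh] <- k
    reach <- reach | reach_new
  }
  span <- max(D[is.finite(D)], 1)
  D[!is.finite(D)] <- span + 2  # keep components apart but finite for MDS
  xy <- stats::cmdscale(stats::as.dist(D), k = 2)
  layout <- tibble::tibble(id = ids, x = xy[, 1], y = xy[, 2],
                           species = object$nodes$species)
  layout$group <- if (is.null(colour_by)) "all" else as.character(colour_by[ids])
  seg <- object$edges |>
    dplyr::mutate(
      x = layout$x[match(.data$from, ids)],
      y = layout$y[match(.data$from, ids)],
      xend = layout$x[match(.data$to, ids)],
      yend = layout$y[match(.data$to, ids)]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60", show.legend = FALSE) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group,
                   shape = .data$species), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "group", shape = "species")
}
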