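#' Simple Ratio Index between two individuals
#'
#' The Simple Ratio Index (SRI) is the Jaccard index of two individuals'
#' sighting records: the proportion of times the pair was seen together out
#' of the total number of times either was seen under any circumstances,
#' `x / (x + yA + yB)` where `x` counts flocks containing both, and `yA`,
#' `yB` count flocks containing only one of them. Flocks containing neither
#' individual do not enter the denominator. SRI ranges from 0 (never sighted
#' together) to 1 (always sighted together).
#'
#' @param gbi GBI matrix from [build_gbi()].
#' @param a,b Individual ids (column names of `gbi`).
#' @return A single number in \[0, 1\]. When neither individual was ever
#'   sighted the index is undefined; 0 is returned with attribute
#'   `undefined = TRUE`.
#' @export
sri <- function(gbi, a, b) {
  for (id in c(a, b)) {
    if (!id %in% colnames(gbi)) stop("unknown individual id: ", id, call. = FALSE)
  }
  if (a == b) stop("sri is defined for two distinct individuals", call. = FALSE)
  ca <- gbi[, a]
  cb <- gbi[, b]
  x <- sum(ca == 1L & cb == 1L)
  denom <- sum(ca == 1L | cb == 1L)
  if (denom == 0) {
    return(structure(0, undefined = TRUE))
  }
  x / denom
}

#' Dense SRI matrix for all pairs
#'
#' @param gbi GBI matrix.
#' @return Symmetric numeric matrix of SRI values with zero diagonal.
#' @export
sri_matrix <- function(gbi) {
  n <- ncol(gbi)
  out <- matrix(0, n, n, dimnames = list(colnames(gbi), colnames(gbi)))
  if (n < 2) return(out)
  e <- cpp_sri_edges(gbi)
  out[cbind(e$from, e$to)] <- e$weight
  out[cbind(e$to, e$from)] <- e$weight
  out
}

new_flock_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "flock_network")
}

#' Build an SRI association network from a GBI matrix
#'
#' Nodes are all individuals in the GBI (isolates retained); an edge joins
#' every pair with SRI > 0, weighted by the SRI.
#'
#' @param gbi GBI matrix.
#' @param attributes Tibble with columns `id`, `species` and optionally
#'   `site`, covering every GBI column. `NULL` leaves species unknown.
#' @return A `flock_network`: list with `nodes` (tibble `id`, `species`,
#'   `site`) and `edges` (tibble `from`, `to`, `weight`, with `from < to`
#'   lexicographically).
#' @export
build_flock_network <- function(gbi, attributes = NULL) {
  ids <- colnames(gbi)
  nodes <- resolve_attributes(ids, attributes)
  e <- cpp_sri_edges(gbi)
  edges <- tibble::tibble(
    from = ids[e$from],
    to = ids[e$to],
    weight = e$weight
  )
  new_flock_network(nodes, edges)
}

#' Build a network directly from a symmetric weight matrix
#'
#' @param mat Symmetric numeric matrix with id dimnames; zero cells mean no
#'   edge, the diagonal is ignored.
#' @param attributes Optional attribute tibble.
#' @return A `flock_network`.
#' @export
network_from_matrix <- function(mat, attributes = NULL) {
  ids <- colnames(mat)
  stopifnot(!is.null(ids), identical(rownames(mat), ids))
  ord <- order(ids)
  mat <- mat[ord, ord, drop = FALSE]
  ids <- ids[ord]
  nodes <- resolve_attributes(ids, attributes)
  ut <- which(upper.tri(mat) & mat > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = ids[ut[, 1]],
    to = ids[ut[, 2]],
    weight = mat[ut]
  ) |> dplyr::arrange(.data$from, .data$to)
  new_flock_network(nodes, edges)
}

resolve_attributes <- function(ids, attributes) {
  if (is.null(attributes)) {
    return(tibble::tibble(id = ids, species = NA_character_, site = NA_character_))
  }
  missing_ids <- setdiff(ids, attributes$id)
  if (length(missing_ids) > 0) {
    stop("attribute table misses id(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  if (!"site" %in% names(attributes)) attributes$site <- NA_character_
  tibble::tibble(id = ids) |>
    dplyr::left_join(attributes[, c("id", "species", "site")], by = "id")
}

#' Adjacency matrix of a network
#'
#' @param net A `flock_network`.
#' @param binary Return 0/1 adjacency instead of SRI weights.
#' @return Dense symmetric matrix over all nodes.
#' @export
as_adjacency <- function(net, binary = FALSE) {
  ids <- net$nodes$id
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$from, ids)
    j <- match(net$edges$to, ids)
    w <- if (binary) 1 else net$edges$weight
    out[cbind(i, j)] <- w
    out[cbind(j, i)] <- w
  }
  out
}

# Integer endpoints (1-based positions in nodes$id) for the C++ kernels.
edge_index <- function(net) {
  list(
    n = nrow(net$nodes),
    from = match(net$edges$from, net$nodes$id),
    to = match(net$edges$to, net$nodes$id),
    weight = net$edges$weight
  )
}

#' @export
print.flock_network <- function(x, ...) {
  sp <- table(x$nodes$species, useNA = "ifany")
  cat("<flock_network> ", nrow(x$nodes), " nodes (",
      paste(sprintf("%s: %d", names(sp), sp), collapse = ", "), "), ",
      nrow(x$edges), " SRI-weighted edges\n", sep = "")
  invisible(x)
}

#' @describeIn build_flock_network `tidy()` returns the edge list as a tibble.
#' @param x A `flock_network`.
#' @param ... Unused.
#' @export
tidy.flock_network <- function(x, ...) {
  x$edges
}

#' Write a network edge list to CSV
#'
#' Columns `id_a`, `id_b`, `sri` (6 decimal places).
#'
#' @param net A `flock_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  out <- tibble::tibble(
    id_a = net$edges$from,
    id_b = net$edges$to,
    sri = sprintf("%.6f", net$edges$weight)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write the dense association matrix to CSV
#'
#' Mirrors the format accepted by [read_association_matrix()].
#'
#' @param net A `flock_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(net, path) {
  mat <- as_adjacency(net)
  wide <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  wide <- dplyr::bind_cols(tibble::tibble(id = rownames(mat)), wide)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}
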