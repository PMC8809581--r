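# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (set arithmetic, BFS, explicit mixing-matrix loops) and
# share no code with the package internals they check.

# Build a flock_network from an edge data frame (from, to, weight).
net_from_edges <- function(edges, ids = NULL, species = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(edges$from, edges$to)))
  mat <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    w <- if ("weight" %in% names(edges)) edges$weight[i] else 1
    mat[edges$from[i], edges$to[i]] <- w
    mat[edges$to[i], edges$from[i]] <- w
  }
  attrs <- if (!is.null(species)) {
    tibble::tibble(id = ids, species = species, site = "test")
  } else NULL
  network_from_matrix(mat, attrs)
}

triangle_pair_edges <- function(bridge = TRUE) {
  e <- data.frame(
    from = c("a", "a", "b", "d", "d", "e"),
    to   = c("b", "c", "c", "e", "f", "f"),
    weight = 1
  )
  if (bridge) e <- rbind(e, data.frame(from = "c", to = "d", weight = 1))
  e
}

# Set-based Jaccard oracle for the SRI of two GBI columns.
jaccard_oracle <- function(gbi, a, b) {
  fa <- which(gbi[, a] == 1)
  fb <- which(gbi[, b] == 1)
  un <- length(union(fa, fb))
  if (un == 0) return(0)
  length(intersect(fa, fb)) / un
}

# Breadth-first-search all-pairs mean distance oracle (unreachable skipped).
bfs_apl_oracle <- function(adj) {
  n <- nrow(adj)
  dists <- c()
  for (s in seq_len(n - 1)) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (is.na(d[v])) { d[v] <- d[u] + 1L; nxt <- c(nxt, v) }
        }
      }
      frontier <- nxt
    }
    keep <- seq_len(n) > s & !is.na(d)
    dists <- c(dists, d[keep])
  }
  mean(dists)
}

# Explicit mixing-matrix oracle: returns list(Q, r) for a labelled weighted
# adjacency matrix, looping over edges one by one.
mixing_oracle <- function(adj, labels, weighted = TRUE) {
  n <- nrow(adj)
  classes <- sort(unique(labels))
  k <- length(classes)
  e <- matrix(0, k, k, dimnames = list(classes, classes))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j] > 0) {
        w <- if (weighted) adj[i, j] else 1
        li <- as.character(labels[i]); lj <- as.character(labels[j])
        e[li, lj] <- e[li, lj] + w
        e[lj, li] <- e[lj, li] + w
      }
    }
  }
  tot <- sum(e)
  if (tot == 0) return(list(Q = 0, r = NA_real_))
  e <- e / tot
  a <- rowSums(e)
  list(
    Q = sum(diag(e)) - sum(a^2),
    r = (sum(diag(e)) - sum(a^2)) / (1 - sum(a^2))
  )
}

# Random connected-ish weighted graph on n nodes for oracle-equivalence
# sweeps.
random_test_network <- function(n, p = 0.5, weighted = TRUE) {
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) {
          adj[i, j] <- adj[j, i] <- if (weighted) stats::runif(1, 0.05, 1) else 1
        }
      }
    }
    if (sum(adj) > 0) break
  }
  dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  network_from_matrix(adj)
}

# All set partitions of 1..n (Bell-number enumeration; used only for n <= 8).
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (c in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, c)
  }
  out
}

# Small long-format observation tibble used across data-model tests.
toy_observations <- function() {
  tibble::tibble(
    flock_id = c("f1", "f1", "f2"),
    individual_id = c("a", "b", "a")
  )
}

small_sim <- function(seed = 1, ...) {
  cfg <- flock_generator_config(seed = seed, ...)
  simulate_flocks(cfg)
}
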