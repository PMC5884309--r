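# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (igraph shortest paths, union-find) so that
# agreement is a real cross-check.

# All-pairs shortest paths by Floyd-Warshall on edge lengths 1/w, then the
# mean inverse distance over off-diagonal pairs.
fw_efficiency <- function(w, ids) {
  sub <- w[ids, ids, drop = FALSE]
  k <- length(ids)
  d <- matrix(Inf, k, k)
  diag(d) <- 0
  d[sub > 0] <- 1 / sub[sub > 0]
  diag(d) <- 0
  for (m in seq_len(k)) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
      }
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (k * (k - 1))
}

# Connected components of an undirected graph by breadth-first flood fill
# over an adjacency list; returns a list of sorted node-id vectors (only
# nodes with at least one incident edge).
flood_fill_components <- function(edges, n) {
  if (nrow(edges) == 0) return(list())
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  comps <- list()
  for (start in sort(unique(as.vector(edges)))) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (u in adj[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# A random symmetric non-negative weighted graph on n nodes.
random_connectome <- function(n, density = 0.5, wmax = 2) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < density]
  w[on] <- stats::runif(length(on), 0.05, wmax)
  w + t(w)
}

# Small cohorts for fast unit tests (16 nodes keeps every stage cheap).
tiny_cohort <- function(n_subjects = 20, n_nodes = 16, seed = 42, ...) {
  simulate_cohort(cohort_spec(
    n_subjects = n_subjects, n_nodes = n_nodes,
    target_subnetwork = 1:6, systems = list(1:6, 7:10),
    rng_seed = seed, ...))
}
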