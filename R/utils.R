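# Run expr with a temporarily fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Derive per-stage child seeds from one master seed
#'
#' Spawns `n` reproducible 31-bit integer seeds from a single master seed so
#' that individual pipeline stages can be re-run in isolation with the same
#' random stream they had inside a full run.
#'
#' @param master_seed single integer.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed), n >= 1)
  with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, n))
}

# Union-find over an edge list; returns integer component id per node of
# `nodes` (nodes are arbitrary integer ids). Used by NBS component
# extraction, where supra-threshold graphs are tiny and this is called once
# per permutation.
uf_components <- function(nodes, edges_i, edges_j) {
  parent <- seq_along(nodes)
  pos_i <- match(edges_i, nodes)
  pos_j <- match(edges_j, nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(pos_i)) {
    ri <- find(pos_i[k]); rj <- find(pos_j[k])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_along(nodes), find, integer(1))
}

# Upper-triangle (i < j) index pairs of an n x n matrix, as a 2-column matrix.
upper_pairs <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
}

# Symmetrize a matrix from its upper triangle values (vector in upper_pairs
# order), zero diagonal.
sym_from_upper <- function(values, n) {
  m <- matrix(0, n, n)
  ut <- upper_pairs(n)
  m[ut] <- values
  m[ut[, c(2, 1), drop = FALSE]] <- values
  m
}

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
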