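#' Weighted global efficiency of a sub-network
#'
#' Efficiency is the average inverse shortest-path length over all ordered
#' node pairs of the sub-network:
#' \deqn{E = \frac{1}{k(k-1)} \sum_{i \ne j} \frac{1}{d_{ij}},}
#' where `d_ij` is the weighted shortest-path distance with per-edge length
#' `1/w` (the standard connectivity-to-distance map: stronger connections
#' are shorter), and `1/d_ij = 0` for disconnected pairs. Paths are
#' restricted to the induced subgraph over the sub-network's nodes — they
#' may not detour through out-of-network nodes, since the metric is meant to
#' summarize connectivity within the named circuit only.
#'
#' @param connectome symmetric non-negative weight matrix.
#' @param subnet a `subnetwork_def` (see [subnetwork()]) or an integer
#'   vector of node ids.
#' @return efficiency (non-negative scalar; 0 iff the induced subgraph has
#'   no edges).
#' @export
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- w[2, 1] <- 0.4
#' global_efficiency(w, 1:2)  # 0.4
global_efficiency <- function(connectome, subnet) {
  ids <- subnet_ids(subnet, nrow(connectome))
  sub <- connectome[ids, ids, drop = FALSE]
  k <- length(ids)
  if (sum(sub > 0) == 0) return(0)
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (k * (k - 1))
}

#' Sum of edge weights within a sub-network
#'
#' Total weight over unordered node pairs of the sub-network, each pair
#' counted once. Used alongside [global_efficiency()] because efficiency is
#' sensitive to disconnections; the sum of weights is a simpler aggregate of
#' the same edges.
#'
#' @inheritParams global_efficiency
#' @return non-negative scalar.
#' @export
sum_of_weights <- function(connectome, subnet) {
  ids <- subnet_ids(subnet, nrow(connectome))
  sub <- connectome[ids, ids, drop = FALSE]
  sum(sub[upper.tri(sub)])
}

subnet_ids <- function(subnet, n) {
  ids <- if (inherits(subnet, "subnetwork_def")) subnet$node_ids
  else as.integer(subnet)
  if (length(ids) < 2) stop("sub-network must have at least 2 nodes")
  if (anyDuplicated(ids)) stop("duplicate node ids in sub-network")
  if (any(ids < 1) || any(ids > n)) stop("sub-network ids outside 1..", n)
  ids
}

#' Per-subject sub-network metrics over a cohort
#'
#' Computes [global_efficiency()] and [sum_of_weights()] for each subject
#' and each sub-network.
#'
#' @param cohort a `svd_cohort` or 3-D connectome array.
#' @param subnetworks named list of `subnetwork_def` (default
#'   [builtin_subnetworks()]).
#' @return data.frame: `subject_id`, then `<name>_eff` and `<name>_sum` per
#'   sub-network.
#' @export
network_metrics <- function(cohort, subnetworks = builtin_subnetworks()) {
  w <- cohort_weights(cohort)
  S <- dim(w)[3]
  ids <- if (inherits(cohort, "svd_cohort")) cohort$table$subject_id
  else sprintf("S%03d", seq_len(S))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (nm in names(subnetworks)) {
    sn <- subnetworks[[nm]]
    out[[paste0(nm, "_eff")]] <- vapply(seq_len(S), function(s) {
      global_efficiency(w[, , s], sn)
    }, numeric(1))
    out[[paste0(nm, "_sum")]] <- vapply(seq_len(S), function(s) {
      sum_of_weights(w[, , s], sn)
    }, numeric(1))
  }
  out
}

#' Write per-subject network metrics to CSV
#'
#' @param metrics data.frame from [network_metrics()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
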