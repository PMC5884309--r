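#' NBS configuration
#'
#' Parameters of the network-based statistic. Edges whose edgewise
#' correlation with the score reaches `|t| >= t_threshold` (default 2.5,
#' roughly two-tailed p <= 0.01 at ~114 subjects) are supra-threshold;
#' connected components of supra-threshold edges are scored by their extent
#' (edge count) against a permutation null of maximal extents, giving
#' family-wise-error-corrected cluster p-values compared to `alpha`.
#'
#' @param t_threshold positive test-statistic cutoff (default 2.5).
#' @param alpha cluster significance level in `(0, 1)` (default 0.05,
#'   applied per tail).
#' @param n_permutations permutation count (default 5000, minimum 100).
#' @param tail `"negative"`, `"positive"` or `"both-separately"` (default):
#'   which supra-threshold sign(s) to analyse; tails are always thresholded
#'   and permuted separately, never on `|t|` jointly.
#' @param rng_seed seed for the permutation stream.
#' @return object of class `nbs_config`.
#' @export
nbs_config <- function(t_threshold = 2.5, alpha = 0.05,
                       n_permutations = 5000L,
                       tail = c("both-separately", "negative", "positive"),
                       rng_seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(t_threshold > 0, alpha > 0, alpha < 1, n_permutations >= 100)
  structure(list(t_threshold = t_threshold, alpha = alpha,
                 n_permutations = as.integer(n_permutations), tail = tail,
                 rng_seed = as.integer(rng_seed)),
            class = "nbs_config")
}

# cap for t at perfect correlation (keeps ordering, avoids Inf)
T_CAP <- 1e9

#' Edgewise correlation t-statistics
#'
#' For every masked-in edge, the Pearson correlation across subjects between
#' edge weight and score, converted to `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' (capped at +/-1e9 for perfect correlations). Edges with zero weight
#' variance get t = 0; masked-out edges get `NA`.
#'
#' @param cohort a `svd_cohort` or 3-D connectome array.
#' @param mask logical edge-presence matrix (see [group_edge_mask()]).
#' @param scores numeric vector, one per subject.
#' @return symmetric matrix of t values (`NA` where masked out).
#' @export
edge_statistics <- function(cohort, mask, scores) {
  w <- cohort_weights(cohort)
  n <- dim(w)[1]; S <- dim(w)[3]
  stopifnot(length(scores) == S, identical(dim(mask), dim(w)[1:2]))
  if (stats::sd(scores) == 0) stop("scores have zero variance")
  ut <- upper_pairs(n)
  on_edges <- which(mask[ut])
  E <- matrix(w[cbind(rep(ut[on_edges, 1], each = S),
                      rep(ut[on_edges, 2], each = S),
                      rep(seq_len(S), length(on_edges)))],
              S, length(on_edges))
  r <- suppressWarnings(as.numeric(stats::cor(scores, E)))
  r[is.na(r)] <- 0  # zero-variance edges
  t_val <- r_to_t(r, S)
  t_mat <- matrix(NA_real_, n, n)
  pairs_on <- ut[on_edges, , drop = FALSE]
  t_mat[pairs_on] <- t_val
  t_mat[pairs_on[, c(2, 1), drop = FALSE]] <- t_val
  dimnames(t_mat) <- dimnames(w)[1:2]
  t_mat
}

r_to_t <- function(r, n) {
  t_val <- r * sqrt(n - 2) / sqrt(pmax(0, 1 - r^2))
  t_val[r >= 1] <- T_CAP
  t_val[r <= -1] <- -T_CAP
  pmin(pmax(t_val, -T_CAP), T_CAP)
}

#' Connected components of the supra-threshold graph
#'
#' Builds the graph of edges with `t <= -t_threshold` (negative tail) or
#' `t >= t_threshold` (positive tail) and returns its connected components
#' with at least one edge.
#'
#' @param t_matrix symmetric t-statistic matrix (`NA` = masked out).
#' @param t_threshold positive cutoff.
#' @param tail `"negative"` or `"positive"`.
#' @return list of components, each a list with `nodes` (sorted ids),
#'   `edges` (2-column matrix) and `extent` (edge count); sorted by
#'   decreasing extent.
#' @export
extract_components <- function(t_matrix, t_threshold = 2.5,
                               tail = c("negative", "positive")) {
  tail <- match.arg(tail)
  n <- nrow(t_matrix)
  ut <- upper_pairs(n)
  tv <- t_matrix[ut]
  supra <- if (tail == "negative") which(!is.na(tv) & tv <= -t_threshold)
  else which(!is.na(tv) & tv >= t_threshold)
  components_from_edges(ut[supra, , drop = FALSE])
}

# connected components given an explicit edge list (2-column matrix)
components_from_edges <- function(edges) {
  if (nrow(edges) == 0) return(list())
  nodes <- sort(unique(as.vector(edges)))
  comp <- uf_components(nodes, edges[, 1], edges[, 2])
  edge_comp <- comp[match(edges[, 1], nodes)]
  out <- lapply(unique(comp), function(cid) {
    e <- edges[edge_comp == cid, , drop = FALSE]
    list(nodes = nodes[comp == cid], edges = e, extent = nrow(e))
  })
  out[order(vapply(out, `[[`, integer(1), "extent"), decreasing = TRUE)]
}

# max component extent for one permutation's supra-threshold edge list
max_extent_from_edges <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  nodes <- sort(unique(as.vector(edges)))
  comp <- uf_components(nodes, edges[, 1], edges[, 2])
  edge_comp <- comp[match(edges[, 1], nodes)]
  max(tabulate(match(edge_comp, unique(edge_comp))))
}

#' Network-based statistic with permutation FWER control
#'
#' Runs the full NBS: observed edgewise t-statistics, supra-threshold
#' component extraction per tail, and a permutation null in which the score
#' vector is shuffled `n_permutations` times and the maximal component
#' extent recorded. Each observed component gets
#' `p_fwer = (1 + #\{perm max extent >= observed extent\}) / (n_permutations + 1)`,
#' the standard positively-biased estimator that can never return zero;
#' components with `p_fwer < alpha` are flagged significant.
#'
#' @inheritParams edge_statistics
#' @param config an [nbs_config()].
#' @return object of class `nbs_result`: list with `t_matrix`, per-tail
#'   `components` (each with `nodes`, `edges`, `extent`, `p_fwer`,
#'   `significant`), `null_max_extents` per tail, and the `config`.
#' @export
nbs <- function(cohort, mask, scores, config = nbs_config()) {
  stopifnot(inherits(config, "nbs_config"))
  w <- cohort_weights(cohort)
  S <- dim(w)[3]
  if (S < 10) stop("need at least 10 subjects for a usable permutation null")
  t_mat <- edge_statistics(cohort, mask, scores)
  tails <- switch(config$tail,
                  "both-separately" = c("negative", "positive"),
                  config$tail)

  # precompute standardized edge weights once; all permutations are one
  # crossproduct away
  n <- dim(w)[1]
  ut <- upper_pairs(n)
  on_edges <- which(mask[ut])
  E <- matrix(w[cbind(rep(ut[on_edges, 1], each = S),
                      rep(ut[on_edges, 2], each = S),
                      rep(seq_len(S), length(on_edges)))],
              S, length(on_edges))
  Z <- scale(E)
  Z[, attr(Z, "scaled:scale") == 0] <- 0  # zero-variance edges contribute r=0
  B <- config$n_permutations
  perm_scores <- with_seed(config$rng_seed, {
    vapply(seq_len(B), function(b) sample(scores), numeric(S))
  })
  zs <- scale(perm_scores)
  R_perm <- crossprod(Z, zs) / (S - 1)     # edges x permutations
  T_perm <- matrix(r_to_t(as.numeric(R_perm), S), nrow(R_perm), B)
  pairs_on <- ut[on_edges, , drop = FALSE]

  null_max <- list()
  components <- list()
  for (tl in tails) {
    nm <- vapply(seq_len(B), function(b) {
      supra <- if (tl == "negative") which(T_perm[, b] <= -config$t_threshold)
      else which(T_perm[, b] >= config$t_threshold)
      max_extent_from_edges(pairs_on[supra, , drop = FALSE])
    }, integer(1))
    comps <- extract_components(t_mat, config$t_threshold, tl)
    comps <- lapply(comps, function(cc) {
      cc$p_fwer <- (1 + sum(nm >= cc$extent)) / (B + 1)
      cc$significant <- cc$p_fwer < config$alpha
      cc$tail <- tl
      cc
    })
    null_max[[tl]] <- nm
    components[[tl]] <- comps[order(vapply(comps, `[[`, numeric(1), "p_fwer"))]
  }
  structure(list(t_matrix = t_mat, components = components,
                 null_max_extents = null_max, config = config,
                 n_subjects = S),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("nbs_result: t >= %.2f, %d permutations, tails: %s\n",
              x$config$t_threshold, x$config$n_permutations,
              paste(names(x$components), collapse = ", ")))
  for (tl in names(x$components)) {
    comps <- x$components[[tl]]
    if (length(comps) == 0) {
      cat(sprintf("  %s tail: no supra-threshold components\n", tl))
    } else {
      for (k in seq_along(comps)) {
        cat(sprintf("  %s tail, component %d: %d edges, %d nodes, p_fwer = %.4g%s\n",
                    tl, k, comps[[k]]$extent, length(comps[[k]]$nodes),
                    comps[[k]]$p_fwer,
                    if (comps[[k]]$significant) " *" else ""))
      }
    }
  }
  invisible(x)
}

#' Write an NBS run as a JSON report plus a t-matrix CSV
#'
#' The JSON mirrors the tabular cluster summary (edge count, node count,
#' participating node names, FWER p-value) and echoes the configuration.
#'
#' @param result an `nbs_result`.
#' @param json_path output JSON file.
#' @param t_csv_path optional output CSV for the t-matrix.
#' @param node_names names for node ids (default [aal90_labels()] when the
#'   matrix is 90 x 90).
#' @return invisibly, `json_path`.
#' @export
write_nbs_report <- function(result, json_path, t_csv_path = NULL,
                             node_names = NULL) {
  n <- nrow(result$t_matrix)
  if (is.null(node_names)) {
    node_names <- rownames(result$t_matrix) %||%
      (if (n == 90) aal90_labels() else as.character(seq_len(n)))
  }
  comp_json <- lapply(names(result$components), function(tl) {
    lapply(result$components[[tl]], function(cc) {
      list(tail = tl, edges_count = cc$extent, nodes_count = length(cc$nodes),
           nodes_participating = node_names[cc$nodes],
           p_fwer = cc$p_fwer, significant = cc$significant)
    })
  })
  names(comp_json) <- names(result$components)
  jsonlite::write_json(
    list(config = unclass(result$config), n_subjects = result$n_subjects,
         components = comp_json),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(t_csv_path)) {
    tm <- result$t_matrix
    dimnames(tm) <- list(node_names, node_names)
    utils::write.csv(tm, t_csv_path)
  }
  invisible(json_path)
}
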