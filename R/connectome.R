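#' Edge weight from streamline lengths
#'
#' The weight of an edge connecting two parcellation nodes is half the sum
#' of inverse streamline lengths,
#' \deqn{w_{ij} = \frac{1}{2} \sum_{m=1}^{N} \frac{1}{l_m},}
#' so it grows with the number of streamlines `N` and shrinks with their
#' lengths `l_m` (in mm). An empty bundle has weight 0.
#'
#' @param streamline_lengths numeric vector of streamline arc lengths (mm),
#'   all strictly positive; may be empty.
#' @return the edge weight (non-negative scalar).
#' @export
#' @examples
#' edge_weight(c(2, 2))     # 0.5
#' edge_weight(c(2, 4, 4))  # 0.5
#' edge_weight(numeric(0))  # 0
edge_weight <- function(streamline_lengths) {
  if (length(streamline_lengths) == 0) return(0)
  if (any(!is.finite(streamline_lengths)) || any(streamline_lengths <= 0)) {
    stop("streamline lengths must be finite and > 0 (degenerate streamline)")
  }
  0.5 * sum(1 / streamline_lengths)
}

#' Build a weighted connectome from edge-labelled streamlines
#'
#' Accumulates [edge_weight()] over all streamlines assigned to each node
#' pair, producing a symmetric non-negative matrix with zero diagonal.
#'
#' @param streamlines an edge-labelled [streamline_set()] (see
#'   [assign_endpoints()]).
#' @param n_nodes matrix dimension (default 90).
#' @param node_names optional row/column names; defaults to
#'   [aal90_labels()] when `n_nodes` is 90.
#' @return `n_nodes` x `n_nodes` numeric matrix.
#' @export
build_connectome <- function(streamlines, n_nodes = 90L, node_names = NULL) {
  stopifnot(inherits(streamlines, "streamline_set"))
  n_nodes <- as.integer(n_nodes)
  w <- matrix(0, n_nodes, n_nodes)
  if (length(streamlines) > 0) {
    if (is.null(streamlines$edges)) {
      stop("streamlines carry no edge labels; run assign_endpoints() first")
    }
    e <- streamlines$edges
    if (any(e < 1) || any(e > n_nodes)) {
      stop("streamline edge labels outside 1..", n_nodes)
    }
    contrib <- 0.5 / streamlines$lengths
    for (k in seq_len(nrow(e))) {
      w[e[k, 1], e[k, 2]] <- w[e[k, 1], e[k, 2]] + contrib[k]
    }
    w <- w + t(w)
  }
  if (is.null(node_names) && n_nodes == 90L) node_names <- aal90_labels()
  if (!is.null(node_names)) dimnames(w) <- list(node_names, node_names)
  w
}

check_connectome <- function(w, what = "connectome") {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop(what, " must be a square matrix")
  }
  if (any(!is.finite(w))) stop(what, " has non-finite entries")
  if (any(w < 0)) stop(what, " has negative weights")
  bad <- which(abs(w - t(w)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%s is asymmetric at cell (%d, %d): %g vs %g", what,
                 bad[1, 1], bad[1, 2], w[bad[1, 1], bad[1, 2]],
                 w[bad[1, 2], bad[1, 1]]))
  }
  if (any(diag(w) != 0)) stop(what, " has nonzero diagonal")
  invisible(w)
}

#' Group edge-presence mask
#'
#' An edge enters group-level analysis only if it is present (weight
#' strictly positive) in at least `min_subjects` subjects; spurious
#' connections reconstructed in few subjects are excluded. The default of 30
#' subjects is the conventional cutoff for a cohort of ~114.
#'
#' @param cohort a `svd_cohort` (see [simulate_cohort()]) or a 3-D array of
#'   per-subject connectomes, `n x n x n_subjects`.
#' @param min_subjects minimum number of subjects (>= 1).
#' @return logical symmetric matrix with `FALSE` diagonal.
#' @export
group_edge_mask <- function(cohort, min_subjects = 30L) {
  w <- cohort_weights(cohort)
  stopifnot(min_subjects >= 1)
  counts <- apply(w > 0, c(1, 2), sum)
  mask <- counts >= min_subjects
  diag(mask) <- FALSE
  mask
}

# Accept either a svd_cohort or a raw 3-D array of connectomes.
cohort_weights <- function(cohort) {
  w <- if (inherits(cohort, "svd_cohort")) cohort$weights else cohort
  if (!is.array(w) || length(dim(w)) != 3 || dim(w)[1] != dim(w)[2]) {
    stop("expected an n x n x n_subjects array of connectomes")
  }
  w
}

#' Write / read a connectome as CSV
#'
#' The CSV carries node names as header row and first column; values are
#' the symmetric weight matrix. `read_connectome_csv()` validates symmetry
#' and non-negativity and reports the first offending cell on failure.
#'
#' @param w connectome matrix.
#' @param path file path.
#' @return `write_connectome_csv` invisibly returns `path`;
#'   `read_connectome_csv` returns the matrix.
#' @export
write_connectome_csv <- function(w, path) {
  check_connectome(w)
  nms <- rownames(w) %||% as.character(seq_len(nrow(w)))
  df <- data.frame(node = nms, w, check.names = FALSE)
  colnames(df) <- c("node", nms)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (colnames(df)[1] != "node") stop("connectome CSV must start with a 'node' column")
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df$node
  storage.mode(w) <- "double"
  check_connectome(w, what = basename(path))
  w
}
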