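#' Tracking configuration
#'
#' Parameters for deterministic (FACT-style) tensor tractography. The two
#' termination thresholds mirror standard deterministic-tracking practice in
#' small vessel disease connectomics: streamlines stop when the turning angle
#' between principal eigenvectors in adjacent voxels reaches
#' `angle_stop_deg` (default 40 degrees) or when they enter a voxel with
#' fractional anisotropy below `fa_stop` (default 0.2, below which the
#' tensor's directional information is unreliable).
#'
#' @param fa_stop FA termination threshold in `(0, 1)`; seeds are placed only
#'   in voxels with `fa >= fa_stop`.
#' @param angle_stop_deg angle termination threshold in degrees, `(0, 180)`;
#'   termination fires when the inter-voxel angle is `>=` this value.
#' @param step_mm propagation step; default `NULL` means half the smallest
#'   voxel dimension of the phantom being tracked.
#' @param min_length_mm minimum retained streamline arc length; default
#'   `NULL` means two voxel lengths.
#' @param seed_per_voxel seeds per eligible voxel (placed at the voxel
#'   center; values > 1 add a fixed sub-voxel offset grid — not random).
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(fa_stop = 0.2, angle_stop_deg = 40,
                            step_mm = NULL, min_length_mm = NULL,
                            seed_per_voxel = 1L) {
  stopifnot(fa_stop > 0, fa_stop < 1,
            angle_stop_deg > 0, angle_stop_deg < 180,
            is.null(step_mm) || step_mm > 0,
            is.null(min_length_mm) || min_length_mm >= 0,
            seed_per_voxel >= 1)
  structure(list(fa_stop = fa_stop, angle_stop_deg = angle_stop_deg,
                 step_mm = step_mm, min_length_mm = min_length_mm,
                 seed_per_voxel = as.integer(seed_per_voxel)),
            class = "tracking_config")
}

#' Streamline set
#'
#' A collection of streamlines: each a polyline of 3-D points (mm
#' coordinates) with its arc length. After endpoint assignment (see
#' [assign_endpoints()]) the set additionally carries a 2-column `edges`
#' matrix of node-pair labels, one row per streamline.
#'
#' @param points list of k x 3 numeric matrices (k >= 2).
#' @param edges optional 2-column matrix of node ids (i < j) per streamline.
#' @return object of class `streamline_set` with fields `points`, `lengths`
#'   and (optionally) `edges`.
#' @export
streamline_set <- function(points, edges = NULL) {
  stopifnot(is.list(points))
  lengths <- vapply(points, function(p) {
    stopifnot(is.matrix(p), ncol(p) == 3, nrow(p) >= 2)
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  if (any(lengths <= 0)) stop("streamlines must have positive arc length")
  if (!is.null(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2)
    stopifnot(nrow(edges) == length(points))
  }
  structure(list(points = points, lengths = lengths, edges = edges),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("streamline_set: %d streamlines, length %.1f-%.1f mm%s\n",
              length(x$points),
              if (length(x$lengths)) min(x$lengths) else NA,
              if (length(x$lengths)) max(x$lengths) else NA,
              if (is.null(x$edges)) "" else " (edge-labelled)"))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$points)

# voxel index (1-based) containing mm point p; NA components if outside
point_to_voxel <- function(p, voxel_size, shape) {
  v <- floor(p / voxel_size) + 1
  if (any(v < 1) || any(v > shape)) return(NULL)
  as.integer(v)
}

voxel_center <- function(v, voxel_size) (v - 0.5) * voxel_size

# Propagate one direction from a seed voxel. Returns a matrix of points
# (excluding the seed point itself).
propagate <- function(phantom, start_point, start_voxel, direction, step,
                      fa_stop, cos_stop) {
  pts <- matrix(numeric(0), 0, 3)
  p <- start_point
  v <- start_voxel
  d <- direction
  vs <- phantom$voxel_size
  shape <- phantom$shape
  repeat {
    p_next <- p + step * d
    v_next <- point_to_voxel(p_next, vs, shape)
    if (is.null(v_next)) break                       # exits the volume
    if (!all(v_next == v)) {                         # voxel transition
      if (phantom$fa[v_next[1], v_next[2], v_next[3]] < fa_stop) break
      d_new <- phantom$principal_dir[v_next[1], v_next[2], v_next[3], ]
      # eigenvector sign is arbitrary: compare as axes
      if (abs(sum(d * d_new)) <= cos_stop) break     # angle >= threshold
      if (sum(d * d_new) < 0) d_new <- -d_new        # sign-align
      v <- v_next
      d <- d_new
    }
    pts <- rbind(pts, p_next)
    p <- p_next
  }
  pts
}

#' Deterministic tractography over a tensor phantom
#'
#' Seeds every voxel with `fa >= fa_stop` and propagates bidirectionally
#' along the per-voxel principal direction (nearest-voxel lookup, no
#' interpolation) in steps of `step_mm`. A streamline terminates when it
#' would enter a voxel with `fa < fa_stop`, when the angle between the
#' current and next voxel's principal directions (taken as undirected axes)
#' is `>= angle_stop_deg`, or when it would exit the volume; the offending
#' point is not appended, so every retained point lies in a trackable voxel.
#' Streamlines shorter than `min_length_mm` are discarded.
#'
#' @param phantom a [tensor_phantom()].
#' @param config a [tracking_config()].
#' @return a [streamline_set()] (possibly empty, with a warning, if no voxel
#'   is seedable).
#' @export
track <- function(phantom, config = tracking_config()) {
  stopifnot(inherits(phantom, "tensor_phantom"),
            inherits(config, "tracking_config"))
  vs <- phantom$voxel_size
  step <- config$step_mm %||% (min(vs) / 2)
  min_len <- config$min_length_mm %||% (2 * min(vs))
  cos_stop <- cos(config$angle_stop_deg * pi / 180)

  seeds <- which(phantom$fa >= config$fa_stop, arr.ind = TRUE)
  if (nrow(seeds) == 0) {
    warning("no voxel has fa >= fa_stop; returning an empty streamline set")
    return(structure(list(points = list(), lengths = numeric(0), edges = NULL),
                     class = "streamline_set"))
  }

  # seed offsets: voxel center, plus a fixed diagonal sub-voxel grid when
  # seed_per_voxel > 1 (deterministic; tracking has no randomness)
  m <- config$seed_per_voxel
  offs <- (seq_len(m) - (m + 1) / 2) / m  # fractions of a voxel, centered
  lines <- vector("list", nrow(seeds) * m)
  n_kept <- 0L
  for (s in seq_len(nrow(seeds))) {
    v <- as.integer(seeds[s, ])
    d <- phantom$principal_dir[v[1], v[2], v[3], ]
    for (o in offs) {
      p0 <- voxel_center(v, vs) + o * vs * 0.5
      fwd <- propagate(phantom, p0, v, d, step, config$fa_stop, cos_stop)
      bwd <- propagate(phantom, p0, v, -d, step, config$fa_stop, cos_stop)
      pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                   matrix(p0, 1, 3), fwd)
      if (nrow(pts) < 2) next
      len <- sum(sqrt(rowSums(diff(pts)^2)))
      if (len < min_len) next
      n_kept <- n_kept + 1L
      lines[[n_kept]] <- unname(pts)
    }
  }
  streamline_set(lines[seq_len(n_kept)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign node-pair endpoints to streamlines
#'
#' Looks up the node label at each streamline's first and last point and
#' attaches the unordered pair `(i, j)` (stored with `i < j`). Streamlines
#' with either endpoint in background (label 0) or with both endpoints in
#' the same node are dropped.
#'
#' @param streamlines a [streamline_set()].
#' @param node_labels 3-D integer label array aligned with the tracked
#'   phantom's grid.
#' @param voxel_size mm per axis of the label grid.
#' @return an edge-labelled [streamline_set()].
#' @export
assign_endpoints <- function(streamlines, node_labels, voxel_size) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  shape <- dim(node_labels)
  keep <- logical(length(streamlines$points))
  edges <- matrix(NA_integer_, length(streamlines$points), 2)
  for (k in seq_along(streamlines$points)) {
    p <- streamlines$points[[k]]
    lab <- vapply(list(p[1, ], p[nrow(p), ]), function(pt) {
      v <- point_to_voxel(pt, voxel_size, shape)
      if (is.null(v)) 0L else node_labels[v[1], v[2], v[3]]
    }, integer(1))
    if (all(lab > 0) && lab[1] != lab[2]) {
      keep[k] <- TRUE
      edges[k, ] <- sort(lab)
    }
  }
  streamline_set(streamlines$points[keep], edges[keep, , drop = FALSE])
}

#' Write streamlines as plain text
#'
#' One `x y z` point per line (mm), streamlines separated by blank lines,
#' with a header comment declaring the units. If the set is edge-labelled,
#' each streamline is preceded by a `# edge i j` comment.
#'
#' @param streamlines a [streamline_set()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_streamlines <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# streamlines: one 'x y z' point per line (mm); blank line separates streamlines", con)
  for (k in seq_along(streamlines$points)) {
    if (!is.null(streamlines$edges)) {
      writeLines(sprintf("# edge %d %d", streamlines$edges[k, 1],
                         streamlines$edges[k, 2]), con)
    }
    writeLines(apply(streamlines$points[[k]], 1,
                     function(r) paste(format(r, digits = 12), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read streamlines written by [write_streamlines()]
#'
#' @param path input file.
#' @return a [streamline_set()].
#' @export
read_streamlines <- function(path) {
  raw <- readLines(path)
  pts <- list(); edges <- list(); cur <- list(); cur_edge <- NA
  flush_line <- function() {
    if (length(cur) >= 2) {
      pts[[length(pts) + 1]] <<- do.call(rbind, cur)
      edges[[length(edges) + 1]] <<- cur_edge
    }
    cur <<- list(); cur_edge <<- NA
  }
  for (ln in raw) {
    ln <- trimws(ln)
    if (startsWith(ln, "# edge")) {
      cur_edge <- as.integer(strsplit(ln, "\\s+")[[1]][3:4])
    } else if (startsWith(ln, "#")) {
      next
    } else if (nzchar(ln)) {
      xyz <- as.numeric(strsplit(ln, "\\s+")[[1]])
      if (length(xyz) != 3 || anyNA(xyz)) {
        stop("malformed streamline point line: '", ln, "'")
      }
      cur[[length(cur) + 1]] <- xyz
    } else {
      flush_line()
    }
  }
  flush_line()
  has_edges <- length(pts) > 0 && all(!vapply(edges, function(e) anyNA(e), logical(1)))
  streamline_set(pts, if (has_edges) do.call(rbind, edges) else NULL)
}
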