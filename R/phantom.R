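#' Tensor phantom: a voxelized direction + FA field for tractography
#'
#' A minimal substrate for deterministic tensor tractography: per-voxel
#' principal fiber direction (unit 3-vector), fractional anisotropy (FA, in
#' `[0, 1]`) and an integer node-label volume (0 = background). This stands
#' in for the principal-eigenvector and FA maps that a tensor fit would
#' produce from diffusion MRI; tensor fitting itself is out of scope.
#'
#' @param shape integer voxel dimensions, length 3.
#' @param voxel_size mm per axis, length 1 or 3.
#' @param principal_dir 4-D array `c(shape, 3)` of per-voxel directions.
#' @param fa 3-D array of FA values in `[0, 1]`.
#' @param node_labels 3-D integer array of non-negative labels.
#' @return object of class `tensor_phantom`.
#' @export
tensor_phantom <- function(shape, voxel_size, principal_dir, fa, node_labels) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape <= 0)) {
    stop("shape must be three positive integers")
  }
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  stopifnot(identical(dim(fa), shape), identical(dim(node_labels), shape),
            identical(dim(principal_dir), c(shape, 3L)))
  if (any(fa < 0 | fa > 1)) stop("fa values must lie in [0, 1]")
  if (any(node_labels < 0)) stop("node labels must be non-negative")
  # directions must be unit-norm wherever FA is trackable
  nrm <- sqrt(principal_dir[, , , 1]^2 + principal_dir[, , , 2]^2 +
                principal_dir[, , , 3]^2)
  trackable <- fa >= 0.2
  if (any(abs(nrm[trackable] - 1) > 1e-6)) {
    stop("principal_dir must be unit-norm wherever fa >= 0.2")
  }
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 principal_dir = principal_dir, fa = fa,
                 node_labels = node_labels),
            class = "tensor_phantom")
}

#' @export
print.tensor_phantom <- function(x, ...) {
  cat(sprintf("tensor_phantom: %s voxels @ %s mm, %d labelled voxels\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              sum(x$node_labels > 0)))
  invisible(x)
}

# Shared scaffolding: an empty phantom of given shape with background FA.
empty_phantom_arrays <- function(shape, fa_outside) {
  list(dir = array(0, c(shape, 3L)),
       fa = array(fa_outside, shape),
       lab = array(0L, shape))
}

#' Straight-bundle phantom
#'
#' A rectilinear corridor of high-FA voxels along the x axis, flanked by two
#' labelled endpoint regions (labels 1 and 2, the first and last two corridor
#' voxels). The principal direction is constant `(1, 0, 0)` inside the
#' corridor; outside, FA is `fa_outside` so tracking terminates at the
#' corridor ends. Used as a fixture for the FA and endpoint-assignment rules.
#'
#' @param length_voxels corridor length in voxels (>= 4, so both endpoint
#'   regions fit).
#' @param fa_inside corridor FA (must be >= 0.2, the tracking threshold).
#' @param fa_outside background FA (must be < 0.2).
#' @param voxel_size mm per voxel (isotropic), default 2.5.
#' @return `tensor_phantom`.
#' @export
make_straight_bundle_phantom <- function(length_voxels, fa_inside = 0.8,
                                         fa_outside = 0.05, voxel_size = 2.5) {
  length_voxels <- as.integer(length_voxels)
  if (length_voxels < 4) stop("corridor needs at least 4 voxels")
  if (!(fa_inside >= 0.2 && fa_inside <= 1)) {
    stop("fa_inside must lie in [0.2, 1]: tracking requires FA >= 0.2")
  }
  if (!(fa_outside >= 0 && fa_outside < 0.2)) {
    stop("fa_outside must lie in [0, 0.2)")
  }
  shape <- c(length_voxels + 2L, 5L, 5L)  # 1-voxel low-FA margin in x
  a <- empty_phantom_arrays(shape, fa_outside)
  xs <- seq_len(length_voxels) + 1L
  yc <- 3L; zc <- 3L
  a$fa[xs, yc, zc] <- fa_inside
  a$dir[xs, yc, zc, 1] <- 1
  a$lab[xs[1:2], yc, zc] <- 1L
  a$lab[xs[c(length_voxels - 1L, length_voxels)], yc, zc] <- 2L
  tensor_phantom(shape, voxel_size, a$dir, a$fa, a$lab)
}

#' Bent-bundle phantom
#'
#' A corridor with a straight lead-in, a central bend in the x-y plane whose
#' fiber direction rotates by `bend_angle_per_step_deg` between consecutive
#' voxels (total bend ~`total_bend_deg`), and a straight lead-out. The
#' corridor is thickened to a radius of ~1.5 voxels around the continuous
#' path so that sub-voxel stepping stays inside it; endpoint labels 1 and 2
#' mark the two ends. Used to exercise the angle-based termination rule.
#'
#' @param bend_angle_per_step_deg rotation per voxel step, in degrees,
#'   in `(0, 180)`.
#' @param total_bend_deg total bend of the central section (default 90; the
#'   number of bend steps is `round(total_bend_deg / bend_angle_per_step_deg)`
#'   but at least 2).
#' @param straight_voxels length of each straight section in voxels
#'   (default 4).
#' @param fa_inside corridor FA (default 0.8).
#' @param fa_outside background FA (default 0.05).
#' @param voxel_size mm per voxel (default 2.5).
#' @return `tensor_phantom`.
#' @export
make_bent_bundle_phantom <- function(bend_angle_per_step_deg,
                                     total_bend_deg = 90,
                                     straight_voxels = 4L,
                                     fa_inside = 0.8, fa_outside = 0.05,
                                     voxel_size = 2.5) {
  if (!(bend_angle_per_step_deg > 0 && bend_angle_per_step_deg < 180)) {
    stop("bend angle per step must lie in (0, 180) degrees")
  }
  straight_voxels <- as.integer(straight_voxels)
  stopifnot(straight_voxels >= 2, total_bend_deg > 0, total_bend_deg <= 120)
  n_bend <- max(2L, as.integer(round(total_bend_deg / bend_angle_per_step_deg)))
  th <- bend_angle_per_step_deg * pi / 180

  # per-step heading: straight, rotating, straight at the final heading
  phi <- c(rep(0, straight_voxels),
           th * seq_len(n_bend),
           rep(th * n_bend, straight_voxels))
  dirs <- cbind(cos(phi), sin(phi), 0)
  knots <- rbind(c(0, 0, 0), apply(dirs, 2, cumsum))  # path knots, voxel units
  # densify: sample each unit step at 1/4-voxel intervals, carrying the
  # step's heading, so nearest-point lookup never skips a heading change
  frac <- seq(0, 0.75, by = 0.25)
  pts <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(k) {
    sweep(outer(frac, dirs[k, ]), 2, knots[k, ], "+")
  }))
  pts <- rbind(pts, knots[nrow(knots), ])
  pt_dir <- rbind(dirs[rep(seq_len(nrow(dirs)), each = length(frac)), ],
                  dirs[nrow(dirs), ])
  n_fine <- length(frac)

  pad <- 4
  lo <- floor(apply(pts[, 1:2], 2, min)) - pad
  hi <- ceiling(apply(pts[, 1:2], 2, max)) + pad
  shape <- c(as.integer(hi - lo + 1), 5L)
  a <- empty_phantom_arrays(shape, fa_outside)
  zc <- 3L
  n_pts <- nrow(pts)

  # voxel centers within 1.5 voxels of the path take the nearest path
  # point's heading; the two ends get labels 1 and 2
  for (vx in seq_len(shape[1])) {
    for (vy in seq_len(shape[2])) {
      cx <- vx + lo[1] - 1; cy <- vy + lo[2] - 1
      d2 <- (pts[, 1] - cx)^2 + (pts[, 2] - cy)^2
      nearest <- which.min(d2)
      if (d2[nearest] <= 1.5^2) {
        a$fa[vx, vy, zc] <- fa_inside
        a$dir[vx, vy, zc, ] <- pt_dir[nearest, ]
        if (nearest <= 2 * n_fine) a$lab[vx, vy, zc] <- 1L
        if (nearest > n_pts - 2 * n_fine) a$lab[vx, vy, zc] <- 2L
      }
    }
  }
  tensor_phantom(shape, voxel_size, a$dir, a$fa, a$lab)
}

#' Write a phantom to NIfTI volumes
#'
#' Writes three files under `prefix`: `<prefix>_dir.nii.gz` (4-D direction
#' field, last dimension 3), `<prefix>_fa.nii.gz` and
#' `<prefix>_labels.nii.gz`.
#'
#' @param phantom `tensor_phantom`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  paths <- paste0(prefix, c("_dir.nii.gz", "_fa.nii.gz", "_labels.nii.gz"))
  pd <- phantom$voxel_size
  as_img <- function(arr, dims) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- dims
    img
  }
  RNifti::writeNifti(as_img(phantom$principal_dir, c(pd, 1)), paths[1])
  RNifti::writeNifti(as_img(phantom$fa, pd), paths[2])
  RNifti::writeNifti(as_img(phantom$node_labels + 0L, pd), paths[3])
  invisible(paths)
}

#' Read a phantom from NIfTI volumes written by [write_phantom_nifti()]
#'
#' @param prefix path prefix used when writing.
#' @return `tensor_phantom`.
#' @export
read_phantom_nifti <- function(prefix) {
  dir_v <- RNifti::readNifti(paste0(prefix, "_dir.nii.gz"))
  fa_v <- RNifti::readNifti(paste0(prefix, "_fa.nii.gz"))
  lab_v <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  vs <- RNifti::pixdim(fa_v)[1:3]
  tensor_phantom(dim(fa_v), vs, array(as.numeric(dir_v), dim(dir_v)),
                 array(as.numeric(fa_v), dim(fa_v)),
                 array(as.integer(lab_v), dim(lab_v)))
}
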