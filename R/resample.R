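# Trilinear sampling of a 3D array at continuous 0-based voxel indices.
# idx: n x 3 matrix.  Points outside the voxel-centre extent [0, dim-1] get
# `outside` and are flagged.  Interpolated values are convex combinations of
# the 8 surrounding voxels, hence bounded by their min/max.
trilinear_sample <- function(arr, idx, outside = 0) {
  d <- dim(arr)
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
            idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
            idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  vals <- rep(as.numeric(outside), nrow(idx))
  if (any(inside)) {
    p <- idx[inside, , drop = FALSE]
    i0 <- floor(p)
    f <- p - i0
    # upper corner clamped so points exactly on the top face stay valid
    i1 <- pmin(i0 + 1, matrix(rep(d - 1, each = nrow(p)), ncol = 3))
    lin <- function(a, b, c3) 1 + a + d[1] * (b + d[2] * c3)
    v000 <- arr[lin(i0[, 1], i0[, 2], i0[, 3])]
    v100 <- arr[lin(i1[, 1], i0[, 2], i0[, 3])]
    v010 <- arr[lin(i0[, 1], i1[, 2], i0[, 3])]
    v110 <- arr[lin(i1[, 1], i1[, 2], i0[, 3])]
    v001 <- arr[lin(i0[, 1], i0[, 2], i1[, 3])]
    v101 <- arr[lin(i1[, 1], i0[, 2], i1[, 3])]
    v011 <- arr[lin(i0[, 1], i1[, 2], i1[, 3])]
    v111 <- arr[lin(i1[, 1], i1[, 2], i1[, 3])]
    fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
    c00 <- v000 * (1 - fx) + v100 * fx
    c10 <- v010 * (1 - fx) + v110 * fx
    c01 <- v001 * (1 - fx) + v101 * fx
    c11 <- v011 * (1 - fx) + v111 * fx
    c0 <- c00 * (1 - fy) + c10 * fy
    c1 <- c01 * (1 - fy) + c11 * fy
    vals[inside] <- c0 * (1 - fz) + c1 * fz
  }
  list(values = vals, inside = inside)
}

#' Resample a prior-course physical dose grid onto the current geometry
#'
#' Each voxel centre of the target geometry is mapped to the prior-course
#' frame through \code{transform} (current-to-prior pull-back) and the prior
#' dose is interpolated trilinearly there.  Points falling outside the prior
#' grid's voxel-centre extent receive 0 Gy and are tallied, so inadequate
#' prior grid coverage is visible rather than silent.
#'
#' @param prior a PHYSICAL \code{dose_grid} of the prior course.
#' @param transform a \code{spatial_transform} mapping current-frame points to
#'   prior-frame points.
#' @param target \code{grid_geometry} of the current planning grid.
#' @return a PHYSICAL \code{dose_grid} on \code{target}, with attribute
#'   \code{"out_of_extent"} holding the count of target voxels that mapped
#'   outside the prior grid.
#' @export
resample_dose <- function(prior, transform, target) {
  if (!inherits(prior, "dose_grid")) stop("prior must be a dose_grid")
  if (prior$dose_kind != "PHYSICAL")
    stop("contract violation: resample_dose maps PHYSICAL dose; convert to EQD2 after mapping")
  pts <- voxel_to_physical(target, all_voxel_indices(target))
  prior_pts <- transform_points(transform, pts)
  idx <- physical_to_voxel(prior$geometry, prior_pts)
  s <- trilinear_sample(prior$values, idx, outside = 0)
  out <- dose_grid(array(s$values, dim = target$shape), target,
                   dose_kind = "PHYSICAL", course_id = prior$course_id)
  attr(out, "out_of_extent") <- sum(!s$inside)
  out
}
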