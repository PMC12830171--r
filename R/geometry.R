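#' Grid geometry of a dose or mask volume
#'
#' Describes a regular 3D voxel grid: its physical origin (the centre of
#' voxel \code{[1,1,1]}), voxel spacing, voxel counts, direction cosines and
#' a frame-of-reference label.  Physical point of the 0-based voxel index
#' \code{v} is \code{origin + orientation \%*\% (v * spacing)}.
#'
#' @param origin numeric(3), mm.
#' @param spacing numeric(3), mm, all > 0.
#' @param shape integer(3), voxel counts along x, y, z, all >= 1.
#' @param orientation 3x3 orthonormal direction-cosine matrix (columns are
#'   the patient-space directions of the grid axes).  Default identity.
#' @param frame_id opaque frame-of-reference label.
#' @return An object of class \code{grid_geometry}.
#' @export
grid_geometry <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1),
                          shape = c(1, 1, 1), orientation = diag(3),
                          frame_id = "FRAME") {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (length(origin) != 3L || length(spacing) != 3L || length(shape) != 3L)
    stop("origin, spacing and shape must each have length 3")
  if (any(!is.finite(origin))) stop("origin must be finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be > 0")
  if (any(is.na(shape)) || any(shape < 1L))
    stop("all shape components must be >= 1")
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation matrix must be orthonormal (within 1e-6)")
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 orientation = orientation, frame_id = as.character(frame_id)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %dx%dx%d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm, frame '%s'\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3], x$frame_id))
  invisible(x)
}

#' Voxel volume of a grid geometry in cubic centimetres
#' @param geom a \code{grid_geometry}.
#' @return scalar cc.
#' @export
voxel_volume_cc <- function(geom) prod(geom$spacing) / 1000

#' Test whether two geometries describe the same grid
#' @param a,b \code{grid_geometry} objects.
#' @param tol numeric tolerance on origin/spacing/orientation.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= tol
}

stop_if_geometry_mismatch <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry mismatch: %s must share one grid geometry", what))
  invisible(TRUE)
}

# Physical coordinates (rows) of 0-based voxel indices idx (n x 3 matrix).
voxel_to_physical <- function(geom, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx %*% diag(geom$spacing) %*% t(geom$orientation), 2, geom$origin, "+")
}

# Continuous 0-based voxel indices of physical points pts (n x 3 matrix).
physical_to_voxel <- function(geom, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts, 2, geom$origin, "-") %*% geom$orientation %*% diag(1 / geom$spacing)
}

# n x 3 matrix of 0-based indices of every voxel, in column-major array order.
all_voxel_indices <- function(geom) {
  s <- geom$shape
  cbind(rep_len(seq_len(s[1]) - 1L, prod(s)),
        rep(rep(seq_len(s[2]) - 1L, each = s[1]), times = s[3]),
        rep(seq_len(s[3]) - 1L, each = s[1] * s[2]))
}

#' Dose grid
#'
#' A regular 3D scalar dose volume with its geometry and a dose-kind tag
#' distinguishing physical dose from equieffective dose in 2 Gy fractions.
#'
#' @param values numeric 3D array of dose in Gy, finite and >= 0, with
#'   dimensions equal to \code{geometry$shape}.
#' @param geometry a \code{grid_geometry}.
#' @param dose_kind "PHYSICAL" or "EQD2".
#' @param course_id label of the course the dose belongs to.
#' @return An object of class \code{dose_grid}.
#' @export
dose_grid <- function(values, geometry, dose_kind = c("PHYSICAL", "EQD2"),
                      course_id = "") {
  dose_kind <- match.arg(dose_kind)
  values <- array(as.numeric(values), dim = geometry$shape)
  if (!all(is.finite(values))) stop("dose values must be finite")
  if (any(values < 0)) stop("dose values must be >= 0")
  structure(list(values = values, geometry = geometry, dose_kind = dose_kind,
                 course_id = as.character(course_id)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid [%s]%s: %dx%dx%d voxels, range %.3f-%.3f Gy\n",
              x$dose_kind,
              if (nzchar(x$course_id)) paste0(" course '", x$course_id, "'") else "",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Named boolean structure mask on a grid geometry
#'
#' @param name structure name.
#' @param mask logical 3D array with dimensions \code{geometry$shape}.
#' @param geometry a \code{grid_geometry}.
#' @return An object of class \code{structure_mask}.
#' @export
structure_mask <- function(name, mask, geometry) {
  mask <- array(as.logical(mask), dim = geometry$shape)
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(list(name = as.character(name), mask = mask, geometry = geometry),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s': %d voxels, %.3f cc\n",
              x$name, sum(x$mask), mask_volume_cc(x)))
  invisible(x)
}

#' Volume of a structure mask in cc
#' @param mask a \code{structure_mask}.
#' @return scalar cc (voxel count times voxel volume).
#' @export
mask_volume_cc <- function(mask) sum(mask$mask) * voxel_volume_cc(mask$geometry)
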