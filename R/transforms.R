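#' Spatial transforms between the current and a prior course frame
#'
#' A transform maps a point in the CURRENT planning frame to the
#' corresponding point in the PRIOR-course frame (pull-back convention), so
#' resampling prior dose onto the current geometry needs no inversion.
#' Registration itself (rigid or deformable) is never computed here; the
#' transform is the registration result supplied by the user.
#'
#' @param affine 4x4 homogeneous matrix; its 3x3 linear part must be
#'   invertible.
#' @return An object of class \code{spatial_transform}.
#' @export
transform_affine <- function(affine) {
  affine <- matrix(as.numeric(affine), 4, 4)
  if (any(!is.finite(affine))) stop("affine matrix must be finite")
  if (abs(det(affine[1:3, 1:3])) <= 1e-12)
    stop("invalid transform: affine linear part is not invertible")
  structure(list(kind = "AFFINE", affine = affine), class = "spatial_transform")
}

#' @rdname transform_affine
#' @export
transform_identity <- function() {
  structure(list(kind = "IDENTITY"), class = "spatial_transform")
}

#' @rdname transform_affine
#' @param translation_mm numeric(3) translation in mm added to current-frame
#'   points to reach the prior frame.
#' @export
transform_translation <- function(translation_mm) {
  m <- diag(4)
  m[1:3, 4] <- as.numeric(translation_mm)
  transform_affine(m)
}

#' @rdname transform_affine
#' @param dvf 4D numeric array (nx, ny, nz, 3) of displacement vectors in mm,
#'   laid out like a dose grid with a trailing component axis; displacement is
#'   ADDED to a current-frame point to obtain the prior-frame point.
#' @param geometry \code{grid_geometry} the DVF is sampled on.
#' @export
transform_dvf <- function(dvf, geometry) {
  dvf <- array(as.numeric(dvf), dim = c(geometry$shape, 3L))
  if (any(!is.finite(dvf))) stop("dvf components must be finite")
  structure(list(kind = "DVF", dvf = dvf, geometry = geometry),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("spatial_transform: %s\n", x$kind))
  invisible(x)
}

#' Apply a spatial transform to physical points
#'
#' @param transform a \code{spatial_transform}.
#' @param pts n x 3 matrix of current-frame points in mm.
#' @return n x 3 matrix of prior-frame points in mm.  DVF displacements are
#'   sampled with trilinear interpolation; points outside the DVF grid take
#'   zero displacement.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  switch(transform$kind,
    IDENTITY = pts,
    AFFINE = {
      out <- cbind(pts, 1) %*% t(transform$affine)
      out[, 1:3, drop = FALSE]
    },
    DVF = {
      idx <- physical_to_voxel(transform$geometry, pts)
      disp <- vapply(1:3, function(c3)
        trilinear_sample(transform$dvf[, , , c3], idx, outside = 0)$values,
        numeric(nrow(pts)))
      pts + matrix(disp, ncol = 3)
    },
    stop("unknown transform kind: ", transform$kind))
}

#' Read a transform from a JSON file
#'
#' Accepted forms: \code{{"kind":"identity"}},
#' \code{{"kind":"affine","matrix":[[...4x4 row-major...]]}}, or
#' \code{{"kind":"dvf","file":"disp.nii.gz"}} where the NIfTI holds a 4D
#' (x,y,z,3) displacement field in mm (path relative to the JSON file).
#'
#' @param path JSON file path.
#' @return a \code{spatial_transform}.
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  spec <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  kind <- toupper(spec$kind %||% "")
  switch(kind,
    IDENTITY = transform_identity(),
    AFFINE = transform_affine(spec$matrix),   # row-major nested arrays
    DVF = {
      f <- file.path(dirname(path), spec$file)
      vol <- read_nifti_volume(f)
      transform_dvf(vol$values, vol$geometry)
    },
    stop("unknown transform kind in ", path, ": '", spec$kind, "'"))
}

#' Write a transform to a JSON file
#' @param transform a \code{spatial_transform} (IDENTITY or AFFINE; a DVF is
#'   written as a side-car NIfTI next to the JSON).
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  spec <- switch(transform$kind,
    IDENTITY = list(kind = "identity"),
    AFFINE = list(kind = "affine", matrix = transform$affine),
    DVF = {
      f <- paste0(sub("\\.json$", "", path), "_dvf.nii.gz")
      write_nifti_volume(transform$dvf, transform$geometry, f)
      list(kind = "dvf", file = basename(f))
    })
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
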