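# NIfTI I/O through RNifti.  The grid's axis frame is written directly into
# the sform/qform (orientation * spacing with the origin as offset), so a
# write -> read cycle restores geometry exactly and float32 values
# bit-exactly.

geom_to_xform <- function(geom) {
  m <- diag(4)
  m[1:3, 1:3] <- geom$orientation %*% diag(geom$spacing)
  m[1:3, 4] <- geom$origin
  m
}

#' Write a volume (3D or 4D array) to NIfTI
#' @param values numeric array; 3D, or 4D for multi-component fields.
#' @param geometry a \code{grid_geometry} for the first three axes.
#' @param path output path (.nii or .nii.gz).
#' @param datatype storage type (default "float" = float32).
#' @return \code{path}, invisibly.
#' @export
write_nifti_volume <- function(values, geometry, path, datatype = "float") {
  img <- RNifti::asNifti(values)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- geometry$spacing
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(geom_to_xform(geometry), code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume with its grid geometry
#' @param path NIfTI file path.
#' @param frame_id frame label to attach (default "FRAME").
#' @return list with \code{values} (array) and \code{geometry}.
#' @export
read_nifti_volume <- function(path, frame_id = "FRAME") {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  dm <- dim(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  ori <- xf[1:3, 1:3] %*% diag(1 / spacing)
  geom <- grid_geometry(origin = xf[1:3, 4], spacing = spacing,
                        shape = dm[1:3], orientation = ori,
                        frame_id = frame_id)
  list(values = array(as.numeric(img), dim = dm), geometry = geom)
}

#' Read/write dose grids and masks as NIfTI
#' @param grid a \code{dose_grid}; \code{mask} a \code{structure_mask}.
#' @param path NIfTI path.
#' @param dose_kind,course_id,name metadata not representable in NIfTI,
#'   supplied on read.
#' @return see individual functions.
#' @export
write_dose_nifti <- function(grid, path)
  write_nifti_volume(grid$values, grid$geometry, path, datatype = "float")

#' @rdname write_dose_nifti
#' @export
read_dose_nifti <- function(path, dose_kind = "PHYSICAL", course_id = "",
                            frame_id = "FRAME") {
  v <- read_nifti_volume(path, frame_id)
  dose_grid(v$values, v$geometry, dose_kind = dose_kind, course_id = course_id)
}

#' @rdname write_dose_nifti
#' @export
write_mask_nifti <- function(mask, path)
  write_nifti_volume(mask$mask * 1, mask$geometry, path, datatype = "uint8")

#' @rdname write_dose_nifti
#' @export
read_mask_nifti <- function(path, name, frame_id = "FRAME") {
  v <- read_nifti_volume(path, frame_id)
  structure_mask(name, v$values > 0.5, v$geometry)
}
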