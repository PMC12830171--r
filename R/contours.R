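# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# px, py: point coords; vx, vy: polygon vertices (closed implicitly).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize planar closed contours into a structure mask
#'
#' Each contour is a closed in-plane polygon with a slice z position; it is
#' assigned to the nearest grid slice (within half a slice spacing) and a
#' voxel is inside iff its centre falls inside the polygon under the even-odd
#' rule.  Multiple polygons on one slice combine by even-odd parity, so
#' disjoint polygons add and nested polygons cut holes — the DICOM RT
#' Structure Set convention.  Axis-aligned geometries only.
#'
#' @param contours list of contours; each a list with \code{points} (n x 2
#'   matrix of in-plane x, y mm, n >= 3) and \code{z} (slice position mm).
#'   An n x 3 matrix with constant third column is also accepted.
#' @param target \code{grid_geometry} (axis-aligned).
#' @param name structure name for the returned mask.
#' @return a \code{structure_mask}; an empty contour list gives an all-false
#'   mask.
#' @export
rasterize_contours <- function(contours, target, name = "structure") {
  mask <- array(FALSE, dim = target$shape)
  xs <- target$origin[1] + (seq_len(target$shape[1]) - 1) * target$spacing[1]
  ys <- target$origin[2] + (seq_len(target$shape[2]) - 1) * target$spacing[2]
  zs <- target$origin[3] + (seq_len(target$shape[3]) - 1) * target$spacing[3]
  px <- rep(xs, times = target$shape[2])
  py <- rep(ys, each = target$shape[1])
  for (ct in contours) {
    if (is.matrix(ct) || is.data.frame(ct)) {
      m <- as.matrix(ct)
      ct <- list(points = m[, 1:2, drop = FALSE], z = m[1, 3])
    }
    pts <- matrix(as.numeric(ct$points), ncol = ncol(ct$points))
    if (nrow(pts) < 3) stop("malformed contour: polygon needs >= 3 vertices")
    k <- which.min(abs(zs - ct$z))
    if (abs(zs[k] - ct$z) > target$spacing[3] / 2 + 1e-6) {
      warning(sprintf("contour at z=%.3f mm lies off all slice planes; skipped", ct$z))
      next
    }
    inside <- point_in_polygon(px, py, pts[, 1], pts[, 2])
    mask[, , k] <- xor(mask[, , k], matrix(inside, target$shape[1], target$shape[2]))
  }
  structure_mask(name, mask, target)
}

#' Trace a mask back into per-slice closed contours
#'
#' Marching-squares contour tracing (\code{grDevices::contourLines} at level
#' 0.5 on each slice of the 0/1 mask) produces closed planar polygons midway
#' between inside and outside voxel centres, suitable for RT Structure Set
#' export.  Re-rasterizing recovers the mask up to its one-voxel boundary
#' layer.
#'
#' @param mask a \code{structure_mask} on an axis-aligned geometry.
#' @return list of contours in the \code{rasterize_contours} input form.
#' @export
mask_to_contours <- function(mask) {
  g <- mask$geometry
  # pad with a false border so boundary-touching structures close properly
  xs <- g$origin[1] + (0:(g$shape[1] + 1) - 1) * g$spacing[1]
  ys <- g$origin[2] + (0:(g$shape[2] + 1) - 1) * g$spacing[2]
  out <- list()
  for (k in seq_len(g$shape[3])) {
    if (!any(mask$mask[, , k])) next
    z <- matrix(0, g$shape[1] + 2, g$shape[2] + 2)
    z[2:(g$shape[1] + 1), 2:(g$shape[2] + 1)] <- mask$mask[, , k] * 1
    cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
    zk <- g$origin[3] + (k - 1) * g$spacing[3]
    for (loop in cl) {
      pts <- cbind(loop$x, loop$y)
      # close the loop explicitly
      if (any(pts[1, ] != pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
      out[[length(out) + 1L]] <- list(points = pts, z = zk)
    }
  }
  out
}
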