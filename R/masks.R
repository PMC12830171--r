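#' Voxel-wise boolean operations on structure masks
#'
#' @param a,b \code{structure_mask} objects on the same geometry.
#' @param op one of "UNION", "INTERSECT", "SUBTRACT";
#'   \code{SUBTRACT(a, b) = a AND NOT b}.
#' @param name name for the result (default derived from the operands).
#' @return a \code{structure_mask}.
#' @export
mask_boolean <- function(a, b, op = c("UNION", "INTERSECT", "SUBTRACT"),
                         name = NULL) {
  op <- match.arg(op)
  stop_if_geometry_mismatch(a$geometry, b$geometry, "masks")
  m <- switch(op,
    UNION = a$mask | b$mask,
    INTERSECT = a$mask & b$mask,
    SUBTRACT = a$mask & !b$mask)
  if (is.null(name))
    name <- sprintf("(%s %s %s)", a$name, tolower(op), b$name)
  structure_mask(name, m, a$geometry)
}

#' @rdname mask_boolean
#' @export
mask_union <- function(a, b, name = NULL) mask_boolean(a, b, "UNION", name)

#' @rdname mask_boolean
#' @export
mask_intersect <- function(a, b, name = NULL) mask_boolean(a, b, "INTERSECT", name)

#' @rdname mask_boolean
#' @export
mask_subtract <- function(a, b, name = NULL) mask_boolean(a, b, "SUBTRACT", name)

#' Dilate a mask by a Euclidean margin in millimetres
#'
#' A voxel joins the dilated mask iff its centre lies within \code{margin_mm}
#' (Euclidean distance, anisotropic spacing respected) of some voxel centre of
#' the input mask.  Distances are computed exactly against the mask's boundary
#' voxels, chunked to bound memory; deterministic.
#'
#' @param mask a \code{structure_mask}.
#' @param margin_mm margin >= 0 in mm.
#' @return a \code{structure_mask} containing the input.
#' @export
mask_dilate <- function(mask, margin_mm) {
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  if (margin_mm == 0 || !any(mask$mask)) return(mask)
  g <- mask$geometry
  s <- g$shape
  m <- mask$mask
  # boundary voxels: in mask with at least one out-of-mask 6-neighbour
  shift_and <- function(arr) {
    core <- array(TRUE, dim = s)
    nb <- function(di, dj, dk) {
      out <- array(FALSE, dim = s)
      i <- seq_len(s[1]); j <- seq_len(s[2]); k <- seq_len(s[3])
      si <- i + di; sj <- j + dj; sk <- k + dk
      ok_i <- si >= 1 & si <= s[1]; ok_j <- sj >= 1 & sj <= s[2]; ok_k <- sk >= 1 & sk <= s[3]
      out[i[ok_i], j[ok_j], k[ok_k]] <- arr[si[ok_i], sj[ok_j], sk[ok_k]]
      out
    }
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
      core <- core & nb(d[1], d[2], d[3])
    core
  }
  interior <- m & shift_and(m)
  boundary_idx <- which(m & !interior)
  if (length(boundary_idx) == 0L) boundary_idx <- which(m)
  bidx <- arrayInd(boundary_idx, s) - 1L
  bpts <- sweep(bidx, 2, g$spacing, "*")   # axis-aligned: work in grid frame
  # candidate voxels: inside the mask's bounding box grown by the margin
  rng <- apply(arrayInd(which(m), s), 2, range)
  grow <- ceiling(margin_mm / g$spacing)
  lo <- pmax(rng[1, ] - grow, 1); hi <- pmin(rng[2, ] + grow, s)
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  lin <- cand[, 1] + s[1] * (cand[, 2] - 1L + s[2] * (cand[, 3] - 1L))
  keep <- !m[lin]                          # mask voxels are trivially inside
  cand <- cand[keep, , drop = FALSE]; lin <- lin[keep]
  out <- m
  if (nrow(cand)) {
    cpts <- sweep(cand - 1L, 2, g$spacing, "*")
    m2 <- margin_mm^2
    chunk <- max(1L, floor(2e7 / nrow(bpts)))
    for (start in seq(1L, nrow(cpts), by = chunk)) {
      ii <- start:min(start + chunk - 1L, nrow(cpts))
      d2 <- outer(rowSums(cpts[ii, , drop = FALSE]^2), rowSums(bpts^2), "+") -
        2 * cpts[ii, , drop = FALSE] %*% t(bpts)
      hit <- apply(d2 <= m2 + 1e-9, 1, any)
      out[lin[ii][hit]] <- TRUE
    }
  }
  structure_mask(mask$name, out, g)
}
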