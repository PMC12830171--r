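# Shared fixture builders; everything is generated in code, no stored data.

small_geom <- function(shape = c(8, 8, 4), spacing = c(2, 2, 2),
                       origin = c(0, 0, 0))
  grid_geometry(origin = origin, spacing = spacing, shape = shape)

uniform_dose <- function(value, geom, kind = "PHYSICAL", course_id = "c")
  dose_grid(array(value, dim = geom$shape), geom, dose_kind = kind,
            course_id = course_id)

random_dose <- function(geom, max_gy = 70, kind = "PHYSICAL") {
  dose_grid(array(stats::runif(prod(geom$shape), 0, max_gy),
                  dim = geom$shape), geom, dose_kind = kind)
}

random_mask <- function(geom, p = 0.4, name = "m") {
  m <- array(stats::runif(prod(geom$shape)) < p, dim = geom$shape)
  if (!any(m)) m[1] <- TRUE
  structure_mask(name, m, geom)
}

full_mask <- function(geom, name = "all")
  structure_mask(name, array(TRUE, dim = geom$shape), geom)

# square contour (axis-aligned, side mm, centred at cx, cy) at slice z
square_contour <- function(cx, cy, side, z) {
  h <- side / 2
  list(points = rbind(c(cx - h, cy - h), c(cx + h, cy - h),
                      c(cx + h, cy + h), c(cx - h, cy + h)), z = z)
}

# brute-force near-max dose metric: full sort, no binning
oracle_d_cc <- function(values, mask, voxel_cc, x_cc) {
  d <- sort(values[mask], decreasing = TRUE)
  k <- ceiling(x_cc / voxel_cc - 1e-12)
  if (k > length(d)) return(min(d))
  d[k]
}

fig4_accumulated <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      case <- make_fig4_case()
      res <- accumulate(case$courses, case$geometry, case$structures,
                        alpha_beta_map())
      cache <<- list(case = case, res = res,
                     oar = case$structures[[2]], target = case$structures[[1]])
    }
    cache
  }
})
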