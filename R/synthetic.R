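# Deterministic synthetic reirradiation cases: smooth prior dose
# distributions (flat high-dose core with a Gaussian shoulder), spherical or
# cuboid OAR/target masks, configurable fractionation and recovery factors.
# The flat-core profile makes isodose shells analytically checkable.

#' Specification of a synthetic reirradiation case
#'
#' @param shape,spacing,origin grid definition (defaults: 48 x 48 x 24
#'   voxels at 2.5 mm isotropic — a torso-region planning grid at the
#'   resolution dose grids typically use).
#' @param courses list of prior courses; each a list with \code{course_id},
#'   \code{center} (mm), \code{peak} (Gy), \code{core_radius} (mm),
#'   \code{sigma} (mm, Gaussian shoulder), \code{n_fractions}, optional
#'   \code{dsf} and \code{transform}.
#' @param structures list of shapes; each a list with \code{name},
#'   \code{kind} ("sphere" or "cuboid"), \code{center} (mm) and
#'   \code{radius} (mm) or \code{size} (mm, full widths).
#' @param jitter_mm optional uniform jitter applied to shape centres.
#' @param seed integer seed for the jitter (fixed seed gives bit-identical
#'   output; with \code{jitter_mm = 0} the case is fully deterministic).
#' @param case_id label.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_case_spec <- function(shape = c(48, 48, 24),
                                spacing = c(2.5, 2.5, 2.5),
                                origin = c(0, 0, 0),
                                courses, structures,
                                jitter_mm = 0, seed = 1L,
                                case_id = "synthetic") {
  for (cr in courses) {
    if ((cr$peak %||% -1) < 0) stop("peak dose must be >= 0")
    if ((cr$sigma %||% 0) <= 0) stop("sigma must be > 0")
  }
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 courses = courses, structures = structures,
                 jitter_mm = jitter_mm, seed = as.integer(seed),
                 case_id = case_id),
            class = "synthetic_spec")
}

# distance from every voxel centre to a point, mm
voxel_distances <- function(geom, center) {
  pts <- voxel_to_physical(geom, all_voxel_indices(geom))
  sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
         (pts[, 3] - center[3])^2)
}

check_inside_grid <- function(geom, center, reach, what) {
  lo <- geom$origin
  hi <- geom$origin + (geom$shape - 1) * geom$spacing
  if (any(center - reach < lo - 1e-9) || any(center + reach > hi + 1e-9))
    stop(what, " extends outside the grid extent")
}

shape_mask <- function(geom, st) {
  if (st$kind == "sphere") {
    check_inside_grid(geom, st$center, st$radius, paste0("structure '", st$name, "'"))
    m <- voxel_distances(geom, st$center) <= st$radius
  } else if (st$kind == "cuboid") {
    check_inside_grid(geom, st$center, st$size / 2, paste0("structure '", st$name, "'"))
    pts <- voxel_to_physical(geom, all_voxel_indices(geom))
    m <- abs(pts[, 1] - st$center[1]) <= st$size[1] / 2 &
         abs(pts[, 2] - st$center[2]) <= st$size[2] / 2 &
         abs(pts[, 3] - st$center[3]) <= st$size[3] / 2
  } else stop("unknown shape kind: ", st$kind)
  structure_mask(st$name, array(m, dim = geom$shape), geom)
}

# flat core with Gaussian shoulder: peak * exp(-max(0, dist - r)^2 / (2 s^2))
core_falloff_dose <- function(geom, center, peak, core_radius, sigma) {
  d <- voxel_distances(geom, center)
  excess <- pmax(0, d - core_radius)
  array(peak * exp(-excess^2 / (2 * sigma^2)), dim = geom$shape)
}

#' Generate a synthetic reirradiation case
#'
#' Each prior course's dose is \code{peak * exp(-max(0, dist - core_radius)^2
#' / (2 sigma^2))}: exactly \code{peak} inside the core, Gaussian falloff
#' outside.  Masks are rasterized analytically from the shape definitions.
#' Output is byte-identical for a fixed spec and seed.
#'
#' @param spec a \code{synthetic_spec}.
#' @return a case list (\code{case_id}, \code{geometry}, \code{courses} of
#'   \code{course_record}, \code{structures} of \code{structure_mask}) as
#'   accepted by \code{\link{write_case_bundle}} and \code{\link{accumulate}}.
#' @export
make_case <- function(spec) {
  geom <- grid_geometry(origin = spec$origin, spacing = spec$spacing,
                        shape = spec$shape, frame_id = spec$case_id)
  jit <- function(center) {
    if (spec$jitter_mm > 0) center + stats::runif(3, -spec$jitter_mm, spec$jitter_mm)
    else center
  }
  if (spec$jitter_mm > 0) set.seed(spec$seed)
  courses <- lapply(spec$courses, function(cr) {
    ctr <- jit(unlist(cr$center))
    check_inside_grid(geom, ctr, cr$core_radius,
                      paste0("course '", cr$course_id, "' dose core"))
    dose <- dose_grid(core_falloff_dose(geom, ctr, cr$peak, cr$core_radius,
                                        cr$sigma),
                      geom, dose_kind = "PHYSICAL", course_id = cr$course_id)
    course_record(cr$course_id, dose, fractionation(cr$n_fractions),
                  transform = cr$transform %||% transform_identity(),
                  dsf = dose_scaling_factor(cr$dsf %||% 1),
                  source_tps = "synthetic")
  })
  structures <- lapply(spec$structures, function(st) {
    st$center <- jit(unlist(st$center))
    shape_mask(geom, st)
  })
  list(case_id = spec$case_id, geometry = geom, courses = courses,
       structures = structures, spec = spec)
}

#' A calibrated two-structure worked-example case
#'
#' Two prior courses with co-centred flat dose cores overlapping an OAR that
#' abuts the new target.  The course peaks are calibrated through the
#' inverse LQ conversion (40 EQD2 Gy in 25 fractions plus 17 EQD2 Gy in 10
#' fractions at alpha/beta 3) so that the accumulated near-target OAR Dmax
#' is exactly 57 EQD2 Gy — the P of the worked optimization-structure
#' example with R = 60 and A = 60 — while the Gaussian shoulders lay a
#' smooth gradient across the OAR for non-degenerate isodose shells.
#'
#' @return a case list as from \code{\link{make_case}}.
#' @export
make_fig4_case <- function() {
  ab <- 3
  peak1 <- eqd2_inverse(40, 25, ab)
  peak2 <- eqd2_inverse(17, 10, ab)
  spec <- synthetic_case_spec(
    shape = c(48, 48, 24), spacing = c(2.5, 2.5, 2.5), origin = c(0, 0, 0),
    courses = list(
      list(course_id = "C1", center = c(60, 52.5, 27.5), peak = peak1,
           core_radius = 15, sigma = 12, n_fractions = 25),
      list(course_id = "C2", center = c(60, 52.5, 27.5), peak = peak2,
           core_radius = 15, sigma = 12, n_fractions = 10)),
    structures = list(
      list(name = "PTV", kind = "sphere", center = c(60, 40, 27.5),
           radius = 12),
      list(name = "OAR", kind = "sphere", center = c(60, 72.5, 27.5),
           radius = 15)),
    case_id = "fig4_like")
  make_case(spec)
}
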