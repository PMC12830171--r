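#' Fractionation scheme
#' @param n_fractions positive integer number of fractions.
#' @param prescription_total optional prescription total dose in Gy.
#' @return object of class \code{fractionation}.
#' @export
fractionation <- function(n_fractions, prescription_total = NULL) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L) stop("n_fractions must be >= 1")
  if (!is.null(prescription_total) && prescription_total < 0)
    stop("prescription_total must be >= 0")
  structure(list(n_fractions = n_fractions,
                 prescription_total = prescription_total),
            class = "fractionation")
}

#' Convert physical dose to EQD2 under the linear-quadratic model
#'
#' \deqn{EQD2 = D \cdot \frac{d + \alpha/\beta}{2 + \alpha/\beta}, \quad d = D/n}
#'
#' EQD2 equals the physical dose exactly at 2 Gy per fraction, exceeds it for
#' hypofractionation (d > 2 Gy) and falls below it for d < 2 Gy.
#'
#' @param total_dose total physical dose D in Gy (vectorized, >= 0).
#' @param n_fractions number of fractions n (>= 1).
#' @param alpha_beta tissue alpha/beta ratio in Gy (> 0).
#' @return EQD2 in Gy, same length as \code{total_dose}.
#' @export
eqd2_forward <- function(total_dose, n_fractions, alpha_beta) {
  if (alpha_beta <= 0) stop("alpha_beta must be > 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (any(total_dose < 0)) stop("total_dose must be >= 0")
  total_dose * (total_dose / n_fractions + alpha_beta) / (2 + alpha_beta)
}

#' Invert EQD2 to total physical dose for a fractionation scheme
#'
#' Solves \eqn{D^2/n + (\alpha/\beta) D - EQD2 (2 + \alpha/\beta) = 0} for its
#' unique non-negative root:
#' \deqn{D = \frac{n}{2}\left(-\alpha/\beta +
#'   \sqrt{(\alpha/\beta)^2 + 4\,EQD2\,(2+\alpha/\beta)/n}\right)}
#'
#' @param target_eqd2 EQD2 in Gy (vectorized, >= 0).
#' @param n_fractions number of fractions (>= 1).
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @return total physical dose in Gy delivering \code{target_eqd2} in
#'   \code{n_fractions} fractions.
#' @export
eqd2_inverse <- function(target_eqd2, n_fractions, alpha_beta) {
  if (alpha_beta <= 0) stop("alpha_beta must be > 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (any(target_eqd2 < 0)) stop("target_eqd2 must be >= 0")
  (n_fractions / 2) *
    (-alpha_beta + sqrt(alpha_beta^2 +
                          4 * target_eqd2 * (2 + alpha_beta) / n_fractions))
}

#' Alpha/beta assignment table
#'
#' Maps structure names to alpha/beta ratios with explicit priority ranks; a
#' voxel inside several structures takes the alpha/beta of the
#' highest-priority (lowest rank number) one, and voxels in no listed
#' structure take \code{default_ab}.
#'
#' @param entries data.frame with columns \code{structure}, \code{ab} (Gy, >
#'   0) and \code{priority} (unique ranks; 1 = highest).  May be empty.
#' @param default_ab alpha/beta in Gy for unlisted tissue (default 3 Gy, the
#'   conventional late-responding normal-tissue value).
#' @param version free-text label recorded in provenance.
#' @return object of class \code{alpha_beta_map}.
#' @export
alpha_beta_map <- function(entries = NULL, default_ab = 3, version = "unversioned") {
  if (is.null(entries))
    entries <- data.frame(structure = character(), ab = numeric(),
                          priority = integer())
  entries <- as.data.frame(entries)
  if (nrow(entries)) {
    if (any(entries$ab <= 0)) stop("all alpha/beta ratios must be > 0")
    if (anyDuplicated(entries$priority))
      stop("priority ranks must be unique")
    entries <- entries[order(entries$priority), , drop = FALSE]
  }
  if (default_ab <= 0) stop("default_ab must be > 0")
  structure(list(entries = entries, default_ab = default_ab,
                 version = as.character(version)),
            class = "alpha_beta_map")
}

# alpha/beta looked up by structure name (default when absent)
ab_for_structure <- function(ab_map, name) {
  i <- match(name, ab_map$entries$structure)
  if (is.na(i)) ab_map$default_ab else ab_map$entries$ab[i]
}

#' Convert a physical dose grid to EQD2 voxel-wise
#'
#' Per-voxel dose per fraction is voxel dose divided by the course's fraction
#' number (uniform fractionation across the course).  Each voxel's
#' alpha/beta comes from the highest-priority structure containing it, else
#' the map's default; conversion uses the CURRENT plan's structures.
#'
#' @param dose a PHYSICAL \code{dose_grid}.
#' @param scheme a \code{fractionation}.
#' @param ab_map an \code{alpha_beta_map}.
#' @param structures list of \code{structure_mask} on the dose geometry.
#' @return an EQD2 \code{dose_grid} on the same geometry.
#' @export
eqd2_convert_grid <- function(dose, scheme, ab_map, structures = list()) {
  if (dose$dose_kind != "PHYSICAL")
    stop("eqd2_convert_grid expects a PHYSICAL dose grid")
  by_name <- stats::setNames(structures, vapply(structures, `[[`, "", "name"))
  ab <- array(ab_map$default_ab, dim = dose$geometry$shape)
  # walk priorities from lowest to highest so higher priority overwrites
  ent <- ab_map$entries
  if (nrow(ent)) {
    for (i in rev(seq_len(nrow(ent)))) {
      sm <- by_name[[ent$structure[i]]]
      if (is.null(sm)) {
        warning("structure '", ent$structure[i],
                "' in alpha/beta map not found; entry skipped")
        next
      }
      stop_if_geometry_mismatch(sm$geometry, dose$geometry, "dose and masks")
      ab[sm$mask] <- ent$ab[i]
    }
  }
  D <- dose$values
  vals <- D * (D / scheme$n_fractions + ab) / (2 + ab)
  dose_grid(vals, dose$geometry, dose_kind = "EQD2", course_id = dose$course_id)
}

#' Dose scaling factor
#'
#' A static multiplier in (0, 1] modelling partial tissue recovery between
#' courses; applied to EQD2 after conversion, course-wide or restricted to a
#' structure.
#'
#' @param value multiplier in (0, 1].
#' @param scope "course" or a structure name.
#' @return object of class \code{dose_scaling_factor}.
#' @export
dose_scaling_factor <- function(value = 1, scope = "course") {
  if (!is.finite(value) || value <= 0 || value > 1)
    stop("dose scaling factor must lie in (0, 1]")
  structure(list(value = as.numeric(value), scope = as.character(scope)),
            class = "dose_scaling_factor")
}

#' Apply a dose scaling factor to an EQD2 grid or scalar
#'
#' @param eqd2 an EQD2 \code{dose_grid} or a numeric scalar/vector.
#' @param dsf a \code{dose_scaling_factor} (or a bare number in (0, 1]).
#' @param scope_mask optional \code{structure_mask}; scaling applies only
#'   inside it.
#' @return same type as \code{eqd2}.
#' @export
apply_dsf <- function(eqd2, dsf, scope_mask = NULL) {
  if (is.numeric(dsf)) dsf <- dose_scaling_factor(dsf)
  if (is.numeric(eqd2)) return(eqd2 * dsf$value)
  vals <- eqd2$values
  if (is.null(scope_mask)) {
    vals <- vals * dsf$value
  } else {
    stop_if_geometry_mismatch(scope_mask$geometry, eqd2$geometry,
                              "dose and scope mask")
    vals[scope_mask$mask] <- vals[scope_mask$mask] * dsf$value
  }
  dose_grid(vals, eqd2$geometry, dose_kind = eqd2$dose_kind,
            course_id = eqd2$course_id)
}

#' Sum EQD2 dose grids voxel-wise
#'
#' @param grids list of EQD2 \code{dose_grid}s sharing one geometry.
#' @return an EQD2 \code{dose_grid}.
#' @export
sum_eqd2 <- function(grids) {
  if (length(grids) == 0L) stop("need at least one grid to sum")
  for (g in grids) {
    if (g$dose_kind != "EQD2")
      stop("contract violation: sum_eqd2 requires EQD2 grids only")
    stop_if_geometry_mismatch(g$geometry, grids[[1]]$geometry, "summed grids")
  }
  vals <- Reduce(`+`, lapply(grids, `[[`, "values"))
  dose_grid(vals, grids[[1]]$geometry, dose_kind = "EQD2", course_id = "sum")
}

#' Point-dose feasibility: allowable new dose under a cumulative constraint
#'
#' Given a cumulative EQD2 constraint A and the prior accumulated EQD2 P at
#' the point (typically the OAR's D0.01cc), the remaining EQD2 budget is
#' B = max(A - P, 0); the physical dose deliverable in \code{n} fractions
#' that spends exactly B is obtained by inverting the LQ conversion.  This
#' is the conservative maximum-overlap point-dose method.
#'
#' @param A cumulative EQD2 constraint in Gy (>= 0).
#' @param P prior accumulated EQD2 at the point in Gy (>= 0).
#' @param scheme a \code{fractionation} for the new course.
#' @param alpha_beta OAR alpha/beta in Gy.
#' @return object of class \code{feasibility_result} with fields
#'   \code{constraint_A}, \code{prior_P}, \code{budget_B},
#'   \code{allowed_per_fraction}, \code{allowed_total}, \code{alpha_beta},
#'   \code{n_fractions}.
#' @export
point_dose_feasibility <- function(A, P, scheme, alpha_beta) {
  if (A < 0 || P < 0) stop("A and P must be >= 0")
  n <- scheme$n_fractions
  B <- max(A - P, 0)
  total <- eqd2_inverse(B, n, alpha_beta)
  structure(list(constraint_A = A, prior_P = P, budget_B = B,
                 allowed_per_fraction = total / n, allowed_total = total,
                 alpha_beta = alpha_beta, n_fractions = n),
            class = "feasibility_result")
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat(sprintf(
    "point-dose feasibility: A = %.3f, P = %.3f -> budget %.3f EQD2 Gy\n  allowed: %.4f Gy/fx x %d fx = %.4f Gy (alpha/beta %.1f)\n",
    x$constraint_A, x$prior_P, x$budget_B,
    x$allowed_per_fraction, x$n_fractions, x$allowed_total, x$alpha_beta))
  invisible(x)
}

#' Fill the calculated columns of a point-dose worksheet
#'
#' Tabular front-end to \code{\link{point_dose_feasibility}}: the user
#' supplies per-OAR rows of the cumulative constraint, prior dose, new-course
#' fraction number and alpha/beta; the calculated columns are the remaining
#' EQD2 budget and the allowed physical dose per fraction and in total.
#'
#' @param worksheet data.frame (or CSV path) with columns \code{oar},
#'   \code{A}, \code{P}, \code{n}, \code{alpha_beta}.
#' @param out_csv optional path; when given the completed worksheet is
#'   written there.
#' @return the worksheet with columns \code{B}, \code{allowed_per_fraction},
#'   \code{allowed_total} appended.
#' @export
pointdose_worksheet <- function(worksheet, out_csv = NULL) {
  if (is.character(worksheet)) worksheet <- utils::read.csv(worksheet)
  need <- c("oar", "A", "P", "n", "alpha_beta")
  if (!all(need %in% names(worksheet)))
    stop("worksheet needs columns: ", paste(need, collapse = ", "))
  res <- lapply(seq_len(nrow(worksheet)), function(i)
    point_dose_feasibility(worksheet$A[i], worksheet$P[i],
                           fractionation(worksheet$n[i]),
                           worksheet$alpha_beta[i]))
  worksheet$B <- vapply(res, `[[`, 0, "budget_B")
  worksheet$allowed_per_fraction <- vapply(res, `[[`, 0, "allowed_per_fraction")
  worksheet$allowed_total <- vapply(res, `[[`, 0, "allowed_total")
  if (!is.null(out_csv))
    utils::write.csv(worksheet, out_csv, row.names = FALSE)
  worksheet
}
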