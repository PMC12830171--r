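#' One prior treatment course
#'
#' Bundles everything needed to bring a prior course onto the current
#' planning grid: its physical dose, fractionation, the current-to-prior
#' spatial transform, and a dose scaling factor for tissue recovery.
#'
#' @param course_id label (unique within a case).
#' @param dose PHYSICAL \code{dose_grid} in the prior course's frame.
#' @param scheme \code{fractionation} of the prior course.
#' @param transform \code{spatial_transform} (current -> prior); default
#'   identity.
#' @param dsf \code{dose_scaling_factor} (default 1, i.e. no recovery).
#' @param dsf_scope_structure optional structure name limiting the DSF.
#' @param source_tps free-text provenance label.
#' @return object of class \code{course_record}.
#' @export
course_record <- function(course_id, dose, scheme,
                          transform = transform_identity(),
                          dsf = dose_scaling_factor(1),
                          dsf_scope_structure = NULL,
                          source_tps = "") {
  if (!inherits(dose, "dose_grid") || dose$dose_kind != "PHYSICAL")
    stop("course dose must be a PHYSICAL dose_grid")
  if (is.numeric(dsf)) dsf <- dose_scaling_factor(dsf)
  structure(list(course_id = as.character(course_id), dose = dose,
                 scheme = scheme, transform = transform, dsf = dsf,
                 dsf_scope_structure = dsf_scope_structure,
                 source_tps = as.character(source_tps)),
            class = "course_record")
}

#' Accumulate prior courses onto the current planning geometry
#'
#' For each course: resample its physical dose to the current grid through
#' its transform, convert to EQD2 using the CURRENT plan's structures and
#' alpha/beta map (prior contours are never used for conversion), apply the
#' course's dose scaling factor; then sum all courses voxel-wise.
#' Per-course provenance (transform kind, DSF, out-of-extent voxel count,
#' alpha/beta map version) is recorded.
#'
#' @param courses non-empty list of \code{course_record}s.
#' @param current_geometry \code{grid_geometry} of the current planning CT.
#' @param current_structures list of \code{structure_mask} on the current
#'   geometry.
#' @param ab_map \code{alpha_beta_map}.
#' @return object of class \code{accumulation_result} with
#'   \code{summed_eqd2}, \code{per_course_eqd2} and \code{provenance}.
#' @export
accumulate <- function(courses, current_geometry, current_structures, ab_map) {
  if (length(courses) == 0L) stop("need at least one course to accumulate")
  per_course <- vector("list", length(courses))
  provenance <- vector("list", length(courses))
  for (i in seq_along(courses)) {
    cr <- courses[[i]]
    res <- tryCatch({
      mapped <- resample_dose(cr$dose, cr$transform, current_geometry)
      eq <- eqd2_convert_grid(mapped, cr$scheme, ab_map, current_structures)
      scope <- NULL
      if (!is.null(cr$dsf_scope_structure)) {
        nm <- vapply(current_structures, `[[`, "", "name")
        j <- match(cr$dsf_scope_structure, nm)
        if (is.na(j)) stop("DSF scope structure '", cr$dsf_scope_structure,
                           "' not among current structures")
        scope <- current_structures[[j]]
      }
      list(eq = apply_dsf(eq, cr$dsf, scope),
           oov = attr(mapped, "out_of_extent"))
    }, error = function(e)
      stop(sprintf("course '%s': %s", cr$course_id, conditionMessage(e)),
           call. = FALSE))
    per_course[[i]] <- res$eq
    provenance[[i]] <- list(course_id = cr$course_id,
                            transform_kind = cr$transform$kind,
                            dsf = cr$dsf$value,
                            dsf_scope = cr$dsf_scope_structure %||% "course",
                            n_fractions = cr$scheme$n_fractions,
                            source_tps = cr$source_tps,
                            out_of_extent_voxels = res$oov,
                            ab_map_version = ab_map$version)
  }
  structure(list(summed_eqd2 = sum_eqd2(per_course),
                 per_course_eqd2 = per_course,
                 provenance = provenance),
            class = "accumulation_result")
}

#' @export
print.accumulation_result <- function(x, ...) {
  cat(sprintf("accumulation_result: %d course(s), summed EQD2 max %.3f Gy\n",
              length(x$per_course_eqd2), max(x$summed_eqd2$values)))
  for (p in x$provenance)
    cat(sprintf("  %s: %s transform, dsf %.2f, %d fx, %d voxels out of extent\n",
                p$course_id, tolower(p$transform_kind), p$dsf,
                p$n_fractions, p$out_of_extent_voxels))
  invisible(x)
}

#' Pre-planning feasibility screen against desired cumulative objectives
#'
#' For each constraint, evaluates the prior accumulated metric from the
#' summed EQD2 and classifies the constraint as ACHIEVABLE (prior plus the
#' full new prescription stays within the limit — no gradient needed),
#' GRADIENT_REQUIRED (prescription would overshoot but budget remains), or
#' INFEASIBLE (the prior dose alone already reaches the limit).  Equality
#' with the limit counts as the safer category (INFEASIBLE).
#'
#' @param result an \code{accumulation_result}.
#' @param constraints list of \code{constraint} objects (EQD2 limits).
#' @param new_prescription new-plan prescription in EQD2 Gy.
#' @param structures list of \code{structure_mask} on the current geometry.
#' @return data.frame with one row per constraint: structure, metric, prior
#'   value, limit, remaining budget, flag.
#' @export
feasibility_screen <- function(result, constraints, new_prescription,
                               structures) {
  nm <- vapply(structures, `[[`, "", "name")
  rows <- lapply(constraints, function(cn) {
    j <- match(cn$structure, nm)
    if (is.na(j))
      stop("unknown structure '", cn$structure, "'; available: ",
           paste(nm, collapse = ", "))
    prior <- evaluate_metric(result$summed_eqd2, structures[[j]], cn$metric)
    budget <- max(cn$limit - prior, 0)
    flag <- if (prior >= cn$limit) "INFEASIBLE"
            else if (prior + new_prescription <= cn$limit) "ACHIEVABLE"
            else "GRADIENT_REQUIRED"
    data.frame(structure = cn$structure, metric = format_metric(cn$metric),
               prior_eqd2 = prior, limit_eqd2 = cn$limit,
               remaining_budget_eqd2 = budget, flag = flag)
  })
  do.call(rbind, rows)
}
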