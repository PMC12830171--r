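#' Maximum prior EQD2 to an OAR within the region near the target
#'
#' P is the Dmax of the summed prior EQD2 (dose scaling already applied)
#' over the intersection of the OAR with the target expanded by a Euclidean
#' margin.  If that intersection is empty the maximum over the whole OAR is
#' returned with a warning.
#'
#' @param summed_eqd2 EQD2 \code{dose_grid} of the accumulated prior dose.
#' @param oar \code{structure_mask} of the organ at risk (non-empty).
#' @param target \code{structure_mask} of the new-plan target.
#' @param near_margin_mm target expansion in mm defining "near" (default 20).
#' @return P in EQD2 Gy.
#' @export
compute_near_target_dmax <- function(summed_eqd2, oar, target,
                                     near_margin_mm = 20) {
  stop_if_geometry_mismatch(summed_eqd2$geometry, oar$geometry, "dose and OAR")
  stop_if_geometry_mismatch(summed_eqd2$geometry, target$geometry,
                            "dose and target")
  if (!any(oar$mask)) stop("OAR mask is empty")
  near <- mask_dilate(target, near_margin_mm)
  region <- oar$mask & near$mask
  if (!any(region)) {
    warning("OAR does not intersect the near-target region; ",
            "using Dmax over the whole OAR")
    region <- oar$mask
  }
  max(summed_eqd2$values[region])
}

#' Generate nested isodose optimization structures for a reirradiation plan
#'
#' Implements the stepped-gradient construction: when the near-target prior
#' maximum P plus the new prescription R exceeds the cumulative constraint A,
#' the OAR is partitioned into N nested shells by prior-EQD2 isodose levels
#' \eqn{D_i = P - i d} with step \eqn{d = ((P + R) - A)/N}.  Every voxel of
#' shell \eqn{S_i} is conservatively assumed to have received \eqn{D_{i-1}}
#' (with \eqn{D_0 = P}), so its new-plan EQD2 limit is \eqn{A - D_{i-1}},
#' also expressed as a physical dose limit for the prescribed fractionation.
#' When \eqn{P + R \le A} no structures are needed: the full prescription
#' can be delivered to the OAR without exceeding the constraint.
#'
#' @param P near-target prior Dmax in EQD2 Gy (see
#'   \code{\link{compute_near_target_dmax}}).
#' @param R new-plan prescription in EQD2 Gy.
#' @param A cumulative OAR constraint in EQD2 Gy (> 0).
#' @param N number of structures (>= 1; default 3 — more structures give a
#'   smoother gradient).
#' @param summed_eqd2 EQD2 \code{dose_grid} of the accumulated prior dose.
#' @param oar \code{structure_mask} of the OAR.
#' @param scheme \code{fractionation} of the new plan (for physical limits).
#' @param alpha_beta the OAR's alpha/beta in Gy (the limit protects the OAR).
#' @param restrict_to_oar build shells inside the OAR (default TRUE); FALSE
#'   gives whole-grid isodose shells for visual review.
#' @return object of class \code{opt_structure_set}: fields \code{P},
#'   \code{R}, \code{A}, \code{N}, \code{d}, \code{structures} (each with
#'   \code{index}, \code{mask}, \code{threshold}, \code{assumed_prior},
#'   \code{eqd2_limit}, \code{physical_limit}) and \code{rest_mask} (OAR
#'   voxels below all thresholds, plannable without regard to prior dose).
#'   Empty (zero structures) iff \eqn{P + R \le A}.
#' @export
generate_opt_structures <- function(P, R, A, N = 3, summed_eqd2, oar, scheme,
                                    alpha_beta = 3, restrict_to_oar = TRUE) {
  if (N < 1) stop("N must be >= 1")
  if (A <= 0) stop("A must be > 0")
  if (R < 0 || P < 0) stop("P and R must be >= 0")
  stop_if_geometry_mismatch(summed_eqd2$geometry, oar$geometry, "dose and OAR")
  geom <- oar$geometry
  domain <- if (restrict_to_oar) oar$mask else array(TRUE, dim = geom$shape)
  empty <- structure(list(P = P, R = R, A = A, N = as.integer(N), d = 0,
                          structures = list(),
                          rest_mask = structure_mask("rest", domain, geom),
                          scheme = scheme, alpha_beta = alpha_beta),
                     class = "opt_structure_set")
  if (P + R <= A) return(empty)
  d <- ((P + R) - A) / N
  thresholds <- pmax(P - seq_len(N) * d, 0)
  assumed <- c(P, thresholds[-N])          # D_0 = P, then D_1 .. D_{N-1}
  taken <- array(FALSE, dim = geom$shape)
  structures <- vector("list", N)
  for (i in seq_len(N)) {
    raw <- domain & (summed_eqd2$values >= thresholds[i])
    m <- raw & !taken
    taken <- taken | m
    eqd2_limit <- A - assumed[i]
    structures[[i]] <- list(
      index = i,
      mask = structure_mask(sprintf("S%d", i), m, geom),
      threshold = thresholds[i],
      assumed_prior = assumed[i],
      eqd2_limit = eqd2_limit,
      # a deficit (P > A) leaves no physical allowance at all
      physical_limit = eqd2_inverse(max(eqd2_limit, 0), scheme$n_fractions,
                                    alpha_beta))
  }
  structure(list(P = P, R = R, A = A, N = as.integer(N), d = d,
                 structures = structures,
                 rest_mask = structure_mask("rest", domain & !taken, geom),
                 scheme = scheme, alpha_beta = alpha_beta),
            class = "opt_structure_set")
}

#' @export
print.opt_structure_set <- function(x, ...) {
  if (length(x$structures) == 0L) {
    cat(sprintf("opt_structure_set: empty (P + R = %.2f <= A = %.2f; full prescription deliverable)\n",
                x$P + x$R, x$A))
    return(invisible(x))
  }
  cat(sprintf("opt_structure_set: P = %.2f, R = %.2f, A = %.2f EQD2 Gy, N = %d, step d = %.3f\n",
              x$P, x$R, x$A, x$N, x$d))
  print(opt_structure_table(x), row.names = FALSE, digits = 6)
  invisible(x)
}

#' Tabulate an optimization structure set
#' @param set an \code{opt_structure_set}.
#' @return data.frame: structure, threshold_eqd2, assumed_prior_eqd2,
#'   limit_eqd2, limit_physical, voxels.
#' @export
opt_structure_table <- function(set) {
  if (length(set$structures) == 0L)
    return(data.frame(structure = character(), threshold_eqd2 = numeric(),
                      assumed_prior_eqd2 = numeric(), limit_eqd2 = numeric(),
                      limit_physical = numeric(), voxels = integer()))
  do.call(rbind, lapply(set$structures, function(s)
    data.frame(structure = s$mask$name, threshold_eqd2 = s$threshold,
               assumed_prior_eqd2 = s$assumed_prior,
               limit_eqd2 = s$eqd2_limit, limit_physical = s$physical_limit,
               voxels = sum(s$mask$mask))))
}

#' Export an optimization structure set as named, annotated masks
#'
#' @param set a non-empty \code{opt_structure_set}.
#' @param name_prefix prefix for exported names
#'   (\code{"<prefix>_S1" .. "<prefix>_SN"} and \code{"<prefix>_rest"}).
#' @return list of \code{structure_mask}, each carrying \code{eqd2_limit}
#'   and \code{physical_limit} attributes (the rest mask carries none); an
#'   empty set returns an empty list with a message.
#' @export
export_opt_structures <- function(set, name_prefix = "opt") {
  if (length(set$structures) == 0L) {
    message("optimization structure set is empty; nothing to export")
    return(list())
  }
  out <- lapply(set$structures, function(s) {
    m <- structure_mask(sprintf("%s_S%d", name_prefix, s$index),
                        s$mask$mask, s$mask$geometry)
    attr(m, "eqd2_limit") <- s$eqd2_limit
    attr(m, "physical_limit") <- s$physical_limit
    m
  })
  c(out, list(structure_mask(paste0(name_prefix, "_rest"),
                             set$rest_mask$mask, set$rest_mask$geometry)))
}
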