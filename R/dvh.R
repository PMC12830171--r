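#' Cumulative dose-volume histogram of a structure
#'
#' Volume-weighted cumulative DVH on uniform dose bins: the curve gives the
#' percentage of the structure's volume receiving at least each bin-edge
#' dose.  It starts at 100\% at 0 Gy and reaches 0\% above the maximum dose.
#'
#' @param dose a \code{dose_grid}.
#' @param mask a non-empty \code{structure_mask} on the same geometry.
#' @param bin_width bin width in Gy (default 0.1).
#' @return object of class \code{dvh_curve}: \code{structure},
#'   \code{dose_bins} (edges, Gy), \code{cumulative_volume_pct},
#'   \code{dose_kind}, and summary fields \code{dmax}, \code{dmean},
#'   \code{volume_cc}.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1) {
  stop_if_geometry_mismatch(dose$geometry, mask$geometry, "dose and mask")
  if (!any(mask$mask))
    stop("cannot compute DVH: structure '", mask$name, "' is empty")
  d <- dose$values[mask$mask]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  pct <- vapply(edges, function(e) 100 * mean(d >= e), 0)
  structure(list(structure = mask$name, dose_bins = edges,
                 cumulative_volume_pct = pct, dose_kind = dose$dose_kind,
                 bin_width = bin_width,
                 dmax = max(d), dmean = mean(d),
                 volume_cc = mask_volume_cc(mask)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve '%s' [%s]: %.3f cc, Dmax %.3f Gy, Dmean %.3f Gy, %d bins of %.3g Gy\n",
              x$structure, x$dose_kind, x$volume_cc, x$dmax, x$dmean,
              length(x$dose_bins), x$bin_width))
  invisible(x)
}

#' Near-maximum dose metric DxCC
#'
#' Minimum dose within the hottest \code{x_cc} of the structure: masked
#' voxel doses are sorted descending and voxel volumes accumulated; the dose
#' at which the running volume first reaches \code{x_cc} is returned.  No
#' sub-voxel interpolation is applied (conservative and reproducible).  If
#' the structure is smaller than \code{x_cc} the minimum masked dose is
#' returned with a warning.
#'
#' @param dose a \code{dose_grid}.
#' @param mask a non-empty \code{structure_mask}.
#' @param x_cc volume in cc (> 0); 0.01 cc is the conventional near-max
#'   point dose.
#' @return dose in Gy.
#' @export
metric_d_cc <- function(dose, mask, x_cc = 0.01) {
  stop_if_geometry_mismatch(dose$geometry, mask$geometry, "dose and mask")
  if (x_cc <= 0) stop("x_cc must be > 0")
  if (!any(mask$mask)) stop("empty structure '", mask$name, "'")
  d <- sort(dose$values[mask$mask], decreasing = TRUE)
  vv <- voxel_volume_cc(dose$geometry)
  cum <- seq_along(d) * vv
  k <- which(cum >= x_cc)
  if (length(k) == 0L) {
    warning(sprintf("structure '%s' volume %.4f cc < %.4f cc; returning its minimum dose",
                    mask$name, cum[length(cum)], x_cc))
    return(d[length(d)])
  }
  d[k[1]]
}

#' Dose-volume metrics on a masked dose grid
#'
#' @param dose a \code{dose_grid}.
#' @param mask a non-empty \code{structure_mask}.
#' @param x metric parameter: cc for \code{metric_d_cc}, percent volume for
#'   \code{metric_d_pct}, Gy for \code{metric_v_gy}.
#' @return \code{metric_dmax}/\code{metric_dmean}: Gy. \code{metric_d_pct}:
#'   minimum dose (Gy) of the hottest x\% of the volume.  \code{metric_v_gy}:
#'   percent of the structure volume receiving >= x Gy.
#' @export
metric_dmax <- function(dose, mask) {
  stop_if_geometry_mismatch(dose$geometry, mask$geometry, "dose and mask")
  if (!any(mask$mask)) stop("empty structure '", mask$name, "'")
  max(dose$values[mask$mask])
}

#' @rdname metric_dmax
#' @export
metric_dmean <- function(dose, mask) {
  stop_if_geometry_mismatch(dose$geometry, mask$geometry, "dose and mask")
  if (!any(mask$mask)) stop("empty structure '", mask$name, "'")
  mean(dose$values[mask$mask])
}

#' @rdname metric_dmax
#' @export
metric_d_pct <- function(dose, mask, x) {
  if (x <= 0 || x > 100) stop("percent volume must be in (0, 100]")
  vol <- mask_volume_cc(mask)
  metric_d_cc(dose, mask, x / 100 * vol)
}

#' @rdname metric_dmax
#' @export
metric_v_gy <- function(dose, mask, x) {
  stop_if_geometry_mismatch(dose$geometry, mask$geometry, "dose and mask")
  if (!any(mask$mask)) stop("empty structure '", mask$name, "'")
  100 * mean(dose$values[mask$mask] >= x)
}

#' Dose constraint on a structure
#'
#' @param structure structure name.
#' @param metric metric spec: "DMAX", "DMEAN", "D0.01CC" (any volume),
#'   "D2%" (any percent), or "V20GY" (any dose).  Case-insensitive.
#' @param limit limit in EQD2 Gy (percent volume for VxGy constraints);
#'   >= 0.
#' @param alpha_beta the structure's alpha/beta in Gy (carried for
#'   provenance; conversion happens upstream).
#' @return object of class \code{constraint}.
#' @export
constraint <- function(structure, metric, limit, alpha_beta = 3) {
  if (limit < 0) stop("constraint limit must be >= 0")
  structure(list(structure = as.character(structure),
                 metric = parse_metric(metric), limit = as.numeric(limit),
                 alpha_beta = alpha_beta),
            class = "constraint")
}

# "DMAX" | "DMEAN" | "D<x>CC" | "D<x>%" | "V<x>GY" -> list(type, param)
parse_metric <- function(metric) {
  if (is.list(metric)) return(metric)
  m <- toupper(gsub(" ", "", metric))
  if (m == "DMAX") return(list(type = "DMAX", param = NA_real_))
  if (m == "DMEAN") return(list(type = "DMEAN", param = NA_real_))
  if (grepl("^D[0-9.]+CC$", m))
    return(list(type = "D_CC", param = as.numeric(sub("^D([0-9.]+)CC$", "\\1", m))))
  if (grepl("^D[0-9.]+%$", m))
    return(list(type = "D_PCT", param = as.numeric(sub("^D([0-9.]+)%$", "\\1", m))))
  if (grepl("^V[0-9.]+GY$", m))
    return(list(type = "V_GY", param = as.numeric(sub("^V([0-9.]+)GY$", "\\1", m))))
  stop("unrecognized metric spec: '", metric, "'")
}

format_metric <- function(metric) {
  switch(metric$type,
    DMAX = "Dmax", DMEAN = "Dmean",
    D_CC = sprintf("D%gcc", metric$param),
    D_PCT = sprintf("D%g%%", metric$param),
    V_GY = sprintf("V%gGy", metric$param))
}

evaluate_metric <- function(dose, mask, metric) {
  metric <- parse_metric(metric)
  switch(metric$type,
    DMAX = metric_dmax(dose, mask),
    DMEAN = metric_dmean(dose, mask),
    D_CC = metric_d_cc(dose, mask, metric$param),
    D_PCT = metric_d_pct(dose, mask, metric$param),
    V_GY = metric_v_gy(dose, mask, metric$param))
}

#' Evaluate a constraint scorecard on a summed EQD2 grid
#'
#' Each constraint's achieved value is computed with its metric on the
#' summed dose; PASS iff achieved <= limit (exact comparison, so equality
#' passes), margin = limit - achieved.
#'
#' @param summed an EQD2 \code{dose_grid}.
#' @param masks list of \code{structure_mask}.
#' @param constraints list of \code{constraint}.
#' @return data.frame of class \code{scorecard}: structure, metric,
#'   achieved, limit, margin, status.
#' @export
evaluate_scorecard <- function(summed, masks, constraints) {
  nm <- vapply(masks, `[[`, "", "name")
  if (length(constraints) == 0L) {
    out <- data.frame(structure = character(), metric = character(),
                      achieved = numeric(), limit = numeric(),
                      margin = numeric(), status = character())
    class(out) <- c("scorecard", class(out))
    return(out)
  }
  rows <- lapply(constraints, function(cn) {
    j <- match(cn$structure, nm)
    if (is.na(j))
      stop("unknown structure '", cn$structure, "'; available: ",
           paste(nm, collapse = ", "))
    achieved <- evaluate_metric(summed, masks[[j]], cn$metric)
    data.frame(structure = cn$structure, metric = format_metric(cn$metric),
               achieved = achieved, limit = cn$limit,
               margin = cn$limit - achieved,
               status = if (achieved <= cn$limit) "PASS" else "FAIL")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scorecard", class(out))
  out
}
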