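#' Render the cumulative dose-sum report
#'
#' Writes the machine-readable report (report.json, versioned schema), a
#' human-readable markdown summary (report.md), the DVH table (dvh.csv) and
#' a cumulative DVH plot (dvh.png).  Content is deterministic given the
#' inputs; the generation timestamp is isolated in one JSON field.
#'
#' @param accum an \code{accumulation_result}.
#' @param scorecard a \code{scorecard} data.frame, or NULL when no
#'   constraints were configured (the report then carries an explicit
#'   notice).
#' @param dvhs list of \code{dvh_curve}.
#' @param case_log optional named list of administrative/technical case
#'   information to embed.
#' @param dir output directory (created if needed).
#' @param plot draw dvh.png (default TRUE; skipped with a warning if no
#'   graphics device is available).
#' @return invisible list of written paths.
#' @export
render_report <- function(accum, scorecard, dvhs, case_log = NULL,
                          dir = ".", plot = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(json = file.path(dir, "report.json"),
                md = file.path(dir, "report.md"),
                dvh_csv = file.path(dir, "dvh.csv"),
                dvh_png = file.path(dir, "dvh.png"))
  no_constraints <- is.null(scorecard) || nrow(scorecard) == 0L
  dvh_summary <- lapply(dvhs, function(d)
    list(structure = d$structure, dose_kind = d$dose_kind,
         volume_cc = d$volume_cc, dmax = d$dmax, dmean = d$dmean))
  report <- list(
    schema_version = "1.0",
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    case = case_log,
    provenance = accum$provenance,
    summed_dose_kind = accum$summed_eqd2$dose_kind,
    summed_dmax = max(accum$summed_eqd2$values),
    scorecard = if (no_constraints) list() else scorecard,
    notice = if (no_constraints) "no constraints evaluated" else NULL,
    dvh = dvh_summary)
  jsonlite::write_json(report, paths$json, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  # DVH long table
  dvh_tab <- do.call(rbind, lapply(dvhs, function(d)
    data.frame(structure = d$structure, dose_gy = d$dose_bins,
               volume_pct = d$cumulative_volume_pct)))
  if (is.null(dvh_tab))
    dvh_tab <- data.frame(structure = character(), dose_gy = numeric(),
                          volume_pct = numeric())
  utils::write.csv(dvh_tab, paths$dvh_csv, row.names = FALSE)
  # markdown summary
  md <- c("# Cumulative dose accumulation report", "",
          sprintf("Summed dose kind: %s; global Dmax %.3f Gy",
                  accum$summed_eqd2$dose_kind, max(accum$summed_eqd2$values)),
          "", "## Courses", "")
  for (p in accum$provenance)
    md <- c(md, sprintf(
      "- %s: %s transform, DSF %.2f, %d fractions, %d voxels out of extent (%s)",
      p$course_id, tolower(p$transform_kind), p$dsf, p$n_fractions,
      p$out_of_extent_voxels, p$source_tps))
  md <- c(md, "", "## Scorecard", "")
  if (no_constraints) {
    md <- c(md, "_No constraints evaluated._")
  } else {
    md <- c(md, "| structure | metric | achieved | limit | margin | status |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %s | %.3f | %.3f | %.3f | %s |",
                    scorecard$structure, scorecard$metric, scorecard$achieved,
                    scorecard$limit, scorecard$margin, scorecard$status))
  }
  md <- c(md, "", "## Structures", "",
          sprintf("- %s: %.3f cc, Dmax %.3f Gy, Dmean %.3f Gy",
                  vapply(dvhs, `[[`, "", "structure"),
                  vapply(dvhs, `[[`, 0, "volume_cc"),
                  vapply(dvhs, `[[`, 0, "dmax"),
                  vapply(dvhs, `[[`, 0, "dmean")))
  writeLines(md, paths$md)
  if (plot && length(dvhs)) {
    ok <- tryCatch({
      grDevices::png(paths$dvh_png, width = 800, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      xmax <- max(vapply(dvhs, function(d) max(d$dose_bins), 0))
      graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 100),
                     xlab = sprintf("Dose (%s Gy)", dvhs[[1]]$dose_kind),
                     ylab = "Volume (%)", main = "Cumulative DVH")
      for (i in seq_along(dvhs))
        graphics::lines(dvhs[[i]]$dose_bins, dvhs[[i]]$cumulative_volume_pct,
                        col = i, lwd = 2)
      graphics::legend("topright",
                       legend = vapply(dvhs, `[[`, "", "structure"),
                       col = seq_along(dvhs), lwd = 2)
      TRUE
    }, error = function(e) {
      warning("DVH plot skipped: ", conditionMessage(e))
      FALSE
    })
    if (!ok) paths$dvh_png <- NULL
  }
  invisible(paths)
}
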