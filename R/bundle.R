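# Case bundle: a directory holding case.json plus one dose volume per prior
# course, the current structures, and per-course transforms.  Dose and mask
# volumes are NIfTI (TPS-neutral) or DICOM RT objects; paths in case.json
# are relative to the bundle root.

CASE_SCHEMA_VERSION <- "1.0"

#' Write an in-memory case to a bundle directory
#'
#' @param case list with \code{geometry} (current \code{grid_geometry}),
#'   \code{courses} (list of \code{course_record}), \code{structures} (list
#'   of \code{structure_mask} on the current geometry), and optional
#'   \code{case_id}.
#' @param dir bundle directory (created if needed).
#' @param format "nifti" (default) or "dicom" for the dose volumes;
#'   structures are always written both as NIfTI label volumes and, for
#'   "dicom", an RT Structure Set.
#' @return \code{dir}, invisibly.
#' @export
write_case_bundle <- function(case, dir, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- case$geometry
  courses_meta <- lapply(case$courses, function(cr) {
    ext <- if (format == "dicom") ".dcm" else ".nii.gz"
    dose_file <- paste0("dose_", cr$course_id, ext)
    if (format == "dicom") write_rtdose(cr$dose, file.path(dir, dose_file))
    else write_dose_nifti(cr$dose, file.path(dir, dose_file))
    tf_file <- paste0("transform_", cr$course_id, ".json")
    write_transform_json(cr$transform, file.path(dir, tf_file))
    list(course_id = cr$course_id, dose_file = dose_file,
         dose_geometry = geom_meta(cr$dose$geometry),
         n_fractions = cr$scheme$n_fractions,
         prescription_total = cr$scheme$prescription_total,
         transform_file = tf_file, dsf = cr$dsf$value,
         dsf_scope_structure = cr$dsf_scope_structure,
         source_tps = cr$source_tps)
  })
  struct_meta <- lapply(case$structures, function(sm) {
    f <- paste0("struct_", gsub("[^A-Za-z0-9_]", "_", sm$name), ".nii.gz")
    write_mask_nifti(sm, file.path(dir, f))
    list(name = sm$name, file = f)
  })
  if (format == "dicom" && length(case$structures))
    write_rtstruct(case$structures, file.path(dir, "structures.dcm"))
  meta <- list(schema_version = CASE_SCHEMA_VERSION,
               case_id = case$case_id %||% "case",
               format = format,
               geometry = geom_meta(g),
               courses = courses_meta,
               structures = struct_meta)
  jsonlite::write_json(meta, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

geom_meta <- function(g)
  list(origin = g$origin, spacing = g$spacing, shape = g$shape,
       orientation = as.numeric(g$orientation), frame_id = g$frame_id)

geom_from_meta <- function(m)
  grid_geometry(origin = unlist(m$origin), spacing = unlist(m$spacing),
                shape = unlist(m$shape),
                orientation = matrix(unlist(m$orientation), 3, 3),
                frame_id = m$frame_id)

#' Read a case bundle directory back into memory
#' @param dir bundle directory containing \code{case.json}.
#' @return a case list as accepted by \code{\link{write_case_bundle}}.
#' @export
read_case_bundle <- function(dir) {
  cj <- file.path(dir, "case.json")
  if (!file.exists(cj)) stop("no case.json in bundle directory: ", dir)
  meta <- jsonlite::fromJSON(cj, simplifyVector = FALSE)
  g <- geom_from_meta(meta$geometry)
  courses <- lapply(meta$courses, function(cm) {
    f <- file.path(dir, cm$dose_file)
    dose <- if (grepl("\\.dcm$", f)) read_rtdose(f)
            else read_dose_nifti(f, dose_kind = "PHYSICAL",
                                 course_id = cm$course_id,
                                 frame_id = cm$dose_geometry$frame_id)
    dose$course_id <- cm$course_id
    tf <- if (!is.null(cm$transform_file))
      read_transform_json(file.path(dir, cm$transform_file))
    else transform_identity()
    course_record(cm$course_id, dose,
                  fractionation(cm$n_fractions, cm$prescription_total),
                  transform = tf,
                  dsf = dose_scaling_factor(cm$dsf %||% 1),
                  dsf_scope_structure = cm$dsf_scope_structure,
                  source_tps = cm$source_tps %||% "")
  })
  structures <- lapply(meta$structures, function(sm)
    read_mask_nifti(file.path(dir, sm$file), name = sm$name,
                    frame_id = meta$geometry$frame_id))
  list(case_id = meta$case_id, geometry = g, courses = courses,
       structures = structures)
}

#' Append an entry to the append-only case log
#'
#' The case log is the machine-readable technical record of a dose
#' accumulation: which plans were included, registration type per course,
#' dose scaling factors, alpha/beta map version, organs of concern, and
#' free-text decisions.  Entries are timestamped JSON lines; the file is
#' never rewritten.
#'
#' @param entry named list; must include \code{case_id}.
#' @param path log file (default "caselog.jsonl").
#' @return the entry as written (with timestamp), invisibly.
#' @export
append_case_log <- function(entry, path = "caselog.jsonl") {
  if (is.null(entry$case_id)) stop("case log entry needs a case_id")
  entry$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(entry)
}

#' Read all case log entries
#' @param path log file.
#' @return list of entries in append order.
#' @export
read_case_log <- function(path = "caselog.jsonl") {
  if (!file.exists(path)) return(list())
  lapply(readLines(path), jsonlite::fromJSON, simplifyVector = FALSE)
}
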