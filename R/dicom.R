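# Minimal DICOM Part 10 codec, Explicit VR Little Endian only, covering the
# axis-aligned RT Dose / RT Structure Set / RT Plan dialect this toolkit
# exchanges.  Oblique orientations, non-uniform slice offsets and other
# transfer syntaxes are rejected explicitly rather than mis-read.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# ---- encoding -------------------------------------------------------------

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536; hi <- x %/% 65536
  c(raw_u16(ifelse(lo > 32767, lo - 65536, lo)),
    raw_u16(ifelse(hi > 32767, hi - 65536, hi)))
}

enc_element <- function(group, elem, vr, data) {
  n <- length(data)
  if (n %% 2L == 1L) stop("internal: odd element length")
  head <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) c(head, raw(2), raw_u32(n), data)
  else c(head, raw_u16(n), data)
}

pad_str <- function(s, pad = " ") {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, charToRaw(pad))
  r
}

enc_str <- function(group, elem, vr, s, pad = " ")
  enc_element(group, elem, vr, pad_str(paste(s, collapse = "\\"), pad))
enc_ui <- function(group, elem, s) {
  r <- charToRaw(paste(s, collapse = "\\"))
  if (length(r) %% 2L == 1L) r <- c(r, as.raw(0))
  enc_element(group, elem, "UI", r)
}
enc_us <- function(group, elem, x)
  enc_element(group, elem, "US", raw_u16(x))
enc_ul <- function(group, elem, x)
  enc_element(group, elem, "UL", raw_u32(x))

# DS values limited to 16 bytes each
fmt_ds <- function(x) {
  s <- vapply(x, function(v) formatC(v, format = "g", digits = 10), "")
  long <- nchar(s) > 16
  if (any(long))
    s[long] <- vapply(x[long], function(v) formatC(v, format = "g", digits = 6), "")
  s
}
enc_ds <- function(group, elem, x) enc_str(group, elem, "DS", fmt_ds(x))
enc_is <- function(group, elem, x)
  enc_str(group, elem, "IS", sprintf("%d", as.integer(x)))

# sequence with undefined lengths; items = list of raw vectors (encoded datasets)
enc_sq <- function(group, elem, items) {
  body <- do.call(c, c(lapply(items, function(it)
    c(raw_u16(0xFFFE), raw_u16(0xE000), raw_u32(4294967295),
      it,
      raw_u16(0xFFFE), raw_u16(0xE00D), raw_u32(0))), list(raw(0))))
  c(raw_u16(group), raw_u16(elem), charToRaw("SQ"), raw(2),
    raw_u32(4294967295), body,
    raw_u16(0xFFFE), raw_u16(0xE0DD), raw_u32(0))
}

uid_from_label <- function(label) {
  if (grepl("^[0-9.]+$", label) && nchar(label) <= 64) return(label)
  digits <- paste(utf8ToInt(label), collapse = "")
  substr(paste0("2.25.", digits), 1, 64)
}

write_dicom_file <- function(path, sop_class_uid, sop_instance_uid, dataset) {
  meta <- c(enc_ui(0x0002, 0x0002, sop_class_uid),
            enc_ui(0x0002, 0x0003, sop_instance_uid),
            enc_ui(0x0002, 0x0010, UID_EXPLICIT_LE))
  meta <- c(enc_ul(0x0002, 0x0000, length(meta)), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(dataset, con)
  invisible(path)
}

# ---- decoding -------------------------------------------------------------

rd_u16 <- function(raw, pos)
  readBin(raw[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
          endian = "little")
rd_u32 <- function(raw, pos) {
  lo <- rd_u16(raw, pos); hi <- rd_u16(raw, pos + 2)
  lo + 65536 * hi
}

tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

# Parse an explicit-VR-LE dataset in raw[pos..end]; returns list(elements, pos).
# Repeated tags (sequence-free datasets only) keep the first occurrence.
parse_dataset <- function(raw, pos, end) {
  elements <- list()
  while (pos + 7 <= end + 1 && pos < end) {
    group <- rd_u16(raw, pos); elem <- rd_u16(raw, pos + 2)
    if (group == 0xFFFE) {                       # item delimiter territory
      if (elem == 0xE00D || elem == 0xE0DD) {    # caller handles; stop here
        break
      }
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- rd_u32(raw, pos + 8)
      data_pos <- pos + 12
    } else {
      len <- rd_u16(raw, pos + 6)
      data_pos <- pos + 8
    }
    key <- tag_key(group, elem)
    if (vr == "SQ" || (vr == "UN" && len == 4294967295)) {
      res <- parse_sequence(raw, data_pos, len, end)
      elements[[key]] <- list(vr = "SQ", items = res$items)
      pos <- res$pos
    } else {
      if (len == 4294967295) stop("undefined length on non-sequence element")
      value <- if (len > 0) raw[data_pos:(data_pos + len - 1)] else raw(0)
      elements[[key]] <- list(vr = vr, value = value)
      pos <- data_pos + len
    }
  }
  list(elements = elements, pos = pos)
}

parse_sequence <- function(raw, pos, len, end) {
  items <- list()
  seq_end <- if (len == 4294967295) end else pos + len
  while (pos < seq_end) {
    group <- rd_u16(raw, pos); elem <- rd_u16(raw, pos + 2)
    ilen <- rd_u32(raw, pos + 4)
    pos <- pos + 8
    if (group == 0xFFFE && elem == 0xE0DD) break          # sequence delimiter
    if (!(group == 0xFFFE && elem == 0xE000))
      stop("malformed sequence: expected item tag")
    item_end <- if (ilen == 4294967295) seq_end else pos + ilen
    res <- parse_dataset(raw, pos, item_end)
    items[[length(items) + 1L]] <- res$elements
    pos <- res$pos
    if (ilen == 4294967295) {                              # item delimiter
      group <- rd_u16(raw, pos); elem <- rd_u16(raw, pos + 2)
      if (!(group == 0xFFFE && elem == 0xE00D))
        stop("malformed sequence: expected item delimitation")
      pos <- pos + 8
    }
  }
  list(items = items, pos = pos)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path)
  pos <- 133
  # file meta group is always explicit little endian
  meta <- parse_meta_group(raw, pos)
  ts <- el_str(meta$elements[["0002,0010"]])
  if (!identical(ts, UID_EXPLICIT_LE))
    stop("unsupported transfer syntax '", ts,
         "'; only Explicit VR Little Endian is supported")
  parse_dataset(raw, meta$pos, length(raw))$elements
}

parse_meta_group <- function(raw, pos) {
  elements <- list()
  repeat {
    if (pos + 7 > length(raw)) break
    group <- rd_u16(raw, pos)
    if (group != 0x0002) break
    elem <- rd_u16(raw, pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) { len <- rd_u32(raw, pos + 8); dp <- pos + 12 }
    else { len <- rd_u16(raw, pos + 6); dp <- pos + 8 }
    elements[[tag_key(group, elem)]] <- list(vr = vr,
      value = if (len > 0) raw[dp:(dp + len - 1)] else raw(0))
    pos <- dp + len
  }
  list(elements = elements, pos = pos)
}

el_str <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el$value[el$value != as.raw(0)])
  sub("[ ]+$", "", s)
}
el_strs <- function(el) if (is.null(el)) NULL else strsplit(el_str(el), "\\\\")[[1]]
el_nums <- function(el) if (is.null(el)) NULL else as.numeric(el_strs(el))
el_u16v <- function(el)
  readBin(el$value, "integer", n = length(el$value) / 2, size = 2,
          signed = FALSE, endian = "little")

require_el <- function(elements, key, what) {
  el <- elements[[key]]
  if (is.null(el))
    stop(sprintf("format error: missing %s (tag %s)", what, key))
  el
}

# ---- RT Dose --------------------------------------------------------------

#' Write a dose grid as a DICOM RT Dose object
#'
#' Dose is stored as 32-bit unsigned integers with
#' \code{DoseGridScaling = max(dose)/(2^32 - 1)}; the quantization error is
#' at most half of one scaled step.  EQD2 grids are written with
#' \code{DoseType EFFECTIVE} and a \code{SeriesDescription} of "EQD2" so the
#' dose kind survives a round trip; physical grids use \code{PHYSICAL}.
#'
#' @param grid a \code{dose_grid} on an axis-aligned geometry.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_rtdose <- function(grid, path) {
  g <- grid$geometry
  if (max(abs(g$orientation - diag(3))) > 1e-6)
    stop("only axis-aligned geometries are written; resample first")
  maxd <- max(grid$values)
  # scaling rounded up within its 16-byte DS representation so the stored
  # decimal string is exactly the factor used for quantization
  scaling_str <- if (maxd > 0)
    formatC(maxd / (2^32 - 1) * (1 + 1e-6), format = "e", digits = 7)
  else "1.0"
  scaling <- as.numeric(scaling_str)
  ints <- round(grid$values / scaling)       # doubles holding 0..2^32-1
  lo <- ints %% 65536; hi <- ints %/% 65536
  inter <- numeric(2 * length(ints))
  inter[seq(1, length(inter), 2)] <- lo
  inter[seq(2, length(inter), 2)] <- hi
  pix <- writeBin(as.integer(ifelse(inter > 32767, inter - 65536, inter)),
                  raw(), size = 2, endian = "little")
  sop_uid <- uid_from_label(paste0("rtdose.", g$frame_id, ".", g$shape[1]))
  ds <- c(
    enc_ui(0x0008, 0x0016, UID_RTDOSE),
    enc_ui(0x0008, 0x0018, sop_uid),
    enc_str(0x0008, 0x0060, "CS", "RTDOSE"),
    enc_str(0x0008, 0x103E, "LO",
            if (grid$dose_kind == "EQD2") "EQD2" else "PHYSICAL DOSE"),
    enc_str(0x0020, 0x000D, "UI", uid_from_label("study")),
    enc_ui(0x0020, 0x0052, uid_from_label(g$frame_id)),
    enc_ds(0x0020, 0x0032, g$origin),
    enc_ds(0x0020, 0x0037, c(g$orientation[, 1], g$orientation[, 2])),
    enc_us(0x0028, 0x0002, 1),
    enc_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    enc_is(0x0028, 0x0008, g$shape[3]),
    enc_us(0x0028, 0x0010, g$shape[2]),     # Rows = y
    enc_us(0x0028, 0x0011, g$shape[1]),     # Columns = x
    enc_ds(0x0028, 0x0030, c(g$spacing[2], g$spacing[1])),
    enc_us(0x0028, 0x0100, 32),
    enc_us(0x0028, 0x0101, 32),
    enc_us(0x0028, 0x0102, 31),
    enc_us(0x0028, 0x0103, 0),
    enc_str(0x3004, 0x0002, "CS", "GY"),
    enc_str(0x3004, 0x0004, "CS",
            if (grid$dose_kind == "EQD2") "EFFECTIVE" else "PHYSICAL"),
    enc_str(0x3004, 0x000A, "CS", "PLAN"),
    enc_ds(0x3004, 0x000C, (seq_len(g$shape[3]) - 1) * g$spacing[3]),
    enc_str(0x3004, 0x000E, "DS", scaling_str),
    enc_element(0x7FE0, 0x0010, "OW", pix))
  write_dicom_file(path, UID_RTDOSE, sop_uid, ds)
}

#' Read a DICOM RT Dose object into a dose grid
#'
#' Supports the axis-aligned, uniformly spaced Explicit VR Little Endian
#' dialect with 16- or 32-bit unsigned dose pixels.  Any missing geometry
#' tag is a hard error; non-uniform grid frame offsets are rejected.
#'
#' @param path RT Dose file path.
#' @param frame_id frame label for the geometry (default: the file's
#'   FrameOfReferenceUID).
#' @return a \code{dose_grid} (dose kind restored from DoseType).
#' @export
read_rtdose <- function(path) {
  el <- read_dicom_file(path)
  sop <- el_str(require_el(el, "0008,0016", "SOP Class UID"))
  if (!identical(sop, UID_RTDOSE)) stop("not an RT Dose object: ", path)
  units <- el_str(require_el(el, "3004,0002", "DoseUnits"))
  if (!identical(units, "GY")) stop("format error: DoseUnits must be GY")
  summ <- el_str(el[["3004,000A"]])
  if (!is.null(summ) && summ != "PLAN")
    warning("DoseSummationType '", summ, "' treated as PLAN")
  ipp <- el_nums(require_el(el, "0020,0032", "ImagePositionPatient"))
  iop <- el_nums(require_el(el, "0020,0037", "ImageOrientationPatient"))
  rows <- el_u16v(require_el(el, "0028,0010", "Rows"))
  cols <- el_u16v(require_el(el, "0028,0011", "Columns"))
  nframes <- as.integer(el_str(require_el(el, "0028,0008", "NumberOfFrames")))
  psp <- el_nums(require_el(el, "0028,0030", "PixelSpacing"))
  gfov <- el_nums(require_el(el, "3004,000C", "GridFrameOffsetVector"))
  scaling <- el_nums(require_el(el, "3004,000E", "DoseGridScaling"))
  bits <- el_u16v(require_el(el, "0028,0100", "BitsAllocated"))
  if (length(gfov) != nframes) stop("format error: GridFrameOffsetVector length")
  dz <- if (nframes > 1) diff(gfov) else 1
  if (nframes > 2 && max(abs(diff(dz))) > 1e-4)
    stop("format error: non-uniform slice offsets are not supported")
  dzv <- if (nframes > 1) dz[1] else 1
  ori <- cbind(iop[1:3], iop[4:6])
  ori <- cbind(ori, c(ori[2, 1] * ori[3, 2] - ori[3, 1] * ori[2, 2],
                      ori[3, 1] * ori[1, 2] - ori[1, 1] * ori[3, 2],
                      ori[1, 1] * ori[2, 2] - ori[2, 1] * ori[1, 2]))
  if (max(abs(ori - diag(3))) > 1e-6)
    stop("format error: only axis-aligned orientations are supported")
  geom <- grid_geometry(origin = ipp, spacing = c(psp[2], psp[1], dzv),
                        shape = c(cols, rows, nframes), orientation = ori,
                        frame_id = el_str(el[["0020,0052"]]) %||% "FRAME")
  pix <- require_el(el, "7FE0,0010", "PixelData")$value
  vals <- if (bits == 32) {
    words <- readBin(pix, "integer", n = length(pix) / 2, size = 2,
                     signed = FALSE, endian = "little")
    lo <- words[seq(1, length(words), 2)]
    hi <- words[seq(2, length(words), 2)]
    (lo + 65536 * hi) * scaling
  } else if (bits == 16) {
    readBin(pix, "integer", n = length(pix) / 2, size = 2, signed = FALSE,
            endian = "little") * scaling
  } else stop("format error: BitsAllocated must be 16 or 32")
  kind <- if (identical(el_str(el[["3004,0004"]]), "EFFECTIVE")) "EQD2"
          else "PHYSICAL"
  out <- dose_grid(array(vals, dim = geom$shape), geom, dose_kind = kind)
  attr(out, "dose_grid_scaling") <- scaling
  out
}

# ---- RT Structure Set -----------------------------------------------------

#' Write structure masks as a DICOM RT Structure Set
#'
#' Each mask is traced into closed planar contours (marching squares per
#' slice) and written as CLOSED_PLANAR contour data with the mask name as
#' ROI name.
#'
#' @param masks list of \code{structure_mask} on one axis-aligned geometry.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_rtstruct <- function(masks, path) {
  if (length(masks) == 0L) stop("need at least one mask")
  g <- masks[[1]]$geometry
  roi_items <- lapply(seq_along(masks), function(i)
    c(enc_is(0x3006, 0x0022, i),
      enc_ui(0x3006, 0x0024, uid_from_label(g$frame_id)),
      enc_str(0x3006, 0x0026, "LO", masks[[i]]$name)))
  contour_items <- lapply(seq_along(masks), function(i) {
    cts <- mask_to_contours(masks[[i]])
    ct_items <- lapply(cts, function(ct) {
      pts <- cbind(ct$points, ct$z)
      c(enc_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        enc_is(0x3006, 0x0046, nrow(pts)),
        enc_ds(0x3006, 0x0050, as.numeric(t(pts))))
    })
    c(if (length(ct_items)) enc_sq(0x3006, 0x0040, ct_items) else raw(0),
      enc_is(0x3006, 0x0084, i))
  })
  sop_uid <- uid_from_label(paste0("rtstruct.", g$frame_id))
  ds <- c(
    enc_ui(0x0008, 0x0016, UID_RTSTRUCT),
    enc_ui(0x0008, 0x0018, sop_uid),
    enc_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    enc_str(0x3006, 0x0002, "SH", "redose"),
    enc_sq(0x3006, 0x0020, roi_items),
    enc_sq(0x3006, 0x0039, contour_items))
  write_dicom_file(path, UID_RTSTRUCT, sop_uid, ds)
}

#' Read a DICOM RT Structure Set into masks on a target geometry
#'
#' Planar contours are rasterized voxel-centre-in-polygon (even-odd rule)
#' onto \code{target}.  ROI names are taken verbatim; duplicates get
#' deterministic "_2", "_3" suffixes.  ROIs without contours yield empty
#' masks with a warning.
#'
#' @param path RT Structure Set file path.
#' @param target \code{grid_geometry} to rasterize onto.
#' @return list of \code{structure_mask}.
#' @export
read_rtstruct <- function(path, target) {
  el <- read_dicom_file(path)
  sop <- el_str(require_el(el, "0008,0016", "SOP Class UID"))
  if (!identical(sop, UID_RTSTRUCT)) stop("not an RT Structure Set: ", path)
  rois <- el[["3006,0020"]]$items %||% list()
  if (length(rois) == 0L) return(list())
  names_raw <- vapply(rois, function(it) el_str(it[["3006,0026"]]) %||% "ROI", "")
  numbers <- vapply(rois, function(it)
    as.integer(el_str(it[["3006,0022"]])), 0L)
  # deterministic de-duplication
  nm <- names_raw
  for (i in seq_along(nm)) {
    k <- sum(nm[seq_len(i - 1)] == names_raw[i] |
               grepl(paste0("^", names_raw[i], "_[0-9]+$"), nm[seq_len(i - 1)]))
    if (k > 0) nm[i] <- paste0(names_raw[i], "_", k + 1)
  }
  citems <- el[["3006,0039"]]$items %||% list()
  by_roi <- stats::setNames(vector("list", length(rois)), as.character(numbers))
  for (it in citems) {
    ref <- el_str(it[["3006,0084"]])
    cts <- lapply(it[["3006,0040"]]$items %||% list(), function(c3) {
      xyz <- matrix(el_nums(c3[["3006,0050"]]), ncol = 3, byrow = TRUE)
      list(points = xyz[, 1:2, drop = FALSE], z = xyz[1, 3])
    })
    by_roi[[ref]] <- cts
  }
  lapply(seq_along(rois), function(i) {
    cts <- by_roi[[as.character(numbers[i])]] %||% list()
    if (length(cts) == 0L)
      warning("ROI '", names_raw[i], "' has no contours; empty mask")
    rasterize_contours(cts, target, name = nm[i])
  })
}

# ---- RT Plan --------------------------------------------------------------

#' Write a minimal DICOM RT Plan carrying the fractionation scheme
#' @param scheme a \code{fractionation}.
#' @param path output file path.
#' @param label plan label.
#' @return \code{path}, invisibly.
#' @export
write_rtplan <- function(scheme, path, label = "plan") {
  fg <- list(c(enc_is(0x300A, 0x0071, 1),
               enc_is(0x300A, 0x0078, scheme$n_fractions)))
  ds <- c(
    enc_ui(0x0008, 0x0016, UID_RTPLAN),
    enc_ui(0x0008, 0x0018, uid_from_label(paste0("rtplan.", label))),
    enc_str(0x0008, 0x0060, "CS", "RTPLAN"),
    enc_str(0x300A, 0x0002, "SH", label),
    if (!is.null(scheme$prescription_total))
      enc_sq(0x300A, 0x0010,
             list(enc_ds(0x300A, 0x0026, scheme$prescription_total)))
    else raw(0),
    enc_sq(0x300A, 0x0070, fg))
  write_dicom_file(path, UID_RTPLAN, uid_from_label(paste0("rtplan.", label)), ds)
}

#' Read the fractionation scheme from a DICOM RT Plan
#'
#' Uses the single fraction group's NumberOfFractionsPlanned and, when a
#' dose reference with a target prescription is present, the prescription
#' total.  Plans with several fraction groups are rejected: the caller must
#' split them explicitly.
#'
#' @param path RT Plan file path.
#' @return a \code{fractionation}.
#' @export
read_rtplan <- function(path) {
  el <- read_dicom_file(path)
  sop <- el_str(require_el(el, "0008,0016", "SOP Class UID"))
  if (!identical(sop, UID_RTPLAN)) stop("not an RT Plan: ", path)
  fgs <- require_el(el, "300A,0070", "FractionGroupSequence")$items
  if (length(fgs) != 1L)
    stop(length(fgs), " fraction groups found; explicit selection required")
  n <- as.integer(el_str(require_el(fgs[[1]], "300A,0078",
                                    "NumberOfFractionsPlanned")))
  if (is.na(n) || n < 1) stop("format error: invalid fraction number")
  presc <- NULL
  drs <- el[["300A,0010"]]$items
  if (!is.null(drs) && length(drs) >= 1L) {
    p <- el_nums(drs[[1]][["300A,0026"]])
    if (!is.null(p)) presc <- p[1]
  }
  fractionation(n, presc)
}
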