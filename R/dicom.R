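# Minimal DICOM I/O: uncompressed Explicit VR Little Endian, one file per
# slice, restricted to the tag subset the pipeline needs (identifiers, slice
# geometry, acquisition metadata, pixel data). This is deliberately not a
# conformant DICOM implementation: multi-frame objects, sequences and
# compressed transfer syntaxes are out of scope; files using them are logged
# as codec exclusions by the loader.

.EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.pad_even <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2 == 1) c(raw, pad) else raw
}

.enc_element <- function(group, element, vr, value_raw) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                   endian = "little")
  vr_raw <- charToRaw(vr)
  if (vr %in% .LONG_VRS) {
    c(head, vr_raw, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, vr_raw,
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

.enc_str <- function(group, element, vr, value) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  .enc_element(group, element, vr,
               .pad_even(charToRaw(paste(value, collapse = "\\")), pad))
}

.enc_us <- function(group, element, value) {
  .enc_element(group, element, "US",
               writeBin(as.integer(value), raw(), size = 2,
                        endian = "little"))
}

#' Write one slice as a DICOM file
#'
#' Emits an uncompressed Explicit VR Little Endian secondary-capture-style
#' object carrying the hierarchy identifiers, slice geometry
#' (ImagePositionPatient, ImageOrientationPatient, SliceThickness),
#' acquisition metadata and 16-bit pixel data. Used to materialize phantom
#' studies as on-disk fixtures for [load_study()].
#'
#' @param record an [image_record()] with non-null integer-valued pixels.
#' @param path output file path.
#' @param modality,manufacturer,series_description,body_part,contrast_agent
#'   metadata strings (contrast_agent empty = non-contrast).
#' @param image_type backslash-joined ImageType value.
#' @param orientation six direction cosines (row then column vector) of the
#'   slice in patient coordinates; the default is a pure axial slice.
#' @export
write_dicom <- function(record, path, modality = "CT",
                        manufacturer = "Phantom", series_description = "",
                        body_part = "", contrast_agent = "",
                        image_type = "ORIGINAL\\PRIMARY\\AXIAL",
                        orientation = c(1, 0, 0, 0, 1, 0)) {
  stopifnot(inherits(record, "image_record"), !is.null(record$pixels))
  px <- record$pixels
  stored <- as.integer(round(pmax(pmin(px, 65535), 0)))
  # pixel data row-major as DICOM expects
  pix_raw <- writeBin(as.vector(t(matrix(stored, nrow(px), ncol(px)))),
                      raw(), size = 2, endian = "little")

  body <- c(
    .enc_str(0x0008, 0x0008, "CS", image_type),
    .enc_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .enc_str(0x0008, 0x0018, "UI", record$sop_uid),
    .enc_str(0x0008, 0x0060, "CS", modality),
    .enc_str(0x0008, 0x0070, "LO", manufacturer),
    .enc_str(0x0008, 0x103E, "LO", series_description),
    .enc_str(0x0010, 0x0020, "LO", record$patient_id),
    .enc_str(0x0018, 0x0010, "LO", contrast_agent),
    .enc_str(0x0018, 0x0015, "CS", body_part),
    .enc_str(0x0018, 0x0050, "DS", format(record$slice_thickness)),
    .enc_str(0x0020, 0x000D, "UI", record$study_uid),
    .enc_str(0x0020, 0x000E, "UI", record$series_uid),
    .enc_str(0x0020, 0x0032, "DS",
             c("0", "0", format(record$z_position))),
    .enc_str(0x0020, 0x0037, "DS", format(orientation)),
    .enc_str(0x0020, 0x0052, "UI", record$frame_of_reference_uid),
    .enc_us(0x0028, 0x0002, record$n_channels),
    .enc_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .enc_us(0x0028, 0x0010, nrow(px)),
    .enc_us(0x0028, 0x0011, ncol(px)),
    .enc_us(0x0028, 0x0100, 16L),
    .enc_us(0x0028, 0x0101, record$bits_stored),
    .enc_us(0x0028, 0x0102, record$bits_stored - 1L),
    .enc_us(0x0028, 0x0103, 0L),
    .enc_element(0x7FE0, 0x0010, "OW", pix_raw))

  meta <- c(
    .enc_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .enc_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .enc_str(0x0002, 0x0003, "UI", record$sop_uid),
    .enc_str(0x0002, 0x0010, "UI", .EXPLICIT_LE))
  meta <- c(.enc_element(0x0002, 0x0000, "UL",
                         writeBin(length(meta), raw(), size = 4,
                                  endian = "little")),
            meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# Parse one Explicit VR Little Endian file into a named list of elements
# keyed "GGGG,EEEE". Values of string VRs are split on backslash; US/UL are
# decoded as integers; OW kept raw.
.read_dicom_elements <- function(path) {
  raw_all <- readBin(path, raw(), file.info(path)$size)
  if (length(raw_all) < 140 ||
      rawToChar(raw_all[129:132]) != "DICM")
    abort_br("not a DICOM file: %s", path)
  pos <- 133L
  n <- length(raw_all)
  out <- list()
  u16 <- function(i) readBin(raw_all[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(raw_all[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7 <= n) {
    grp <- u16(pos); elt <- u16(pos + 2L)
    vr <- rawToChar(raw_all[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- u32(pos + 8L); val_start <- pos + 12L
    } else {
      len <- u16(pos + 6L); val_start <- pos + 8L
    }
    if (len < 0 || val_start + len - 1 > n)
      abort_br("truncated DICOM element in %s", path)
    val_raw <- if (len > 0) raw_all[val_start:(val_start + len - 1L)] else raw()
    key <- sprintf("%04X,%04X", grp, elt)
    out[[key]] <- switch(vr,
      US = readBin(val_raw, "integer", n = len / 2, size = 2,
                   endian = "little", signed = FALSE),
      UL = readBin(val_raw, "integer", n = len / 4, size = 4,
                   endian = "little"),
      OW = val_raw,
      OB = val_raw,
      {
        s <- rawToChar(val_raw[val_raw != as.raw(0)])
        trimws(strsplit(s, "\\", fixed = TRUE)[[1]])
      })
    pos <- val_start + len
  }
  ts <- out[["0002,0010"]]
  if (!is.null(ts) && ts != .EXPLICIT_LE)
    abort_br("unsupported transfer syntax (codec) in %s: %s", path, ts)
  out
}

# Obliquity: angle in degrees between the slice normal (cross product of the
# row and column direction cosines) and the patient z axis.
.obliquity_from_orientation <- function(ori) {
  if (is.null(ori) || length(ori) != 6) return(0)
  o <- as.numeric(ori)
  r <- o[1:3]; c_ <- o[4:6]
  nrm <- c(r[2] * c_[3] - r[3] * c_[2],
           r[3] * c_[1] - r[1] * c_[3],
           r[1] * c_[2] - r[2] * c_[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  acos(min(1, abs(nrm[3]))) * 180 / pi
}

.series_type_from_tags <- function(image_type, series_description,
                                   keywords = series_type_keywords()) {
  it <- toupper(paste(image_type, collapse = "\\"))
  sd <- tolower(paste(series_description, collapse = " "))
  has <- function(words, x) any(vapply(words, grepl, TRUE, x = x,
                                       fixed = TRUE))
  if (grepl("LOCALIZER", it) || has(keywords$scout, sd)) return("scout")
  if (grepl("SECONDARY", it)) return("secondary")
  if (has(keywords$reformat, sd) || grepl("REFORMATTED", it))
    return("reformat")
  if (has(keywords$other, sd)) return("other")
  "axial_primary"
}

#' Keyword lists for series-type detection
#'
#' Series categories (scout/calibration, reformat, secondary capture) are
#' detected from the ImageType value and free-text SeriesDescription; the
#' keyword lists are configurable because description text is
#' site-dependent.
#'
#' @param scout,reformat,other lowercase substrings matched against the
#'   series description.
#' @export
series_type_keywords <- function(scout = c("scout", "localizer", "topogram",
                                           "calibration", "qc"),
                                 reformat = c("mpr", "reformat", "cor ",
                                              "sag ", "coronal", "sagittal"),
                                 other = c("perfusion", "cine", "cad",
                                           "screen save", "3d")) {
  list(scout = scout, reformat = reformat, other = other)
}

.record_from_elements <- function(el) {
  rows <- el[["0028,0010"]] %||% NA_integer_
  cols <- el[["0028,0011"]] %||% NA_integer_
  pix <- NULL
  if (!is.null(el[["7FE0,0010"]]) && !is.na(rows) && !is.na(cols)) {
    vals <- readBin(el[["7FE0,0010"]], "integer", n = rows * cols,
                    size = 2, endian = "little", signed = FALSE)
    pix <- matrix(vals, nrow = rows, byrow = TRUE)
  }
  ipp <- as.numeric(el[["0020,0032"]] %||% c(0, 0, 0))
  image_record(
    pixels = pix,
    z_position = ipp[3],
    slice_thickness = as.numeric(el[["0018,0050"]] %||% 0),
    obliquity_deg = .obliquity_from_orientation(el[["0020,0037"]]),
    bits_stored = as.integer(el[["0028,0101"]] %||% 16L),
    n_channels = as.integer(el[["0028,0002"]] %||% 1L),
    sop_uid = el[["0008,0018"]] %||% "",
    series_uid = el[["0020,000E"]] %||% "",
    study_uid = el[["0020,000D"]] %||% "",
    patient_id = el[["0010,0020"]] %||% "",
    frame_of_reference_uid = el[["0020,0052"]] %||% "")
}

#' Load a directory of DICOM slices into studies
#'
#' Reads every file under `path`, groups slices by (patient, study, series),
#' sorts each series by slice position and detects the series type from
#' ImageType/SeriesDescription keywords. Files that cannot be parsed (wrong
#' format, unsupported codec) are skipped and counted; slices without pixel
#' data are kept as flagged records so [filter_images()] can log them.
#'
#' @param path directory containing DICOM files (searched recursively).
#' @param keywords see [series_type_keywords()].
#' @return list with `studies` (list of `region_study`) and `skipped`
#'   (`data.frame` of unreadable files with messages).
#' @export
load_study <- function(path, keywords = series_type_keywords()) {
  files <- sort(list.files(path, recursive = TRUE, full.names = TRUE))
  if (!length(files)) abort_br("no files under %s", path)
  skipped <- list()
  parsed <- list()
  for (f in files) {
    el <- tryCatch(.read_dicom_elements(f), error = function(e) e)
    if (inherits(el, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(file = f, message = conditionMessage(el),
                   stringsAsFactors = FALSE)
      next
    }
    parsed[[length(parsed) + 1L]] <- el
  }
  if (length(skipped))
    message(sprintf("load_study: skipped %d unreadable file(s)",
                    length(skipped)))
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(file = character(), message = character())

  series_key <- vapply(parsed, function(el)
    paste(el[["0010,0020"]] %||% "", el[["0020,000D"]] %||% "",
          el[["0020,000E"]] %||% "", sep = "|"), "")
  studies <- list()
  for (sk in unique(series_key)) {
    els <- parsed[series_key == sk]
    recs <- lapply(els, .record_from_elements)
    el1 <- els[[1]]
    modality <- (el1[["0008,0060"]] %||% "CT")[1]
    ser <- new_series(
      recs,
      series_type = .series_type_from_tags(el1[["0008,0008"]],
                                           el1[["0008,103E"]], keywords),
      metadata = list(
        modality = modality,
        manufacturer = (el1[["0008,0070"]] %||% "")[1],
        contrast = length(el1[["0018,0010"]] %||% character()) > 0,
        body_part_examined = (el1[["0018,0015"]] %||% "")[1],
        series_description = (el1[["0008,103E"]] %||% "")[1]))
    stid <- paste(recs[[1]]$patient_id, recs[[1]]$study_uid, sep = "|")
    studies[[stid]] <- c(studies[[stid]], list(ser))
  }
  studies <- lapply(studies, new_study)
  list(studies = unname(studies), skipped = skipped)
}

#' Write a whole study as DICOM files
#'
#' One file per slice under `dir/<series_uid>/<sop_uid>.dcm`.
#'
#' @param study a `region_study`.
#' @param dir output directory (created if needed).
#' @param modality written into every file.
#' @export
write_study_dicom <- function(study, dir, modality = "CT") {
  stopifnot(inherits(study, "region_study"))
  for (s in study$series) {
    sd <- file.path(dir, s$series_uid)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    desc <- s$metadata$series_description %||% ""
    itype <- switch(s$series_type,
      scout = "ORIGINAL\\PRIMARY\\LOCALIZER",
      secondary = "DERIVED\\SECONDARY",
      reformat = "DERIVED\\SECONDARY\\REFORMATTED",
      "ORIGINAL\\PRIMARY\\AXIAL")
    contrast <- if (isTRUE(s$metadata$contrast)) "CONTRAST" else ""
    for (im in s$images) {
      write_dicom(im, file.path(sd, paste0(im$sop_uid, ".dcm")),
                  modality = s$metadata$modality %||% modality,
                  manufacturer = s$metadata$manufacturer %||% "Phantom",
                  series_description = desc,
                  body_part = s$metadata$body_part_examined %||% "",
                  contrast_agent = contrast,
                  image_type = itype)
    }
  }
  invisible(dir)
}
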