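# Patient -> study -> series -> image data model.
#
# The hierarchy mirrors the DICOM information model: a study is one exam of
# one patient; a series is one acquisition (a stack of 2D slices sharing a
# frame of reference); an image is one slice with its geometry and
# acquisition metadata.

#' Construct a single-slice image record
#'
#' @param pixels numeric matrix of stored pixel values (single channel), or
#'   `NULL` when the source had no pixel data (such records are flagged and
#'   removed by [filter_images()]).
#' @param z_position slice-center position in mm along the patient
#'   cranio-caudal axis (larger z = more cranial).
#' @param slice_thickness slice thickness in mm.
#' @param obliquity_deg angular deviation of the slice from the axial plane,
#'   in degrees.
#' @param bits_stored stored bit depth.
#' @param n_channels number of samples per pixel (1 for grayscale).
#' @param sop_uid,series_uid,study_uid,patient_id,frame_of_reference_uid
#'   identifiers.
#' @return an object of class `image_record`.
#' @export
image_record <- function(pixels, z_position, slice_thickness = 5,
                         obliquity_deg = 0, bits_stored = 12L,
                         n_channels = 1L, sop_uid = "",
                         series_uid = "", study_uid = "", patient_id = "",
                         frame_of_reference_uid = "") {
  if (!is.null(pixels) && !is.matrix(pixels))
    abort_br("pixels must be a matrix or NULL")
  if (!is.finite(z_position)) abort_br("z_position must be finite")
  structure(list(
    pixels = pixels,
    z_position = as.numeric(z_position),
    slice_thickness = as.numeric(slice_thickness),
    obliquity_deg = as.numeric(obliquity_deg),
    bits_stored = as.integer(bits_stored),
    n_channels = as.integer(n_channels),
    pixel_count = if (is.null(pixels)) 0L else length(pixels),
    sop_uid = sop_uid, series_uid = series_uid, study_uid = study_uid,
    patient_id = patient_id,
    frame_of_reference_uid = frame_of_reference_uid),
    class = "image_record")
}

#' Construct a series (stack of slices)
#'
#' Images are sorted ascending by `z_position` on construction; all images
#' must share the series identifiers.
#'
#' @param images list of [image_record()] objects.
#' @param series_type one of `"axial_primary"`, `"scout"`, `"reformat"`,
#'   `"secondary"`, `"other"`. Only `axial_primary` series enter the
#'   classification pipeline (see [filter_series()]).
#' @param metadata named list of acquisition metadata (modality,
#'   manufacturer, contrast flag, sequence family or CT kernel, institution
#'   type, patient age band / sex).
#' @param series_uid,frame_of_reference_uid identifiers; default to the
#'   first image's.
#' @return an object of class `region_series`.
#' @export
new_series <- function(images, series_type = "axial_primary",
                       metadata = list(), series_uid = NULL,
                       frame_of_reference_uid = NULL) {
  stopifnot(is.list(images))
  series_type <- match.arg(series_type,
    c("axial_primary", "scout", "reformat", "secondary", "other"))
  if (length(images)) {
    z <- vapply(images, function(im) im$z_position, 0)
    images <- images[order(z)]
    series_uid <- series_uid %||% images[[1]]$series_uid
    frame_of_reference_uid <-
      frame_of_reference_uid %||% images[[1]]$frame_of_reference_uid
    uids <- unique(vapply(images, function(im) im$series_uid, ""))
    if (length(uids) > 1) abort_br("images span multiple series_uids")
  }
  structure(list(images = images, series_type = series_type,
                 metadata = metadata,
                 series_uid = series_uid %||% "",
                 frame_of_reference_uid = frame_of_reference_uid %||% ""),
            class = "region_series")
}

#' Construct a study (one exam of one patient)
#'
#' @param series list of [new_series()] objects sharing `study_uid`.
#' @param study_uid,patient_id identifiers; default to the first series'.
#' @return an object of class `region_study`.
#' @export
new_study <- function(series, study_uid = NULL, patient_id = NULL) {
  stopifnot(is.list(series))
  if (length(series)) {
    first <- series[[1]]$images
    if (length(first)) {
      study_uid <- study_uid %||% first[[1]]$study_uid
      patient_id <- patient_id %||% first[[1]]$patient_id
    }
  }
  structure(list(series = series, study_uid = study_uid %||% "",
                 patient_id = patient_id %||% ""),
            class = "region_study")
}

#' @export
print.region_series <- function(x, ...) {
  cat(sprintf("<region_series> %s [%s] %d image(s)\n",
              x$series_uid, x$series_type, length(x$images)))
  invisible(x)
}

#' @export
print.region_study <- function(x, ...) {
  cat(sprintf("<region_study> %s patient=%s %d series\n",
              x$study_uid, x$patient_id, length(x$series)))
  invisible(x)
}

n_images <- function(study) {
  sum(vapply(study$series, function(s) length(s$images), 0L))
}

study_images <- function(study) {
  unlist(lapply(study$series, function(s) s$images), recursive = FALSE)
}
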