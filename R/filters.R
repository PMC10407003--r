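# Series- and image-level inclusion/exclusion filters.
#
# The pipeline classifies primary axial acquisitions only. Planning series
# (scouts, calibration), multiplanar reformats and post-processed/secondary
# captures are dropped at the series level. At the image level, slices are
# kept only if they carry usable grayscale pixel data: obliquity from the
# axial plane up to 45 degrees (inclusive), more than 8 stored bits, a
# single channel, and at least 1000 pixels.

#' Image-level filter configuration
#'
#' @param max_obliquity_deg maximum angular deviation from the axial plane;
#'   the boundary is inclusive ("up to 45 degrees" keeps 45.0).
#' @param min_bits_stored minimum stored bit depth; images at 8 bits or
#'   lower are excluded.
#' @param min_pixel_count minimum number of pixels.
#' @export
filter_config <- function(max_obliquity_deg = 45, min_bits_stored = 9L,
                          min_pixel_count = 1000L) {
  structure(list(max_obliquity_deg = max_obliquity_deg,
                 min_bits_stored = as.integer(min_bits_stored),
                 min_pixel_count = as.integer(min_pixel_count)),
            class = "filter_config")
}

.image_exclusion_reason <- function(im, rules) {
  if (is.null(im$pixels)) return("no_pixel_data")
  if (im$n_channels != 1L) return("multi_channel")
  if (im$bits_stored < rules$min_bits_stored) return("bit_depth")
  if (im$pixel_count < rules$min_pixel_count) return("pixel_count")
  if (im$obliquity_deg > rules$max_obliquity_deg) return("obliquity")
  NA_character_
}

#' Apply image-level exclusion criteria
#'
#' Filtering never raises: every removed image is recorded in the exclusion
#' log with a single reason (the first criterion it fails, checked in the
#' order no-pixel-data, multi-channel, bit depth, pixel count, obliquity).
#' The operation is idempotent and retained + excluded always partitions the
#' input.
#'
#' @param study a `region_study`.
#' @param rules a [filter_config()].
#' @return list with elements `study` (filtered) and `exclusions`
#'   (`data.frame` with columns `sop_uid`, `series_uid`, `reason`).
#' @export
filter_images <- function(study, rules = filter_config()) {
  stopifnot(inherits(study, "region_study"))
  logs <- list()
  series <- lapply(study$series, function(s) {
    reasons <- vapply(s$images, .image_exclusion_reason, "", rules = rules)
    drop <- !is.na(reasons)
    if (any(drop)) {
      logs[[length(logs) + 1L]] <<- data.frame(
        sop_uid = vapply(s$images[drop], function(im) im$sop_uid, ""),
        series_uid = s$series_uid,
        reason = reasons[drop], stringsAsFactors = FALSE)
    }
    s$images <- s$images[!drop]
    s
  })
  excl <- if (length(logs)) do.call(rbind, logs) else
    data.frame(sop_uid = character(), series_uid = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(study = new_study(series, study$study_uid, study$patient_id),
       exclusions = excl)
}

#' Apply series-level exclusion criteria
#'
#' Keeps only `axial_primary` series; scouts, reformats, secondary captures
#' and other non-primary series are removed and logged. A study left with no
#' series triggers a warning but is returned (empty) rather than raising.
#'
#' @param study a `region_study`.
#' @return list with elements `study` and `exclusions` (`data.frame` with
#'   columns `series_uid`, `reason`).
#' @export
filter_series <- function(study) {
  stopifnot(inherits(study, "region_study"))
  types <- vapply(study$series, function(s) s$series_type, "")
  keep <- types == "axial_primary"
  excl <- data.frame(
    series_uid = vapply(study$series[!keep], function(s) s$series_uid, ""),
    reason = paste0("series_type:", types[!keep], recycle0 = TRUE),
    stringsAsFactors = FALSE)
  if (!any(keep) && length(study$series))
    warning(sprintf("study %s has no axial primary series left",
                    study$study_uid), call. = FALSE)
  list(study = new_study(study$series[keep], study$study_uid,
                         study$patient_id),
       exclusions = excl)
}

#' Write an exclusion log as CSV
#'
#' @param exclusions a `data.frame` as returned by [filter_images()] or
#'   [filter_series()].
#' @param path output file.
#' @export
write_exclusion_log <- function(exclusions, path) {
  write.csv(exclusions, path, row.names = FALSE)
  invisible(path)
}
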