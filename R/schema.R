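# Body-region vocabularies and anatomical landmark intervals.

# Canonical snake_case class names. Ordering of the output classes is
# alphabetical and frozen: the index of a class in the vocabulary is the
# classifier's output position, so it must never change between a trained
# model and a report.
.CT_REGIONS <- sort(c(
  "head", "neck", "chest", "abdomen", "pelvis_hip", "thigh", "knee",
  "calf", "foot", "shoulder", "arm", "elbow", "forearm", "hand",
  "spine_cervical", "spine_thoracic", "spine_lumbar"
))
.MRI_REGIONS <- sort(c(.CT_REGIONS, "breast"))

# Internal transitional class used by the classifier between the thoracic
# and abdominal cavities; never a final output label. Appended after the
# output classes so output indices are identical with or without it.
.TRANSITIONAL_CLASS <- "abdomen_chest"

#' Build the fixed body-region vocabulary for a modality
#'
#' The classification task distinguishes 17 body regions on CT and 18 on MRI
#' (breast is imaged as a dedicated region on MRI only). The vocabulary also
#' carries the internal transitional `abdomen_chest` class that the slice
#' classifier may emit around the thoraco-abdominal junction; a series-level
#' rule resolves it to either chest or abdomen, so it is never a final label.
#'
#' Output classes are ordered alphabetically on their canonical snake_case
#' names and the ordering is frozen: position in `output_classes` is the
#' classifier output index. `internal_classes` appends `abdomen_chest` last.
#'
#' @param modality `"CT"` or `"MRI"`.
#' @return an object of class `region_vocabulary` with fields `modality`,
#'   `output_classes` and `internal_classes`.
#' @examples
#' length(build_vocabulary("CT")$output_classes)   # 17
#' length(build_vocabulary("MRI")$output_classes)  # 18
#' @export
build_vocabulary <- function(modality) {
  if (!is.character(modality) || length(modality) != 1 ||
      !modality %in% c("CT", "MRI")) {
    abort_br("unknown modality '%s': must be \"CT\" or \"MRI\"",
             paste(format(modality), collapse = ","))
  }
  out <- if (modality == "CT") .CT_REGIONS else .MRI_REGIONS
  structure(
    list(modality = modality,
         output_classes = out,
         internal_classes = c(out, .TRANSITIONAL_CLASS)),
    class = "region_vocabulary")
}

#' @export
print.region_vocabulary <- function(x, ...) {
  cat(sprintf("<region_vocabulary> %s: %d output classes (+%d internal)\n",
              x$modality, length(x$output_classes),
              length(x$internal_classes) - length(x$output_classes)))
  cat(" ", paste(x$output_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Anatomical landmark intervals for all 18 body regions
#'
#' Each body region is delimited cranio-caudally by a top and a bottom
#' anatomical landmark (e.g. the knee spans from the distal 6th of the femur
#' to the proximal 6th of the tibia). The table returns the landmark text
#' for all 18 regions; `top_z`/`bottom_z` are `NA` until instantiated for a
#' concrete patient, with the convention that larger z is more cranial
#' (DICOM patient coordinates), so `top_z > bottom_z` once instantiated.
#'
#' Adjacent regions share landmarks (the lumbar spine starts at T11 while
#' the thoracic spine ends at T12; the pelvis ends where the thigh begins),
#' so instantiated intervals are treated as half-open `[bottom_z, top_z)`
#' and ties between overlapping regions are resolved by a precedence list
#' (see [default_precedence()]).
#'
#' @return a `data.frame` with columns `region`, `top_landmark`,
#'   `bottom_landmark`, `top_z`, `bottom_z` (18 rows).
#' @export
landmark_table <- function() {
  lm <- list(
    abdomen = c("Diaphragm/lung base", "Bifurcation of the aorta"),
    arm = c("Proximal 6th of humerus", "Distal 6th of humerus"),
    breast = c("Skin surface of upper breast at chest wall",
               "Skin surface of lower breast at chest wall"),
    calf = c("Proximal 6th of tibia", "Distal third of calf"),
    chest = c("Lung apex", "Lung base"),
    elbow = c("Distal 6th of humerus", "Proximal 6th of radius"),
    foot = c("Distal third of calf", "Bottom of the foot"),
    forearm = c("Proximal 6th of radius", "Distal 6th of radius"),
    hand = c("Distal 6th of radius", "Tip of finger"),
    head = c("Top of head", "Bottom of skull base (foramen magnum)"),
    knee = c("Distal 6th of femur", "Proximal 6th of tibia"),
    neck = c("Skull base (foramen magnum)", "Lung apex"),
    pelvis_hip = c("Aortic bifurcation",
                   "Lesser trochanter (hip), inferior extent of pubis symphysis (pelvis)"),
    shoulder = c("Top of acromioclavicular (AC) joint", "Proximal 6th of humerus"),
    spine_cervical = c("Tip of odontoid", "Bottom of T1"),
    spine_thoracic = c("Top of T1", "Bottom of T12"),
    spine_lumbar = c("T11", "Mid sacrum (S2, S3)"),
    thigh = c("Lesser trochanter", "Distal 6th of femur")
  )
  regions <- .MRI_REGIONS
  data.frame(
    region = regions,
    top_landmark = vapply(lm[regions], `[`, "", 1),
    bottom_landmark = vapply(lm[regions], `[`, "", 2),
    top_z = NA_real_, bottom_z = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Default label precedence for overlapping ground-truth intervals
#'
#' A slice can fall inside two instantiated landmark intervals (spine
#' segments overlap the body cavities; shared landmarks bound adjacent
#' regions). Because the classifier is single-label per image, such ties are
#' resolved by a declared precedence: spine segments first, then breast, then
#' the remaining regions in vocabulary order. This is a package convention,
#' configurable wherever a precedence list is accepted.
#'
#' @param vocabulary a `region_vocabulary`.
#' @return character vector covering `vocabulary$output_classes`.
#' @export
default_precedence <- function(vocabulary) {
  first <- intersect(
    c("spine_cervical", "spine_thoracic", "spine_lumbar", "breast"),
    vocabulary$output_classes)
  c(first, setdiff(vocabulary$output_classes, first))
}

#' Export a vocabulary as JSON
#'
#' Writes `(name, index, modality_scope)` per class so model checkpoints and
#' reports can pin the exact class ordering they were produced with. Index is
#' zero-based to match classifier output positions.
#'
#' @param vocabulary a `region_vocabulary`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
vocabulary_json <- function(vocabulary, path = NULL) {
  stopifnot(inherits(vocabulary, "region_vocabulary"))
  scope <- function(nm) {
    if (nm == "breast") list("MRI") else list("CT", "MRI")
  }
  entries <- lapply(seq_along(vocabulary$internal_classes), function(i) {
    nm <- vocabulary$internal_classes[i]
    list(name = nm, index = i - 1L,
         internal = nm == .TRANSITIONAL_CLASS,
         modality_scope = scope(nm))
  })
  js <- jsonlite::toJSON(list(modality = vocabulary$modality,
                              classes = entries), auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
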