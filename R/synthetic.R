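# Seedable phantom-study generator.
#
# Each body region is rendered as a distinctive, deterministic geometric
# texture (discs, rings, squares, bars at class-specific sizes/positions) on
# a [-1,1]^2 grid; slices stack cranio-caudally with DICOM-style geometry
# and acquisition metadata. Realism is a non-goal: the generator's contract
# is distinguishable, geometry-consistent classes so that training,
# inference, post-processing and evaluation are exercisable without clinical
# data. At boundaries between adjacent regions the two textures are blended
# linearly over a configurable transition zone, emulating the ambiguous
# transitional anatomy where real classifiers concentrate their errors.

.texture_cache <- new.env(parent = emptyenv())

.disc <- function(u, v, cx, cy, r) ((u - cx)^2 + (v - cy)^2) <= r^2
.ring <- function(u, v, cx, cy, r_out, r_in)
  .disc(u, v, cx, cy, r_out) & !.disc(u, v, cx, cy, r_in)
.square <- function(u, v, half) (abs(u) <= half) & (abs(v) <= half)

# One deterministic binary pattern per class, drawn on u,v in [-1,1].
.region_pattern <- function(region, u, v) {
  switch(region,
    head = .ring(u, v, 0, 0, 0.80, 0.35),
    neck = .disc(u, v, 0, 0, 0.30),
    chest = .disc(u / 0.35, (v - 0) / 0.55, -0.45 / 0.35, 0, 1) |
            .disc(u / 0.35, (v - 0) / 0.55,  0.45 / 0.35, 0, 1),
    breast = .disc(u, v, -0.40, 0.45, 0.28) | .disc(u, v, 0.40, 0.45, 0.28),
    abdomen = .disc(u / 0.80, v / 0.60, 0, 0, 1),
    pelvis_hip = .ring(u, v, -0.50, -0.30, 0.30, 0.15) |
                 .ring(u, v,  0.50, -0.30, 0.30, 0.15),
    thigh = .disc(u, v, -0.50, 0, 0.30) | .disc(u, v, 0.50, 0, 0.30),
    knee = .ring(u, v, -0.35, 0, 0.20, 0.10) |
           .ring(u, v,  0.35, 0, 0.20, 0.10),
    calf = .disc(u, v, -0.30, 0, 0.15) | .disc(u, v, 0.30, 0, 0.15),
    foot = (abs(v + 0.50) <= 0.15) & (abs(u) <= 0.70),
    shoulder = abs(u - v) <= 0.25,
    arm = .disc(u, v, -0.40, 0.30, 0.25),
    elbow = .ring(u, v, 0, 0, 0.25, 0.12),
    forearm = .disc(u, v, -0.15, 0, 0.12) | .disc(u, v, 0.15, 0, 0.12),
    hand = (abs(v) <= 0.7) &
           ((abs(u + 0.60) <= 0.08) | (abs(u + 0.20) <= 0.08) |
            (abs(u - 0.20) <= 0.08) | (abs(u - 0.60) <= 0.08)),
    spine_cervical = .square(u, v, 0.15),
    spine_thoracic = .square(u, v, 0.45) & !.square(u, v, 0.30),
    spine_lumbar = .square(u, v, 0.45),
    abort_br("no phantom texture defined for region '%s'", region))
}

region_texture <- function(region, n) {
  key <- paste0(region, "_", n)
  if (!is.null(.texture_cache[[key]])) return(.texture_cache[[key]])
  ax <- seq(-1, 1, length.out = n)
  u <- matrix(ax, n, n)
  v <- matrix(ax, n, n, byrow = TRUE)
  tx <- .region_pattern(region, u, v) * 1.0
  .texture_cache[[key]] <- tx
  tx
}

#' Phantom study specification
#'
#' @param modality `"CT"` or `"MRI"`.
#' @param regions ordered character vector of regions, most cranial first.
#' @param extent_mm cranio-caudal extent of each region in mm (recycled).
#' @param slice_spacing_mm distance between slice centers, mm.
#' @param slice_thickness_mm slice thickness, mm.
#' @param image_size side length of the square slice in pixels.
#' @param noise_sd additive Gaussian noise standard deviation, in stored
#'   intensity units (the foreground/background contrast is
#'   `intensity_scale`).
#' @param intensity_scale stored-value contrast between pattern foreground
#'   and background (HU-like for CT, arbitrary for MRI).
#' @param obliquity_deg slice obliquity recorded in the metadata.
#' @param transition_zone_mm width of the blended ambiguous zone centered on
#'   each region boundary.
#' @param n_series number of axial series to render (same geometry and
#'   frame of reference, independent noise).
#' @param patient_id,study_uid identifiers.
#' @param seed integer; fixes all randomness of the study.
#' @export
phantom_spec <- function(modality = "MRI", regions = c("head", "neck"),
                         extent_mm = 40, slice_spacing_mm = 5,
                         slice_thickness_mm = 5, image_size = 64,
                         noise_sd = 250, intensity_scale = 2500,
                         obliquity_deg = 0, transition_zone_mm = 10,
                         n_series = 1L, patient_id = "P0001",
                         study_uid = NULL, seed = 1L) {
  stopifnot(slice_spacing_mm > 0, image_size >= 8, n_series >= 1)
  extent_mm <- rep_len(extent_mm, length(regions))
  if (any(extent_mm <= 0)) abort_br("region extents must be positive")
  structure(list(
    modality = modality, regions = regions, extent_mm = extent_mm,
    slice_spacing_mm = slice_spacing_mm,
    slice_thickness_mm = slice_thickness_mm, image_size = image_size,
    noise_sd = noise_sd, intensity_scale = intensity_scale,
    obliquity_deg = obliquity_deg,
    transition_zone_mm = transition_zone_mm, n_series = as.integer(n_series),
    patient_id = patient_id,
    study_uid = study_uid %||% paste0("1.2.826.0.1.", patient_id),
    seed = as.integer(seed)), class = "phantom_spec")
}

# Categorical metadata distributions used when rendering studies. The mix
# loosely follows a multi-vendor clinical case mix (one dominant vendor,
# mostly non-contrast acquisitions, a spread of institution types).
.default_metadata_dist <- function() {
  list(
    manufacturer = c(Siemens = 0.55, GE = 0.20, Philips = 0.10,
                     Toshiba = 0.10, Canon = 0.05),
    contrast = 0.25,
    sequence = c(weighting = 0.6, gradient_echo = 0.2, spin_echo = 0.1,
                 inversion_recovery = 0.1),
    kernel = c(soft_tissue = 0.75, bone = 0.25),
    institution = c(primary_care = 0.55, community = 0.25,
                    imaging_center = 0.20),
    sex = c(F = 0.5, M = 0.5),
    age_band = c(`18-44` = 0.25, `45-64` = 0.35, `65+` = 0.40))
}

.sample_cat <- function(p) sample(names(p), 1L, prob = p)

#' Generate one phantom study with ground truth
#'
#' Renders the requested regions as stacked slices (most cranial region
#' first, larger z = more cranial; slice centers at
#' `total - spacing/2 - k*spacing`), with per-region textures, linear
#' texture blending over `transition_zone_mm` at region boundaries, additive
#' seeded Gaussian noise and sampled acquisition metadata. Ground truth per
#' slice comes from half-open region intervals `[z_min, z_max)` and is also
#' returned as thin 3D bounding boxes (one per region) so the annotation
#' machinery can reproduce it. Training labels equal the truth except inside
#' the chest/abdomen transition zone, where slices carry the internal
#' `abdomen_chest` class.
#'
#' @param spec a [phantom_spec()].
#' @param metadata_dist categorical metadata distributions.
#' @return object of class `phantom_study`: list with `study`
#'   (`region_study`), `truth` and `train_labels` (`data.frame` of
#'   `sop_uid`, `region`), and `boxes` (list of [bounding_box3d()]).
#' @export
generate_study <- function(spec, metadata_dist = .default_metadata_dist()) {
  stopifnot(inherits(spec, "phantom_spec"))
  vocab <- build_vocabulary(spec$modality)
  bad <- setdiff(spec$regions, vocab$output_classes)
  if (length(bad))
    abort_br("region(s) not in %s vocabulary: %s", spec$modality,
             paste(bad, collapse = ", "))

  k <- length(spec$regions)
  total <- sum(spec$extent_mm)
  z_top <- total - c(0, cumsum(spec$extent_mm))[1:k]
  z_bot <- z_top - spec$extent_mm
  frame_uid <- paste0(spec$study_uid, ".FOR")
  fov <- spec$image_size * 2  # nominal in-plane FOV, mm

  boxes <- lapply(seq_len(k), function(i)
    bounding_box3d(spec$regions[i], x = c(-fov / 2, fov / 2),
                   y = c(-fov / 2, fov / 2), z = c(z_bot[i], z_top[i]),
                   frame_of_reference_uid = frame_uid))

  z_slices <- seq(total - spec$slice_spacing_mm / 2, spec$slice_spacing_mm / 2,
                  by = -spec$slice_spacing_mm)
  # half-open [z_bot, z_top): region i owns z iff z_bot_i <= z < z_top_i
  region_at <- vapply(z_slices, function(z)
    1L + sum(z_top[-1] > z), integer(1))
  region_at[region_at > k] <- k

  # linear blend weights near each interior boundary
  tz <- spec$transition_zone_mm
  n <- spec$image_size
  truth <- spec$regions[region_at]
  train_label <- truth
  blend <- vector("list", length(z_slices))
  for (j in seq_along(z_slices)) {
    z <- z_slices[j]; i <- region_at[j]
    blend[[j]] <- list(r1 = spec$regions[i], r2 = NULL, w = 1)
    for (b_i in seq_len(k - 1L)) {
      b <- z_bot[b_i]  # boundary between region b_i (above) and b_i+1
      if (tz > 0 && abs(z - b) < tz / 2) {
        w_up <- (z - (b - tz / 2)) / tz
        blend[[j]] <- list(r1 = spec$regions[b_i],
                           r2 = spec$regions[b_i + 1L], w = w_up)
        pair <- sort(c(spec$regions[b_i], spec$regions[b_i + 1L]))
        if (identical(pair, c("abdomen", "chest")))
          train_label[j] <- "abdomen_chest"
      }
    }
  }

  with_seed(spec$seed, {
    meta_common <- list(
      modality = spec$modality,
      manufacturer = .sample_cat(metadata_dist$manufacturer),
      contrast = runif(1) < metadata_dist$contrast,
      institution = .sample_cat(metadata_dist$institution),
      sex = .sample_cat(metadata_dist$sex),
      age_band = .sample_cat(metadata_dist$age_band))
    if (spec$modality == "MRI") {
      meta_common$sequence <- .sample_cat(metadata_dist$sequence)
    } else {
      meta_common$kernel <- .sample_cat(metadata_dist$kernel)
    }

    series_list <- lapply(seq_len(spec$n_series), function(s) {
      series_uid <- sprintf("%s.S%d", spec$study_uid, s)
      imgs <- lapply(seq_along(z_slices), function(j) {
        bl <- blend[[j]]
        pat <- region_texture(bl$r1, n) * bl$w
        if (!is.null(bl$r2)) pat <- pat + region_texture(bl$r2, n) * (1 - bl$w)
        px <- 200 + spec$intensity_scale * pat
        if (spec$noise_sd > 0)
          px <- px + matrix(rnorm(n * n, sd = spec$noise_sd), n, n)
        px <- round(pmin(pmax(px, 0), 4095))
        image_record(px, z_position = z_slices[j],
                     slice_thickness = spec$slice_thickness_mm,
                     obliquity_deg = spec$obliquity_deg,
                     bits_stored = 12L,
                     sop_uid = sprintf("%s.I%03d", series_uid, j),
                     series_uid = series_uid, study_uid = spec$study_uid,
                     patient_id = spec$patient_id,
                     frame_of_reference_uid = frame_uid)
      })
      new_series(imgs, "axial_primary", metadata = meta_common)
    })
    study <- new_study(series_list, spec$study_uid, spec$patient_id)
  })

  all_sops <- vapply(study_images(study), function(im) im$sop_uid, "")
  per_series_truth <- rep(truth[order(z_slices)], spec$n_series)
  per_series_train <- rep(train_label[order(z_slices)], spec$n_series)
  structure(list(
    study = study,
    truth = data.frame(sop_uid = all_sops, region = per_series_truth,
                       stringsAsFactors = FALSE),
    train_labels = data.frame(sop_uid = all_sops,
                              region = per_series_train,
                              stringsAsFactors = FALSE),
    boxes = boxes, spec = spec), class = "phantom_study")
}

#' Canonical region ring used to compose multi-region phantom studies
#'
#' Regions are arranged so that anatomically adjacent trunk regions are
#' neighbors (head..foot), followed by the spine segments and the upper
#' extremity; MRI inserts breast next to chest. Cohort studies cover
#' contiguous windows of this ring, which guarantees the chest/abdomen
#' junction (and its transitional class) occurs regularly.
#'
#' @param modality `"CT"` or `"MRI"`.
#' @export
region_ring <- function(modality) {
  ring <- c("head", "neck", "chest", "abdomen", "pelvis_hip", "thigh",
            "knee", "calf", "foot", "spine_cervical", "spine_thoracic",
            "spine_lumbar", "shoulder", "arm", "elbow", "forearm", "hand")
  if (modality == "MRI") ring <- append(ring, "breast", after = 2L)
  ring
}

#' Generate a seeded cohort of phantom studies
#'
#' Patients receive unique ids; each patient's study covers a contiguous
#' window of `regions_per_study` regions of [region_ring()], with window
#' starts assigned round-robin (in seeded random patient order) so every
#' region appears with near-equal frequency across the cohort.
#'
#' @param n_patients number of patients (one study each).
#' @param modality `"CT"` or `"MRI"`.
#' @param regions_per_study window length.
#' @param seed integer master seed for the cohort.
#' @param ... further arguments passed to [phantom_spec()] (e.g.
#'   `extent_mm`, `noise_sd`, `n_series`).
#' @return list of `phantom_study`.
#' @export
generate_cohort <- function(n_patients, modality = "MRI",
                            regions_per_study = 3L, seed = 1L, ...) {
  stopifnot(n_patients >= 1)
  ring <- region_ring(modality)
  nr <- length(ring)
  starts <- with_seed(derive_seed(seed, "cohort_starts"),
                      sample(rep_len(seq_len(nr), n_patients)))
  lapply(seq_len(n_patients), function(i) {
    idx <- ((starts[i] - 1L + 0:(regions_per_study - 1L)) %% nr) + 1L
    pid <- sprintf("P%04d", i)
    spec <- phantom_spec(
      modality = modality, regions = ring[idx],
      patient_id = pid,
      study_uid = sprintf("1.2.826.0.1.%d.%d", seed %% 100000L, i),
      seed = derive_seed(seed, paste0("study_", i)), ...)
    generate_study(spec)
  })
}

#' Export cohort ground truth as CSV
#'
#' @param cohort list of `phantom_study`.
#' @param path output CSV (columns `sop_uid`, `region`).
#' @param what `"truth"` (final evaluation labels) or `"train_labels"`
#'   (includes the internal transitional class).
#' @export
write_truth_csv <- function(cohort, path, what = c("truth", "train_labels")) {
  what <- match.arg(what)
  df <- do.call(rbind, lapply(cohort, `[[`, what))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
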