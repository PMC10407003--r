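test_that("series sort their slices by position regardless of input order", {
  z <- c(30, 10, 50, 20, 40)
  s <- make_test_series(z)
  expect_equal(vapply(s$images, `[[`, 0, "z_position"), sort(z))
  s2 <- make_test_series(sort(z))
  expect_equal(vapply(s2$images, `[[`, "", "sop_uid")[order(sort(z))],
               vapply(s2$images, `[[`, "", "sop_uid"))
})

test_that("image filters implement the inclusion criteria with exact boundaries", {
  mk <- function(...) new_study(list(make_test_series(...)))
  # < 1000 pixels excluded
  r <- filter_images(mk(z = 10, npix = 20))  # 400 px
  expect_equal(n_images_of(r$study), 0)
  expect_equal(r$exclusions$reason, "pixel_count")
  # obliquity boundary: "up to 45 degrees" is inclusive
  expect_equal(n_images_of(filter_images(mk(z = 10, obliquity = 44.9))$study), 1)
  expect_equal(n_images_of(filter_images(mk(z = 10, obliquity = 45.0))$study), 1)
  r <- filter_images(mk(z = 10, obliquity = 45.1))
  expect_equal(n_images_of(r$study), 0)
  expect_equal(r$exclusions$reason, "obliquity")
  # 8-bit or lower excluded, 9 bits kept
  r <- filter_images(mk(z = 10, bits = 8L))
  expect_equal(r$exclusions$reason, "bit_depth")
  expect_equal(n_images_of(filter_images(mk(z = 10, bits = 9L))$study), 1)
  # missing pixel data flagged, not crashed
  s <- make_test_series(c(10, 20))
  s$images[[1]]$pixels <- NULL
  s$images[[1]]$pixel_count <- 0L
  r <- filter_images(new_study(list(s)))
  expect_equal(n_images_of(r$study), 1)
  expect_equal(r$exclusions$reason, "no_pixel_data")
})

test_that("filtering is idempotent and partitions the input", {
  s1 <- make_test_series(c(10, 20, 30), series_uid = "A", obliquity = 50)
  s2 <- make_test_series(c(10, 20, 30, 40), series_uid = "B")
  st <- new_study(list(s1, s2))
  r1 <- filter_images(st)
  expect_equal(n_images_of(r1$study) + nrow(r1$exclusions), n_images_of(st))
  r2 <- filter_images(r1$study)
  expect_equal(n_images_of(r2$study), n_images_of(r1$study))
  expect_equal(nrow(r2$exclusions), 0)
})

test_that("series filter keeps only primary axial acquisitions", {
  ax <- make_test_series(c(10, 20), series_uid = "AX")
  sc <- make_test_series(5, series_uid = "SC", series_type = "scout")
  r <- filter_series(new_study(list(ax, sc)))
  expect_length(r$study$series, 1)
  expect_equal(r$study$series[[1]]$series_uid, "AX")
  expect_equal(r$exclusions$reason, "series_type:scout")
  # only reformats -> empty study with a warning
  rf <- make_test_series(5, series_uid = "RF", series_type = "reformat")
  expect_warning(r2 <- filter_series(new_study(list(rf))), "no axial")
  expect_length(r2$study$series, 0)
  # all-axial study unchanged
  r3 <- filter_series(new_study(list(ax)))
  expect_length(r3$study$series, 1)
  expect_equal(nrow(r3$exclusions), 0)
})

test_that("DICOM writer/loader round-trips a phantom study", {
  ps <- generate_study(phantom_spec(modality = "MRI",
                                    regions = c("head", "neck"),
                                    extent_mm = 20, seed = 7))
  dir <- withr::local_tempdir()
  write_study_dicom(ps$study, dir, modality = "MRI")
  loaded <- load_study(dir)
  expect_length(loaded$studies, 1)
  st <- loaded$studies[[1]]
  expect_equal(n_images_of(st), n_images_of(ps$study))
  orig <- ps$study$series[[1]]$images
  back <- st$series[[1]]$images
  for (i in seq_along(orig)) {
    expect_equal(back[[i]]$z_position, orig[[i]]$z_position)
    expect_equal(unname(back[[i]]$pixels), unname(orig[[i]]$pixels),
                 ignore_attr = TRUE)
  }
  expect_equal(st$series[[1]]$metadata$modality, "MRI")
  expect_equal(st$patient_id, ps$study$patient_id)
  expect_equal(back[[1]]$frame_of_reference_uid,
               orig[[1]]$frame_of_reference_uid)
})

test_that("unreadable files are skipped and counted, not fatal", {
  ps <- generate_study(phantom_spec(regions = "head", extent_mm = 10,
                                    seed = 1))
  dir <- withr::local_tempdir()
  write_study_dicom(ps$study, dir)
  writeLines("this is not dicom at all, just text", file.path(dir, "junk.txt"))
  expect_message(loaded <- load_study(dir), "skipped 1")
  expect_equal(nrow(loaded$skipped), 1)
  expect_length(loaded$studies, 1)
})

test_that("series type is detected from ImageType and description keywords", {
  ps <- generate_study(phantom_spec(regions = "head", extent_mm = 10,
                                    seed = 2))
  st <- ps$study
  st$series[[1]]$series_type <- "scout"
  dir <- withr::local_tempdir()
  write_study_dicom(st, dir)
  loaded <- load_study(dir)
  expect_equal(loaded$studies[[1]]$series[[1]]$series_type, "scout")
})

test_that("written files parse with an independent DICOM implementation", {
  rec <- image_record(matrix(7L, 32, 48), z_position = 12.5,
                      slice_thickness = 2.5, sop_uid = "1.2.3.4",
                      series_uid = "1.2.3", study_uid = "1.2",
                      patient_id = "PX", frame_of_reference_uid = "1.9")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(rec, path, modality = "MRI", manufacturer = "Phantom")
  script <- paste0(
    "import pydicom, sys\n",
    "d = pydicom.dcmread(sys.argv[1])\n",
    "print(d.Rows, d.Columns, d.Modality, d.PatientID,\n",
    "      d.ImagePositionPatient[2], d.BitsStored,\n",
    "      int(d.pixel_array[0][0]), d.pixel_array.shape[0])\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE)
  expect_equal(strsplit(out, " +")[[1]],
               c("32", "48", "MRI", "PX", "12.5", "12", "7", "32"))
})
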