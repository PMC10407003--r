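# Shared fixture builders: everything is generated in code at test time.

# Prediction sequence from hard labels: the labeled class gets probability
# `conf`, the remainder is spread uniformly over the other classes.
seq_from_labels <- function(labels, classes, conf = 0.9, modality = "CT",
                            z = NULL) {
  k <- length(classes)
  probs <- matrix((1 - conf) / (k - 1), length(labels), k,
                  dimnames = list(NULL, classes))
  probs[cbind(seq_along(labels), match(labels, classes))] <- conf
  prediction_sequence(z = z %||% seq(2.5, by = 5,
                                     length.out = length(labels)),
                      probs = probs, classes = classes, modality = modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_images_of <- function(study)
  sum(vapply(study$series, function(s) length(s$images), 0L))

all_images_of <- function(study)
  unlist(lapply(study$series, function(s) s$images), recursive = FALSE)

# Minimal in-memory study: one or more series of flat images at given z.
make_test_series <- function(z, series_uid = "S1", frame = "F1",
                             series_type = "axial_primary",
                             obliquity = 0, bits = 12L, npix = 64L,
                             pixels = NULL, modality = "CT") {
  imgs <- lapply(seq_along(z), function(i)
    image_record(pixels %||% matrix(seq_len(npix * npix), npix, npix),
                 z_position = z[i], obliquity_deg = obliquity,
                 bits_stored = bits,
                 sop_uid = sprintf("%s.I%d", series_uid, i),
                 series_uid = series_uid, study_uid = "ST1",
                 patient_id = "P1", frame_of_reference_uid = frame))
  new_series(imgs, series_type, metadata = list(modality = modality),
             series_uid = series_uid, frame_of_reference_uid = frame)
}

# Brute-force metric oracle: expand a confusion matrix into per-image
# (pred, truth) pairs and count TP/FP/FN/TN per class directly.
oracle_metrics <- function(cm) {
  classes <- colnames(cm)
  pred <- character(0); truth <- character(0)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    n <- cm[i, j]
    if (n > 0) {
      pred <- c(pred, rep(classes[i], n))
      truth <- c(truth, rep(classes[j], n))
    }
  }
  n_tot <- length(pred)
  per <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- n_tot - tp - fp - fn
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (!is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else if (is.na(sens)) NA_real_ else 0
    c(support = tp + fn, sens = sens, spec = spec, f1 = f1)
  })
  per <- do.call(rbind, per)
  w <- per[, "support"] / n_tot
  ok <- per[, "support"] > 0
  c(sensitivity = sum(w[ok] * per[ok, "sens"]),
    specificity = sum(w[ok] * per[ok, "spec"]),
    f1 = sum(w[ok] * per[ok, "f1"]))
}

# Synthetic evaluated cohort with known per-image accuracy: each slice is
# correct with probability `acc`, independent across slices.
known_accuracy_cohort <- function(n_studies, n_slices, classes, acc) {
  lapply(seq_len(n_studies), function(s) {
    truth <- sample(classes, n_slices, replace = TRUE)
    pred <- truth
    wrong <- runif(n_slices) >= acc
    if (any(wrong))
      pred[wrong] <- vapply(truth[wrong], function(tr)
        sample(setdiff(classes, tr), 1), "")
    list(data.frame(z = seq(2.5, by = 5, length.out = n_slices),
                    pred = pred, truth = truth, stringsAsFactors = FALSE))
  })
}
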