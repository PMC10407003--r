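# End-to-end orchestration: simulate -> filter -> annotate -> split ->
# train -> predict -> post-process -> evaluate.

#' End-to-end run configuration
#'
#' A single global seed fans out to per-stage seeds through [derive_seed()],
#' so each stage is individually reproducible. Sub-configurations carry
#' their own invariants.
#'
#' @param modality `"CT"` or `"MRI"`.
#' @param n_patients cohort size (one study per patient).
#' @param regions_per_study regions per phantom study.
#' @param extent_mm per-region extent (mm).
#' @param slice_spacing_mm slice spacing (mm).
#' @param noise_sd phantom noise (stored intensity units).
#' @param transition_zone_mm blended boundary-zone width (mm).
#' @param image_size phantom slice side (pixels).
#' @param n_series axial series per study.
#' @param train_fraction patient fraction used for training.
#' @param train training settings, a [train_config()] (its `seed` is
#'   overridden by the derived stage seed).
#' @param postprocess a [postprocess_config()].
#' @param bootstrap a [bootstrap_config()] (seed overridden), or `NULL` to
#'   skip CI computation.
#' @param seed global seed.
#' @param out_dir optional directory for artifacts (config snapshot,
#'   reports).
#' @export
run_config <- function(modality = "MRI", n_patients = 200L,
                       regions_per_study = 3L, extent_mm = 40,
                       slice_spacing_mm = 5, noise_sd = 250,
                       transition_zone_mm = 10, image_size = 64L,
                       n_series = 1L, train_fraction = 0.75,
                       train = train_config(),
                       postprocess = postprocess_config(),
                       bootstrap = bootstrap_config(n_iterations = 200L),
                       seed = 1L, out_dir = NULL) {
  structure(list(modality = modality, n_patients = as.integer(n_patients),
                 regions_per_study = as.integer(regions_per_study),
                 extent_mm = extent_mm, slice_spacing_mm = slice_spacing_mm,
                 noise_sd = noise_sd,
                 transition_zone_mm = transition_zone_mm,
                 image_size = as.integer(image_size),
                 n_series = as.integer(n_series),
                 train_fraction = train_fraction, train = train,
                 postprocess = postprocess, bootstrap = bootstrap,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort_br("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Derive per-study region sets from post-processed predictions
#'
#' The study-level region set is the union over the study's series of the
#' classes covering at least one (non-indeterminate) image.
#'
#' @param study_predictions named list: study id -> list of
#'   [prediction_sequence()] (one per series).
#' @return named list of character vectors.
#' @export
derive_study_regions <- function(study_predictions) {
  lapply(study_predictions, function(series_preds) {
    if (inherits(series_preds, "prediction_sequence"))
      series_preds <- list(series_preds)
    sort(unique(unlist(lapply(series_preds, function(ps)
      ps$labels[!ps$indeterminate]))))
  })
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a seeded phantom cohort, applies the series- and image-level
#' filters, derives ground truth by propagating the generator's bounding
#' boxes and resolving candidate labels, splits patients into
#' train/validation (stratified by region), trains the compact classifier
#' on the training slices (transitional-class labels included), predicts
#' and post-processes every held-out series, and evaluates weighted metrics
#' with spatially aware bootstrap CIs.
#'
#' @param cfg a [run_config()].
#' @return list of class `pipeline_report`: `metrics` (`metric_report`),
#'   `confusion` (`confusion_matrix`), `bootstrap` (`bootstrap_report` or
#'   `NULL`), `study_regions`, `n_indeterminate`, `n_unlabeled`, `model`,
#'   `partition`, and the resolved `config`.
#' @export
run_end_to_end <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  vocab <- build_vocabulary(cfg$modality)

  cohort <- .stage("simulate", generate_cohort(
    cfg$n_patients, modality = cfg$modality,
    regions_per_study = cfg$regions_per_study,
    seed = derive_seed(cfg$seed, "simulate"),
    extent_mm = cfg$extent_mm, slice_spacing_mm = cfg$slice_spacing_mm,
    noise_sd = cfg$noise_sd, transition_zone_mm = cfg$transition_zone_mm,
    image_size = cfg$image_size, n_series = cfg$n_series))

  cohort <- .stage("filter", lapply(cohort, function(ps) {
    ps$study <- filter_images(filter_series(ps$study)$study)$study
    ps
  }))

  # ground truth from box propagation (the annotation machinery), not the
  # generator's shortcut labels
  precedence <- default_precedence(vocab)
  truth_by_sop <- .stage("annotate", {
    out <- list()
    for (ps in cohort) {
      cand <- propagate(ps$boxes, ps$study)
      out <- c(out, as.list(resolve_labels(cand, precedence)))
    }
    unlist(out)
  })

  plan <- .stage("split", split_patients(
    data.frame(
      patient_id = vapply(cohort, function(ps) ps$study$patient_id, ""),
      region = vapply(cohort, function(ps) ps$spec$regions[1], ""),
      stringsAsFactors = FALSE),
    fraction = cfg$train_fraction, seed = derive_seed(cfg$seed, "split")))

  is_train <- vapply(cohort, function(ps)
    ps$study$patient_id %in% plan$train, TRUE)

  train_images <- list(); train_labels <- character(0)
  for (ps in cohort[is_train]) {
    lab <- setNames(ps$train_labels$region, ps$train_labels$sop_uid)
    for (im in study_images(ps$study)) {
      train_images[[length(train_images) + 1L]] <- im$pixels
      train_labels <- c(train_labels, lab[[im$sop_uid]])
    }
  }

  tr_cfg <- cfg$train
  tr_cfg$seed <- derive_seed(cfg$seed, "train")
  model <- .stage("train",
                  train_classifier(train_images, train_labels, vocab, tr_cfg))

  test_cohort <- cohort[!is_train]
  study_preds <- .stage("infer", {
    out <- list()
    for (ps in test_cohort) {
      out[[ps$study$study_uid]] <- lapply(ps$study$series, function(s)
        postprocess_sequence(predict_series(model, s), cfg$postprocess))
    }
    out
  })

  eval_units <- list()  # study -> series -> data.frame(z, pred, truth)
  n_ind <- 0L; n_unl <- 0L
  for (uid in names(study_preds)) {
    series_dfs <- list()
    for (ps_seq in study_preds[[uid]]) {
      truth <- unname(truth_by_sop[ps_seq$sop_uids])
      keep <- !ps_seq$indeterminate & !is.na(truth)
      n_ind <- n_ind + sum(ps_seq$indeterminate)
      n_unl <- n_unl + sum(is.na(truth))
      if (any(keep))
        series_dfs[[length(series_dfs) + 1L]] <- data.frame(
          z = ps_seq$z[keep], pred = ps_seq$labels[keep],
          truth = truth[keep], stringsAsFactors = FALSE)
    }
    if (length(series_dfs)) eval_units[[uid]] <- series_dfs
  }

  report <- .stage("evaluate", {
    if (!length(eval_units))
      abort_br(paste0("no evaluable test images (every slice indeterminate ",
                      "or unlabeled); train longer or lower the threshold"))
    all_df <- do.call(rbind, unlist(eval_units, recursive = FALSE))
    cm <- accumulate_confusion(all_df$pred, all_df$truth,
                               vocab$output_classes)
    metrics <- suppressWarnings(compute_metrics(cm))
    boot <- NULL
    if (!is.null(cfg$bootstrap)) {
      bcfg <- cfg$bootstrap
      bcfg$seed <- derive_seed(cfg$seed, "bootstrap")
      boot <- bootstrap_ci(eval_units, vocab$output_classes, bcfg)
    }
    list(cm = cm, metrics = metrics, boot = boot)
  })

  out <- structure(list(
    metrics = report$metrics, confusion = report$cm,
    bootstrap = report$boot,
    study_regions = derive_study_regions(study_preds),
    n_indeterminate = n_ind, n_unlabeled = n_unl,
    n_test_studies = length(test_cohort), model = model, partition = plan,
    config = cfg), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    snapshot <- cfg
    snapshot$train$augmentation <- unclass(snapshot$train$augmentation)
    jsonlite::write_json(
      list(version = as.character(utils::packageVersion("bodyregions")),
           config = lapply(unclass(snapshot), function(x)
             if (is.list(x)) unclass(x) else x)),
      file.path(cfg$out_dir, "run_config.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
    write_evaluation_report(report$cm, report$metrics, cfg$out_dir,
                            report$boot)
    save_checkpoint(model, file.path(cfg$out_dir, "checkpoint"))
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  w <- x$metrics$weighted * 100
  cat(sprintf(paste0("<pipeline_report> %s: %d test studies, %d images ",
                     "evaluated\n  weighted sensitivity %.1f%%, F1 %.1f%%, ",
                     "specificity %.1f%%\n"),
              x$config$modality, x$n_test_studies, x$metrics$n,
              w["sensitivity"], w["f1"], w["specificity"]))
  if (!is.null(x$bootstrap)) {
    ci <- x$bootstrap$ci * 100
    cat(sprintf("  95%% CI sensitivity (%.1f-%.1f)\n",
                ci["sensitivity", "low"], ci["sensitivity", "high"]))
  }
  cat(sprintf("  indeterminate slices: %d\n", x$n_indeterminate))
  invisible(x)
}
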