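# Metrics, confusion matrices, spatially aware bootstrap confidence
# intervals, confounder association statistics and the DICOM-tag audit.

#' Accumulate a confusion matrix
#'
#' Rows are predictions, columns are ground truth, class order comes from
#' the vocabulary's output classes. Indeterminate (below-threshold) images
#' are excluded; every other image increments one cell.
#'
#' @param predicted,truth character vectors of equal length.
#' @param classes class order (rows and columns).
#' @param indeterminate logical vector; flagged entries are skipped.
#' @return integer matrix of class `confusion_matrix`.
#' @export
accumulate_confusion <- function(predicted, truth, classes,
                                 indeterminate = rep(FALSE,
                                                     length(predicted))) {
  stopifnot(length(predicted) == length(truth))
  keep <- !indeterminate
  predicted <- predicted[keep]; truth <- truth[keep]
  bad <- setdiff(unique(c(predicted, truth)), classes)
  if (length(bad))
    abort_br("label(s) outside vocabulary: %s", paste(bad, collapse = ", "))
  cm <- table(factor(predicted, levels = classes),
              factor(truth, levels = classes))
  structure(unclass(cm), class = "confusion_matrix",
            dimnames = list(predicted = classes, truth = classes))
}

#' Per-class and support-weighted classification metrics
#'
#' One-vs-rest per class: sensitivity (recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and `F1 = 2PR/(P+R)`. Weighted
#' aggregates average per-class values with weights proportional to
#' true-class support; classes with no ground-truth images have undefined
#' sensitivity/F1 and are excluded from the weighting with a warning.
#' Weighted sensitivity equals micro-averaged accuracy when every image is
#' evaluated.
#'
#' @param cm a `confusion_matrix` (rows predictions, columns truth).
#' @return list of class `metric_report` with `per_class` (`data.frame`)
#'   and `weighted` (named vector: f1, sensitivity, specificity).
#' @export
compute_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) abort_br("confusion matrix is empty")
  support <- colSums(cm)
  tp <- diag(cm)
  fn <- support - tp
  fp <- rowSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(support > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse((tn + fp) > 0, tn / (tn + fp), NA_real_)
  prec <- ifelse((tp + fp) > 0, tp / (tp + fp), 0)
  f1 <- ifelse(!is.na(sens) & (prec + sens) > 0,
               2 * prec * sens / (prec + sens), ifelse(is.na(sens), NA, 0))
  if (any(support == 0))
    warning(sprintf("%d class(es) have no ground-truth images; excluded %s",
                    sum(support == 0), "from weighting"), call. = FALSE)
  w <- support / total
  wavg <- function(x) sum(w[support > 0] * x[support > 0])
  structure(list(
    per_class = data.frame(
      class = colnames(cm), support = as.integer(support),
      sensitivity = sens, specificity = spec, f1 = f1,
      row.names = NULL, stringsAsFactors = FALSE),
    weighted = c(f1 = wavg(f1), sensitivity = wavg(sens),
                 specificity = wavg(spec)),
    n = total), class = "metric_report")
}

#' Bootstrap configuration for the spatially aware resampling
#'
#' @param n_iterations bootstrap iterations (default 1000; at least 10).
#' @param min_spacing_mm minimum physical spacing between sampled slices
#'   (default 10 mm).
#' @param ci_level confidence level for the percentile interval.
#' @param seed seed for all resampling randomness.
#' @export
bootstrap_config <- function(n_iterations = 1000L, min_spacing_mm = 10,
                             ci_level = 0.95, seed = 1L) {
  stopifnot(min_spacing_mm > 0, ci_level > 0, ci_level < 1)
  if (n_iterations < 10) abort_br("n_iterations must be at least 10")
  structure(list(n_iterations = as.integer(n_iterations),
                 min_spacing_mm = min_spacing_mm, ci_level = ci_level,
                 seed = as.integer(seed)), class = "bootstrap_config")
}

#' Spatially aware slice subsampling
#'
#' Greedy scan over a series sorted by slice position: starting from a
#' randomly offset first slice (uniform within the first `min_spacing_mm`
#' window), a slice is kept only if its z is at least `min_spacing_mm` from
#' the last kept slice. All pairwise distances between kept slices are
#' therefore at least the minimum spacing. This removes the strong
#' correlation between physically adjacent slices before metrics are
#' accumulated.
#'
#' @param z sorted numeric slice positions (mm).
#' @param min_spacing_mm minimum spacing.
#' @param random_start if `TRUE`, the scan starts at a random slice within
#'   the first spacing window (uses the current RNG stream); if `FALSE` at
#'   the first slice.
#' @return integer indices of kept slices.
#' @export
spatial_sample <- function(z, min_spacing_mm = 10, random_start = FALSE) {
  n <- length(z)
  if (n == 0) return(integer())
  if (is.unsorted(z)) abort_br("z must be sorted ascending")
  start <- 1L
  if (random_start) {
    window <- which(z < z[1] + min_spacing_mm)
    start <- if (length(window) > 1) sample(window, 1L) else 1L
  }
  keep <- start
  last <- z[start]
  i <- start + 1L
  while (i <= n) {
    if (z[i] - last >= min_spacing_mm) {
      keep <- c(keep, i)
      last <- z[i]
    }
    i <- i + 1L
  }
  keep
}

#' Spatially aware bootstrap confidence intervals for weighted metrics
#'
#' Each iteration resamples studies with replacement, selects one series per
#' study at random (reducing inter-series correlation), subsamples each
#' selected series with [spatial_sample()] (random start offset each
#' iteration), accumulates a confusion matrix and records the weighted
#' metrics. The CI is the percentile interval over iterations. Fully seeded
#' and deterministic given the seed.
#'
#' @param cohort list of evaluated studies; each study is a list of series,
#'   each series a `data.frame` with columns `z` (sorted ascending), `pred`,
#'   `truth` (indeterminate slices already removed).
#' @param classes vocabulary class order.
#' @param cfg a [bootstrap_config()].
#' @return list of class `bootstrap_report`: `point` (weighted metrics on
#'   the full cohort), `ci` (matrix with rows f1/sensitivity/specificity,
#'   columns low/high), `iterations` (per-iteration weighted metrics).
#' @export
bootstrap_ci <- function(cohort, classes, cfg = bootstrap_config()) {
  stopifnot(length(cohort) > 0, inherits(cfg, "bootstrap_config"))
  all_df <- do.call(rbind, unlist(cohort, recursive = FALSE))
  point <- suppressWarnings(compute_metrics(
    accumulate_confusion(all_df$pred, all_df$truth, classes)))$weighted

  iter_metrics <- with_seed(cfg$seed, {
    t(vapply(seq_len(cfg$n_iterations), function(it) {
      studies <- sample(length(cohort), replace = TRUE)
      pred <- character(0); truth <- character(0)
      for (si in studies) {
        series_list <- cohort[[si]]
        df <- series_list[[sample.int(length(series_list), 1L)]]
        keep <- spatial_sample(df$z, cfg$min_spacing_mm,
                               random_start = TRUE)
        pred <- c(pred, df$pred[keep])
        truth <- c(truth, df$truth[keep])
      }
      cm <- accumulate_confusion(pred, truth, classes)
      suppressWarnings(compute_metrics(cm))$weighted
    }, c(f1 = 0, sensitivity = 0, specificity = 0)))
  })

  a <- (1 - cfg$ci_level) / 2
  ci <- t(apply(iter_metrics, 2, quantile, probs = c(a, 1 - a),
                na.rm = TRUE, names = FALSE))
  colnames(ci) <- c("low", "high")
  structure(list(point = point, ci = ci, iterations = iter_metrics,
                 config = cfg), class = "bootstrap_report")
}

#' Association between correctness and a confounding factor
#'
#' Builds the correct/incorrect x factor-level contingency table, applies
#' Pearson's chi-squared test (no continuity correction) and reports
#' Cramer's V `sqrt(chi2 / (n * (min(r, c) - 1)))`.
#'
#' @param correct logical vector of per-image correctness flags.
#' @param factor_levels factor (or character) of the same length.
#' @param name factor name carried into the result.
#' @return list of class `association_result`: `factor`, `cramers_v`,
#'   `chi2`, `p_value`, `table`.
#' @export
association <- function(correct, factor_levels, name = "factor") {
  stopifnot(length(correct) == length(factor_levels))
  tab <- table(correct = factor(correct, levels = c(FALSE, TRUE)),
               level = factor_levels)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (ncol(tab) < 2 || nrow(tab) < 2)
    abort_br("association needs at least 2 levels and both outcomes")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(as.numeric(ct$statistic) /
              (n * (min(dim(tab)) - 1)))
  structure(list(factor = name, cramers_v = v,
                 chi2 = as.numeric(ct$statistic),
                 p_value = ct$p.value, table = tab),
            class = "association_result")
}

#' Audit body-region DICOM tags against ground truth
#'
#' Free-text tag values (e.g. BodyPartExamined) are mapped to vocabulary
#' regions through a configurable dictionary; a study counts as accurate iff
#' its mapped region is among the study's ground-truth regions. Unmapped or
#' empty values count as inaccurate.
#'
#' @param tag_values named character vector: study id -> raw tag value.
#' @param truth_regions named list: study id -> character vector of
#'   ground-truth regions present in the study.
#' @param tag_map named character vector mapping uppercase tag text to
#'   vocabulary regions (e.g. `c(CHEST = "chest")`).
#' @return list with `accuracy` (percent, one decimal), `n_studies`,
#'   `n_accurate`.
#' @export
audit_dicom_tags <- function(tag_values, truth_regions, tag_map) {
  ids <- names(tag_values)
  stopifnot(!is.null(ids), all(ids %in% names(truth_regions)))
  ok <- vapply(ids, function(id) {
    v <- toupper(trimws(tag_values[[id]]))
    if (is.na(v) || !nzchar(v) || !v %in% names(tag_map)) return(FALSE)
    tag_map[[v]] %in% truth_regions[[id]]
  }, TRUE)
  list(accuracy = round1(100 * mean(ok)), n_studies = length(ids),
       n_accurate = sum(ok))
}

#' Write an evaluation report to disk
#'
#' Emits the confusion matrix and per-class metrics as CSV plus a JSON
#' summary (weighted metrics, CIs).
#'
#' @param cm a `confusion_matrix`.
#' @param metrics a `metric_report`.
#' @param dir output directory (created).
#' @param boot optional `bootstrap_report`.
#' @export
write_evaluation_report <- function(cm, metrics, dir, boot = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame.matrix(unclass(cm)),
            file.path(dir, "confusion_matrix.csv"))
  write.csv(metrics$per_class, file.path(dir, "per_class_metrics.csv"),
            row.names = FALSE)
  summary <- list(weighted = as.list(metrics$weighted), n = metrics$n)
  if (!is.null(boot))
    summary$ci <- list(
      f1 = as.numeric(boot$ci["f1", ]),
      sensitivity = as.numeric(boot$ci["sensitivity", ]),
      specificity = as.numeric(boot$ci["specificity", ]))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
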