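# Patient-stratified partitioning and the survey sample-size model.

#' Patient-stratified train/validation split
#'
#' For each body region, the region's patients are shuffled (seeded) and
#' split at `floor(fraction * n)` into training vs validation, so that no
#' patient appears in both partitions. A patient whose studies span several
#' regions is assigned once, under their first-listed region.
#'
#' @param cohort `data.frame` with columns `patient_id` and `region` (one
#'   row per study; a patient may appear several times).
#' @param fraction training fraction in (0, 1), default 0.75.
#' @param seed shuffle seed.
#' @return list of class `partition_plan`: `train` and `validation`
#'   character vectors of patient ids (disjoint, union = cohort).
#' @export
split_patients <- function(cohort, fraction = 0.75, seed = 1L) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0,
            all(c("patient_id", "region") %in% names(cohort)))
  if (fraction <= 0 || fraction >= 1)
    abort_br("fraction must be in (0, 1)")
  first <- cohort[!duplicated(cohort$patient_id), ]
  train <- character(0); validation <- character(0)
  with_seed(seed, {
    for (rg in unique(first$region)) {
      pats <- sample(first$patient_id[first$region == rg])
      n_tr <- floor(fraction * length(pats))
      train <- c(train, pats[seq_len(n_tr)])
      validation <- c(validation, setdiff(pats, pats[seq_len(n_tr)]))
    }
  })
  structure(list(train = train, validation = validation,
                 fraction = fraction, seed = seed),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> train %d / validation %d patients\n",
              length(x$train), length(x$validation)))
  invisible(x)
}

#' Write a partition plan as CSV
#'
#' @param plan a `partition_plan`.
#' @param path output CSV (columns `patient_id`, `partition`).
#' @export
write_partition_csv <- function(plan, path) {
  write.csv(data.frame(
    patient_id = c(plan$train, plan$validation),
    partition = rep(c("train", "validation"),
                    c(length(plan$train), length(plan$validation)))),
    path, row.names = FALSE)
  invisible(path)
}

#' Required test-set size under a survey sampling model
#'
#' For an expected accuracy `p`, confidence level `z` and relative error
#' `r`, the number of independent samples is
#' `ceil(z^2 * (1 - p) / (r^2 * p))`; the returned image count multiplies
#' this by a design effect (images per effective independent sample, >= 1)
#' to account for intra-series correlation. With p = 0.90, z = 1.96 and
#' r = 0.10 the independent sample size is 43.
#'
#' @param expected_accuracy `p` in (0, 1), default 0.90.
#' @param z normal quantile for the CI level, default 1.96 (95%).
#' @param relative_error `r` > 0, default 0.10.
#' @param design_effect images per independent sample, default 1.
#' @return integer number of images per body region.
#' @export
required_images <- function(expected_accuracy = 0.90, z = 1.96,
                            relative_error = 0.10, design_effect = 1) {
  p <- expected_accuracy
  stopifnot(p > 0, p < 1, relative_error > 0, design_effect >= 1)
  n_ind <- ceiling(z^2 * (1 - p) / (relative_error^2 * p))
  as.integer(n_ind * design_effect)
}
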