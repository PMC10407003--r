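test_that("confusion accumulation indexes [predicted, truth] and honors flags", {
  cls <- c("head", "neck", "chest")
  cm <- accumulate_confusion(c("head", "head", "neck"),
                             c("head", "neck", "neck"), cls)
  expect_equal(sum(cm), 3)
  expect_equal(cm["head", "head"], 1)
  expect_equal(cm["head", "neck"], 1)   # rows are predictions
  expect_equal(cm["neck", "neck"], 1)
  # perfect predictions -> diagonal
  p <- sample(cls, 30, replace = TRUE)
  expect_equal(sum(diag(accumulate_confusion(p, p, cls))), 30)
  # all-indeterminate -> zero matrix
  cm0 <- accumulate_confusion(p, p, cls, indeterminate = rep(TRUE, 30))
  expect_equal(sum(cm0), 0)
  expect_error(accumulate_confusion("skull", "head", cls), "outside")
})

test_that("hand-checked metrics: 2x2 with equal supports", {
  cm <- accumulate_confusion(
    c(rep("A", 8), rep("B", 2), rep("A", 1), rep("B", 9)),
    c(rep("A", 10), rep("B", 10)), c("A", "B"))
  expect_equal(unname(cm), matrix(c(8, 2, 1, 9), 2))
  m <- compute_metrics(cm)
  expect_equal(m$per_class$sensitivity, c(0.8, 0.9))
  expect_equal(unname(m$weighted["sensitivity"]), 0.85)
  # diagonal matrix: all metrics 1
  d <- accumulate_confusion(rep(c("A", "B"), 5), rep(c("A", "B"), 5),
                            c("A", "B"))
  expect_equal(unname(compute_metrics(d)$weighted),
               c(1, 1, 1))
  # one class entirely misclassified -> its sensitivity is 0
  w <- accumulate_confusion(rep("A", 4), rep("B", 4), c("A", "B"))
  mw <- suppressWarnings(compute_metrics(w))
  expect_equal(mw$per_class$sensitivity[mw$per_class$class == "B"], 0)
})

test_that("an empty truth class is excluded from weighting with a warning", {
  cm <- accumulate_confusion(c("A", "B"), c("A", "A"), c("A", "B"))
  expect_warning(m <- compute_metrics(cm), "no ground-truth")
  expect_equal(unname(m$weighted["sensitivity"]), 0.5)
})

test_that("weighted sensitivity equals micro accuracy when all images count", {
  withr::local_seed(99)
  for (i in 1:20) {
    cls <- LETTERS[1:sample(2:6, 1)]
    pred <- sample(cls, 200, replace = TRUE)
    truth <- sample(cls, 200, replace = TRUE)
    m <- suppressWarnings(
      compute_metrics(accumulate_confusion(pred, truth, cls)))
    expect_equal(unname(m$weighted["sensitivity"]), mean(pred == truth))
  }
})

test_that("spatial sampling enforces the minimum spacing greedily", {
  expect_equal(spatial_sample(c(0, 5, 10, 15, 20), 10), c(1, 3, 5))
  expect_equal(spatial_sample(seq(0, 60, by = 12), 10), 1:6)  # all kept
  expect_equal(spatial_sample(42, 10), 1L)                    # single slice
  expect_error(spatial_sample(c(5, 1), 10), "sorted")
  # property: pairwise spacing >= threshold over random series
  withr::local_seed(7)
  for (i in 1:50) {
    z <- sort(runif(sample(2:40, 1), 0, 300))
    kept <- z[spatial_sample(z, 10, random_start = TRUE)]
    if (length(kept) > 1) expect_gte(min(diff(kept)), 10)
  }
})

test_that("bootstrap CIs are seeded, collapse for perfect classifiers and tighten with n", {
  cls <- c("head", "neck", "chest")
  perfect <- withr::with_seed(1, known_accuracy_cohort(15, 12, cls, 1.0))
  cfg <- bootstrap_config(n_iterations = 50, seed = 3)
  b <- bootstrap_ci(perfect, cls, cfg)
  expect_equal(unname(b$ci["sensitivity", ]), c(1, 1))
  b2 <- bootstrap_ci(perfect, cls, cfg)
  expect_identical(b$ci, b2$ci)
  expect_error(bootstrap_config(n_iterations = 5), "at least 10")
  # CI width shrinks as the cohort grows
  small <- withr::with_seed(2, known_accuracy_cohort(10, 12, cls, 0.9))
  large <- withr::with_seed(2, known_accuracy_cohort(160, 12, cls, 0.9))
  w_small <- diff(bootstrap_ci(small, cls, cfg)$ci["sensitivity", ])
  w_large <- diff(bootstrap_ci(large, cls, cfg)$ci["sensitivity", ])
  expect_lt(w_large, w_small)
})

test_that("association reproduces exact and null Cramer's V", {
  # perfectly associated 2x2 table
  r <- association(rep(c(TRUE, FALSE), each = 10),
                   rep(c("a", "b"), each = 10))
  expect_equal(r$cramers_v, 1.0)
  # exactly proportional -> chi2 = 0, V = 0
  r0 <- association(rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 60, 20)),
                    rep(c("a", "a", "b", "b"), c(30, 10, 60, 20)))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$cramers_v, 0)
  expect_error(association(c(TRUE, FALSE), c("a", "a")), "2 levels")
  expect_error(association(c(TRUE, TRUE), c("a", "b")), "2 levels")
})

test_that("chi-squared matches a brute-force oracle on random 2x2 tables", {
  withr::local_seed(31)
  for (i in 1:25) {
    tab <- matrix(sample(5:40, 4), 2)
    correct <- rep(rep(c(FALSE, TRUE), 2), as.vector(tab))
    lev <- rep(rep(c("x", "y"), each = 2), as.vector(tab))
    r <- association(correct, lev)
    # oracle: sum (O - E)^2 / E from the definition
    n <- sum(tab)
    E <- outer(rowSums(tab), colSums(tab)) / n
    chi2 <- sum((tab - E)^2 / E)
    expect_equal(r$chi2, chi2, tolerance = 1e-12)
    expect_equal(r$cramers_v, sqrt(chi2 / n), tolerance = 1e-12)
  }
})

test_that("DICOM tag audit counts mapped membership at the study level", {
  truth <- list(s1 = c("chest", "abdomen"), s2 = "head", s3 = "knee",
                s4 = "foot")
  tags <- c(s1 = "CHEST", s2 = "BRAIN", s3 = "", s4 = "ANKLE")
  map <- c(CHEST = "chest", BRAIN = "head", KNEE = "knee")
  r <- audit_dicom_tags(tags, truth, map)
  # s1 member, s2 mapped+match, s3 empty, s4 unmapped -> 2/4
  expect_equal(r$accuracy, 50.0)
  r2 <- audit_dicom_tags(tags[1:3], truth, map)
  expect_equal(r2$n_accurate, 2)
  expect_equal(audit_dicom_tags(c(s2 = "BRAIN", s3 = "KNEE", s1 = "CHEST",
                                  s4 = "X"), truth, map)$accuracy, 75.0)
})

test_that("evaluation reports serialize to CSV and JSON", {
  cls <- c("A", "B")
  cm <- accumulate_confusion(c("A", "A", "B"), c("A", "B", "B"), cls)
  m <- compute_metrics(cm)
  dir <- withr::local_tempdir()
  write_evaluation_report(cm, m, dir)
  expect_true(file.exists(file.path(dir, "confusion_matrix.csv")))
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(js$weighted$sensitivity,
               unname(m$weighted["sensitivity"]))
})
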