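classes_ct <- build_vocabulary("CT")$internal_classes
classes_mri <- build_vocabulary("MRI")$internal_classes

test_that("prediction sequences validate and sort their entries", {
  sq <- seq_from_labels(c("head", "neck"), classes_ct, z = c(20, 10))
  expect_equal(sq$z, c(10, 20))
  expect_identical(sq$labels, c("neck", "head"))
  bad <- matrix(0.3, 2, length(classes_ct),
                dimnames = list(NULL, classes_ct))
  expect_error(prediction_sequence(z = c(1, 2), probs = bad,
                                   classes = classes_ct), "sum to 1")
})

test_that("transitional class merges to the predominant cavity", {
  sq <- seq_from_labels(c(rep("chest", 5), rep("abdomen_chest", 2),
                          rep("abdomen", 3)), classes_ct)
  out <- merge_abdomen_chest(sq)
  expect_false(any(out$labels == "abdomen_chest"))
  expect_equal(sum(out$labels == "chest"), 7)  # chest predominant (5 > 3)
  # absence of both cavities -> abdomen fallback
  only <- merge_abdomen_chest(seq_from_labels(rep("abdomen_chest", 4),
                                              classes_ct))
  expect_true(all(only$labels == "abdomen"))
  # tie -> abdomen (declared tie-break, by analogy with the fallback)
  tie <- merge_abdomen_chest(seq_from_labels(
    c("chest", "chest", "abdomen", "abdomen", "abdomen_chest"), classes_ct))
  expect_equal(tie$labels[5], "abdomen")
  # probability mass follows the relabel so smoothing cannot reintroduce it
  relabeled <- which(sq$labels == "abdomen_chest")
  expect_true(all(out$probs[relabeled, "abdomen_chest"] == 0))
})

test_that("breast series rule triggers at exactly 50% and only on MRI", {
  mk <- function(n_breast, n_other, modality = "MRI")
    seq_from_labels(c(rep("breast", n_breast), rep("chest", n_other)),
                    classes_mri, modality = modality)
  expect_true(all(breast_series_rule(mk(6, 4))$labels == "breast"))
  expect_true(all(breast_series_rule(mk(5, 5))$labels == "breast"))  # >= 50%
  out <- breast_series_rule(mk(4, 6))
  expect_equal(sum(out$labels == "breast"), 4)                        # unchanged
  ct <- breast_series_rule(mk(6, 4, modality = "CT"))
  expect_equal(sum(ct$labels == "breast"), 6)                         # no-op
})

test_that("isolated outlier labels are replaced to a fixed point", {
  run <- function(labels)
    remove_outliers(seq_from_labels(labels, classes_ct))$labels
  expect_equal(run(c("head", "head", "neck", "head", "head")),
               rep("head", 5))
  expect_equal(run(c("head", "neck", "neck", "head")),
               c("head", "neck", "neck", "head"))  # run of 2 untouched
  expect_equal(run(c("head", "neck", "head", "neck", "head")),
               rep("head", 5))                      # fixed-point iteration
  expect_equal(run(c("neck", "head", "head")), c("neck", "head", "head"))
  expect_equal(run("head"), "head")
})

test_that("probability smoothing fixes single flips and keeps constants", {
  const <- seq_from_labels(rep("chest", 6), classes_ct, conf = 0.8)
  sm <- smooth_sequence(const)
  expect_identical(sm$labels, const$labels)
  expect_equal(sm$probs, const$probs, tolerance = 1e-12)
  # low-confidence flip between confident neighbors is voted away:
  # window average at the flip is (0.9 + 0.4 + 0.9)/3 = 0.733 for chest
  k <- length(classes_ct)
  probs <- matrix((1 - 0.9) / (k - 1), 3, k,
                  dimnames = list(NULL, classes_ct))
  probs[c(1, 3), "chest"] <- 0.9
  probs[2, ] <- (1 - 0.4) / (k - 1); probs[2, "neck"] <- 0.4
  probs <- probs / rowSums(probs)
  sq <- prediction_sequence(z = c(0, 5, 10), probs = probs,
                            classes = classes_ct)
  out <- smooth_sequence(sq)
  expect_identical(out$labels, rep("chest", 3))
  # single-entry sequence unchanged (truncated window)
  single <- seq_from_labels("head", classes_ct)
  expect_equal(smooth_sequence(single)$probs, single$probs)
  # never emits a class with zero probability mass in the window
  two <- matrix(0, 4, k, dimnames = list(NULL, classes_ct))
  two[, "chest"] <- c(1, 0.6, 0.6, 1)
  two[, "abdomen"] <- 1 - two[, "chest"]
  sm2 <- smooth_sequence(prediction_sequence(z = c(0, 5, 10, 15),
                                             probs = two,
                                             classes = classes_ct))
  expect_true(all(sm2$probs[, setdiff(classes_ct,
                                      c("chest", "abdomen"))] == 0))
  expect_true(all(sm2$labels %in% c("chest", "abdomen")))
})

test_that("confidence threshold keeps the boundary and marks the rest", {
  k <- length(classes_ct)
  sq <- seq_from_labels(rep("head", 3), classes_ct, conf = 0.9)
  sq$confidence <- c(0.825, 0.49, 0.5)
  out <- apply_threshold(sq)
  expect_identical(out$indeterminate, c(FALSE, TRUE, FALSE))
})

test_that("the full chain is deterministic and preserves the slice count", {
  labels <- c(rep("chest", 4), "abdomen_chest", rep("abdomen", 4), "neck",
              rep("abdomen", 2))
  sq <- seq_from_labels(labels, classes_ct, conf = 0.7)
  out1 <- postprocess_sequence(sq)
  out2 <- postprocess_sequence(sq)
  expect_identical(out1, out2)
  expect_length(out1$labels, length(labels))
  expect_false(any(out1$labels == "abdomen_chest"))
  # the isolated neck flip inside the abdomen block is gone
  expect_false("neck" %in% out1$labels)
})
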