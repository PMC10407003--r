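test_that("zero-maxima augmentation is the identity and draws are seeded", {
  px <- preprocess_image(matrix(runif(64 * 64, 0, 4000), 64, 64))
  id_cfg <- augmentation_config(rotation_max_rad = 0, translate_max_frac = 0,
                                shear_max_frac = 0, scale_max_frac = 0)
  expect_equal(withr::with_seed(1, augment(px, id_cfg)), px)
  cfg <- augmentation_config()
  a1 <- withr::with_seed(7, augment(px, cfg))
  a2 <- withr::with_seed(7, augment(px, cfg))
  expect_identical(a1, a2)
  expect_false(identical(a1, withr::with_seed(8, augment(px, cfg))))
  # shape and label-free contract: same dimensions, values stay in range
  expect_equal(dim(a1), dim(px))
  expect_true(all(a1 >= -2 - 1e-9 & a1 <= 2 + 1e-9))
})

test_that("deformation samples respect the policy bounds", {
  cfg <- augmentation_config()
  draws <- withr::with_seed(3, replicate(1e4, simplify = FALSE,
    bodyregions:::sample_deformation(cfg, 224)))
  theta <- vapply(draws, `[[`, 0, "theta")
  expect_true(all(abs(theta) <= pi / 10))
  expect_true(all(abs(vapply(draws, `[[`, 0, "tx")) <= 0.10 * 224))
  expect_true(all(abs(vapply(draws, `[[`, 0, "shx")) <= 0.10))
  sx <- vapply(draws, `[[`, 0, "sx")
  expect_true(all(sx >= 0.8 & sx <= 1.2))
  # the bounds are actually exercised
  expect_gt(max(abs(theta)), 0.95 * pi / 10)
})

test_that("invalid augmentation policies are rejected", {
  expect_error(augmentation_config(rotation_max_rad = 4))
  expect_error(augmentation_config(translate_max_frac = 1.5))
  expect_error(train_config(backbone = "resnet50v2_pretrained"),
               "not available")
})

test_that("training learns a separable two-class problem and logs a falling loss", {
  imgs <- list(); labs <- character()
  for (i in 1:6) {
    rg <- if (i %% 2 == 0) "head" else "calf"
    ps <- generate_study(phantom_spec(modality = "CT", regions = rg,
                                      extent_mm = 40, seed = 17 + i,
                                      patient_id = sprintf("P%d", i)))
    for (im in all_images_of(ps$study)) {
      imgs[[length(imgs) + 1L]] <- im$pixels
      labs <- c(labs, rg)
    }
  }
  expect_gte(length(unique(labs)), 2)
  cfg <- train_config(epochs = 5, seed = 5, hidden_units = 16,
                      batch_size = 8, learning_rate = 5e-3)
  m <- train_classifier(imgs, labs, build_vocabulary("CT"), cfg)
  P <- bodyregions:::.predict_images(m, imgs)
  acc <- mean(colnames(P)[max.col(P)] == labs)
  expect_gt(acc, 0.95)
  expect_lt(tail(m$loss_curve, 1), m$loss_curve[1])
  # seeded reproducibility
  m2 <- train_classifier(imgs, labs, build_vocabulary("CT"), cfg)
  expect_equal(m$W2, m2$W2)
})

test_that("degenerate training sets are rejected", {
  v <- build_vocabulary("CT")
  expect_error(train_classifier(list(), character(), v), "empty")
  one <- list(matrix(1:100, 10, 10), matrix(101:200, 10, 10))
  expect_error(train_classifier(one, c("head", "head"), v), "at least 2")
  expect_error(train_classifier(one, c("head", "skull"), v),
               "outside vocabulary")
})

test_that("series prediction is ordered, normalized and deterministic", {
  ps <- generate_study(phantom_spec(modality = "CT",
                                    regions = c("head", "neck"),
                                    extent_mm = 20, seed = 23))
  imgs <- lapply(all_images_of(ps$study), `[[`, "pixels")
  labs <- ps$train_labels$region
  m <- train_classifier(imgs, labs, build_vocabulary("CT"),
                        train_config(epochs = 2, seed = 1,
                                     augmentation = NULL))
  sq <- predict_series(m, ps$study$series[[1]])
  expect_length(sq$z, length(imgs))
  expect_false(is.unsorted(sq$z))
  expect_equal(rowSums(sq$probs), rep(1, length(imgs)), tolerance = 1e-9)
  expect_identical(sq$probs, predict_series(m, ps$study$series[[1]])$probs)
  # empty series -> empty sequence
  empty <- new_series(list(), metadata = list(modality = "CT"))
  sq0 <- predict_series(m, empty)
  expect_length(sq0$z, 0)
})

test_that("uncertainty ranking orders studies by mean (1 - confidence)", {
  classes <- c("head", "neck", "chest")
  mk <- function(conf) seq_from_labels(rep("head", 4), classes, conf = conf)
  preds <- list(sure = mk(0.99), unsure = mk(0.40), mid = mk(0.70))
  expect_identical(rank_uncertain(preds, k = 2), c("unsure", "mid"))
  expect_identical(rank_uncertain(preds, k = 10),
                   c("unsure", "mid", "sure"))
  # permutation invariance
  expect_identical(sort(rank_uncertain(preds, k = 3)),
                   sort(rank_uncertain(rev(preds), k = 3)))
  expect_error(rank_uncertain(preds, k = 0), "positive")
  # hand-sorted scores 0.5 / 0.2 / 0.1 -> top two ids
  p2 <- list(a = mk(0.5), b = mk(0.8), c = mk(0.9))
  expect_identical(rank_uncertain(p2, k = 2), c("a", "b"))
  # entropy alternative ranks uniform above one-hot as well
  expect_identical(rank_uncertain(preds, k = 1, method = "entropy"),
                   "unsure")
})

test_that("checkpoints round-trip weights and predictions", {
  ps <- generate_study(phantom_spec(modality = "CT",
                                    regions = c("head", "neck"),
                                    extent_mm = 15, seed = 31))
  imgs <- lapply(all_images_of(ps$study), `[[`, "pixels")
  m <- train_classifier(imgs, ps$train_labels$region,
                        build_vocabulary("CT"),
                        train_config(epochs = 2, seed = 2,
                                     augmentation = NULL))
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir)
  expect_true(file.exists(file.path(dir, "vocabulary.json")))
  m2 <- load_checkpoint(dir)
  expect_equal(m2$W1, m$W1, tolerance = 1e-12)
  s1 <- predict_series(m, ps$study$series[[1]])
  s2 <- predict_series(m2, ps$study$series[[1]])
  expect_equal(s1$probs, s2$probs, tolerance = 1e-9)
})
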