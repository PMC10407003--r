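# Compact trainable multi-class slice classifier.
#
# The backbone is a compact feed-forward softmax network trained with
# categorical cross-entropy: model inputs (224 x 224 x 3 preprocessed
# tensors) are mean-pooled to a small grid (channels are identical, so one
# channel is pooled), flattened, and passed through one ReLU hidden layer
# into a softmax over the modality's internal classes. Training runs
# mini-batch Adam for a fixed number of epochs, re-drawing the spatial
# augmentation set every epoch. The backbone is deliberately small - the
# pipeline treats the classifier as pluggable and everything upstream and
# downstream of it is backbone-agnostic.

#' Training configuration
#'
#' @param backbone only `"compact"` (pooled feed-forward softmax network) is
#'   provided; the argument exists so checkpoints record which backbone
#'   produced them.
#' @param epochs,batch_size,learning_rate optimizer settings (Adam).
#' @param hidden_units width of the ReLU hidden layer.
#' @param pool_dim side of the mean-pooled feature grid (224 must be a
#'   multiple of it).
#' @param target model input side length (see [preprocess_image()]).
#' @param augmentation an [augmentation_config()], or `NULL` to disable.
#' @param uncertainty `"confidence"` scores a study by mean (1 - max
#'   probability); `"entropy"` by mean normalized entropy.
#' @param seed seed for initialization, shuffling and augmentation.
#' @export
train_config <- function(backbone = "compact", epochs = 10L,
                         batch_size = 32L, learning_rate = 1e-3,
                         hidden_units = 64L, pool_dim = 16L, target = 224L,
                         augmentation = augmentation_config(),
                         uncertainty = c("confidence", "entropy"),
                         seed = 1L) {
  if (!identical(backbone, "compact"))
    abort_br(paste0("backbone '%s' is not available; this package ships ",
                    "the compact pooled network backbone only"), backbone)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            target %% pool_dim == 0)
  structure(list(backbone = backbone, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 hidden_units = as.integer(hidden_units),
                 pool_dim = as.integer(pool_dim), target = as.integer(target),
                 augmentation = augmentation,
                 uncertainty = match.arg(uncertainty),
                 loss = "categorical_crossentropy",
                 seed = as.integer(seed)), class = "train_config")
}

#' Mean-pool a model input to the classifier feature vector
#'
#' The three channels are identical by construction, so channel 1 is pooled
#' over non-overlapping blocks to a `pool_dim x pool_dim` grid and
#' flattened.
#'
#' @param input `target x target x 3` array (or matrix).
#' @param pool_dim feature grid side.
#' @return numeric vector of length `pool_dim^2`.
#' @export
featurize <- function(input, pool_dim = 16L) {
  x <- if (length(dim(input)) == 3) input[, , 1] else input
  n <- nrow(x)
  stopifnot(n %% pool_dim == 0, ncol(x) == n)
  b <- n %/% pool_dim
  a <- array(x, c(b, pool_dim, b, pool_dim))
  as.vector(apply(a, c(2, 4), mean))
}

.softmax <- function(scores) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

.forward <- function(model, X) {
  A1 <- pmax(X %*% model$W1 + rep(model$b1, each = nrow(X)), 0)
  P <- .softmax(A1 %*% model$W2 + rep(model$b2, each = nrow(X)))
  list(A1 = A1, P = P)
}

# normalize(clip(x)) at native resolution; cached small matrices keep the
# training-set memory footprint low, pad_resize happens on the fly.
.normalized_native <- function(pixels) {
  st <- image_stats(pixels)
  normalize_intensities(clip_intensities(pixels, st), st)
}

#' Train the compact slice classifier
#'
#' Trains the pooled feed-forward softmax backbone with categorical
#' cross-entropy on all labeled slices. Every epoch a fresh random subset of
#' images (probability `apply_prob` each) is spatially deformed under the
#' augmentation policy before feature extraction. The per-epoch mean
#' training loss is recorded in the returned handle's `loss_curve`. Training
#' is fully seeded and reproducible.
#'
#' @param images list of raw single-channel pixel matrices.
#' @param labels character vector of slice labels (drawn from the
#'   vocabulary's internal classes; the transitional class is allowed).
#' @param vocabulary a [build_vocabulary()] object.
#' @param cfg a [train_config()].
#' @return an object of class `region_classifier` producing per-slice class
#'   probability vectors; see [predict_series()].
#' @export
train_classifier <- function(images, labels, vocabulary,
                             cfg = train_config()) {
  stopifnot(inherits(vocabulary, "region_vocabulary"),
            inherits(cfg, "train_config"))
  if (!length(images)) abort_br("training dataset is empty")
  if (length(images) != length(labels))
    abort_br("images and labels differ in length")
  classes <- vocabulary$internal_classes
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    abort_br("label(s) outside vocabulary: %s", paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2)
    abort_br("training requires at least 2 classes, got %d",
             length(unique(labels)))

  d <- cfg$pool_dim^2
  K <- length(classes)
  y <- match(labels, classes)
  n <- length(images)

  norm_native <- lapply(images, .normalized_native)
  base_X <- t(vapply(norm_native, function(im)
    featurize(pad_resize(im, cfg$target), cfg$pool_dim), numeric(d)))

  with_seed(cfg$seed, {
    h <- cfg$hidden_units
    model <- list(
      W1 = matrix(rnorm(d * h, sd = sqrt(2 / d)), d, h),
      b1 = numeric(h),
      W2 = matrix(rnorm(h * K, sd = sqrt(2 / h)), h, K),
      b2 = numeric(K))
    adam <- list(m = lapply(model, function(p) p * 0),
                 v = lapply(model, function(p) p * 0), t = 0)
    b1_ <- 0.9; b2_ <- 0.999; eps <- 1e-8
    loss_curve <- numeric(cfg$epochs)

    for (epoch in seq_len(cfg$epochs)) {
      X <- base_X
      if (!is.null(cfg$augmentation) && cfg$augmentation$apply_prob > 0) {
        deform <- runif(n) < cfg$augmentation$apply_prob
        for (i in which(deform)) {
          X[i, ] <- featurize(
            augment(pad_resize(norm_native[[i]], cfg$target),
                    cfg$augmentation),
            cfg$pool_dim)
        }
      }
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- .forward(model, Xb)
        nb <- length(idx)
        losses <- c(losses,
                    -mean(log(pmax(fw$P[cbind(seq_len(nb), yb)], 1e-12))))
        dS <- fw$P
        dS[cbind(seq_len(nb), yb)] <- dS[cbind(seq_len(nb), yb)] - 1
        dS <- dS / nb
        grads <- list(
          W1 = crossprod(Xb, (dS %*% t(model$W2)) * (fw$A1 > 0)),
          b1 = colSums((dS %*% t(model$W2)) * (fw$A1 > 0)),
          W2 = crossprod(fw$A1, dS),
          b2 = colSums(dS))
        adam$t <- adam$t + 1
        for (p in names(model)) {
          adam$m[[p]] <- b1_ * adam$m[[p]] + (1 - b1_) * grads[[p]]
          adam$v[[p]] <- b2_ * adam$v[[p]] + (1 - b2_) * grads[[p]]^2
          mh <- adam$m[[p]] / (1 - b1_^adam$t)
          vh <- adam$v[[p]] / (1 - b2_^adam$t)
          model[[p]] <- model[[p]] - cfg$learning_rate * mh / (sqrt(vh) + eps)
        }
      }
      loss_curve[epoch] <- mean(losses)
    }
  })

  structure(c(model, list(classes = classes, modality = vocabulary$modality,
                          pool_dim = cfg$pool_dim, target = cfg$target,
                          loss_curve = loss_curve, config = cfg)),
            class = "region_classifier")
}

#' @export
print.region_classifier <- function(x, ...) {
  cat(sprintf(
    "<region_classifier> %s, %d classes, %d->%d->%d, final loss %.4f\n",
    x$modality, length(x$classes), nrow(x$W1), ncol(x$W1), ncol(x$W2),
    tail(x$loss_curve, 1)))
  invisible(x)
}

# probability matrix for a list of raw pixel matrices
.predict_images <- function(model, images) {
  if (!length(images))
    return(matrix(0, 0, length(model$classes),
                  dimnames = list(NULL, model$classes)))
  X <- t(vapply(images, function(px)
    featurize(preprocess_image(px, model$target), model$pool_dim),
    numeric(model$pool_dim^2)))
  P <- .forward(model, X)$P
  colnames(P) <- model$classes
  P
}

#' Predict per-slice class probabilities for a series
#'
#' Runs the preprocessing chain and the classifier on every image of the
#' series, in slice-position order. Inference is deterministic.
#'
#' @param model a `region_classifier`.
#' @param series a `region_series` (already filtered).
#' @return a [prediction_sequence()] (empty series give an empty sequence).
#' @export
predict_series <- function(model, series) {
  stopifnot(inherits(model, "region_classifier"),
            inherits(series, "region_series"))
  z <- vapply(series$images, function(im) im$z_position, 0)
  P <- .predict_images(model, lapply(series$images, `[[`, "pixels"))
  prediction_sequence(
    z = z, probs = P, classes = model$classes,
    modality = series$metadata$modality %||% model$modality,
    sop_uids = vapply(series$images, function(im) im$sop_uid, ""))
}

#' Rank studies by prediction uncertainty (active learning)
#'
#' Scores each study by the mean per-image uncertainty (1 - max probability
#' by default, normalized entropy as an alternative) and returns the ids of
#' the `k` most uncertain studies, ties broken by study id. The ranking is
#' invariant to the input order.
#'
#' @param study_predictions named list (study id -> [prediction_sequence()]
#'   or list of them, one per series).
#' @param k number of studies to select (default 200).
#' @param method `"confidence"` or `"entropy"`.
#' @return character vector of `min(k, n)` study ids, most uncertain first.
#' @export
rank_uncertain <- function(study_predictions, k = 200L,
                           method = c("confidence", "entropy")) {
  method <- match.arg(method)
  if (k <= 0) abort_br("k must be positive")
  score_one <- function(ps) {
    if (inherits(ps, "prediction_sequence")) ps <- list(ps)
    probs <- do.call(rbind, lapply(ps, `[[`, "probs"))
    if (!nrow(probs)) abort_br("a study has no predictions")
    if (method == "confidence") {
      mean(1 - apply(probs, 1, max))
    } else {
      p <- pmax(probs, 1e-12)
      mean(-rowSums(p * log(p)) / log(ncol(probs)))
    }
  }
  scores <- vapply(study_predictions, score_one, 0)
  ids <- names(scores) %||% as.character(seq_along(scores))
  ord <- order(-scores, ids)
  head(ids[ord], min(k, length(ids)))
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint directory holds the weights as JSON together with the
#' vocabulary JSON and a preprocessing version tag, so a checkpoint fully
#' pins the input contract it was trained under.
#'
#' @param model a `region_classifier`.
#' @param dir checkpoint directory (created).
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
            classes = model$classes, modality = model$modality,
            pool_dim = model$pool_dim, target = model$target,
            loss_curve = model$loss_curve,
            preprocessing = "clip4sd-norm2sd-3ch-pad224-v1")
  jsonlite::write_json(w, file.path(dir, "weights.json"), digits = NA)
  vocabulary_json(build_vocabulary(model$modality),
                  file.path(dir, "vocabulary.json"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  w <- jsonlite::fromJSON(file.path(dir, "weights.json"))
  structure(list(W1 = as.matrix(w$W1), b1 = as.numeric(w$b1),
                 W2 = as.matrix(w$W2), b2 = as.numeric(w$b2),
                 classes = w$classes, modality = w$modality,
                 pool_dim = w$pool_dim, target = w$target,
                 loss_curve = w$loss_curve),
            class = "region_classifier")
}
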