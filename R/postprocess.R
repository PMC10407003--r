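# Series-level rule engine and smoothing.
#
# Fixed pipeline order: transitional-class merge -> breast-series rule ->
# outlier removal -> moving-average smoothing -> confidence threshold. The
# whole chain is deterministic and never adds or removes entries.

#' Ordered per-slice prediction sequence
#'
#' @param z numeric slice-center positions (mm); entries are stored sorted
#'   ascending by z.
#' @param probs numeric matrix, one row per slice, columns named by class;
#'   each row is a probability vector (sums to 1 within 1e-6).
#' @param classes class names (column order of `probs`).
#' @param modality `"CT"` or `"MRI"`.
#' @param sop_uids optional per-slice identifiers.
#' @return object of class `prediction_sequence` with derived `labels`
#'   (argmax class), `confidence` (max probability) and an `indeterminate`
#'   flag vector (all `FALSE` until [apply_threshold()]).
#' @export
prediction_sequence <- function(z, probs, classes = colnames(probs),
                                modality = "CT", sop_uids = NULL) {
  probs <- matrix(as.numeric(probs), nrow = length(z),
                  ncol = length(classes), dimnames = list(NULL, classes))
  if (nrow(probs) > 0) {
    bad <- abs(rowSums(probs) - 1) > 1e-6
    if (any(bad)) abort_br("probability rows must sum to 1")
  }
  ord <- order(z)
  structure(list(z = z[ord], probs = probs[ord, , drop = FALSE],
                 classes = classes, modality = modality,
                 sop_uids = (sop_uids %||% rep("", length(z)))[ord],
                 labels = .argmax_labels(probs[ord, , drop = FALSE]),
                 confidence = .max_prob(probs[ord, , drop = FALSE]),
                 indeterminate = rep(FALSE, length(z))),
            class = "prediction_sequence")
}

.argmax_labels <- function(probs) {
  if (!nrow(probs)) return(character())
  colnames(probs)[max.col(probs, ties.method = "first")]
}

# Relabel slices `idx` to `target`, moving the probability mass of each
# slice's current argmax class onto the target class. Label-editing rules
# use this so the probability matrix stays consistent with the labels and
# the later probability-space smoothing cannot silently undo a rule.
.relabel_mass <- function(seq, idx, target) {
  for (i in idx) {
    old <- seq$labels[i]
    if (old == target) next
    seq$probs[i, target] <- seq$probs[i, target] + seq$probs[i, old]
    seq$probs[i, old] <- 0
    seq$labels[i] <- target
  }
  seq$confidence <- .max_prob(seq$probs)
  seq
}

.max_prob <- function(probs) {
  if (!nrow(probs)) return(numeric())
  apply(probs, 1, max)
}

#' @export
print.prediction_sequence <- function(x, ...) {
  cat(sprintf("<prediction_sequence> %s, %d slice(s): %s\n", x$modality,
              length(x$z), paste(rle(x$labels)$values, collapse = " | ")))
  invisible(x)
}

#' Post-processing configuration
#'
#' @param breast_fraction_threshold fraction of breast-labeled slices at or
#'   above which the whole series becomes breast (default 0.5, "at least
#'   50%").
#' @param smoothing_window moving-average window in slices (odd, default 3).
#' @param confidence_threshold slices below this confidence are marked
#'   indeterminate (default 0.5; the boundary is kept, read as `>=`).
#' @export
postprocess_config <- function(breast_fraction_threshold = 0.5,
                               smoothing_window = 3L,
                               confidence_threshold = 0.5) {
  stopifnot(breast_fraction_threshold >= 0, breast_fraction_threshold <= 1,
            confidence_threshold >= 0, confidence_threshold <= 1,
            smoothing_window >= 1, smoothing_window %% 2 == 1)
  structure(list(breast_fraction_threshold = breast_fraction_threshold,
                 smoothing_window = as.integer(smoothing_window),
                 confidence_threshold = confidence_threshold),
            class = "postprocess_config")
}

#' Merge the transitional abdomen-chest class at the series level
#'
#' Every slice whose argmax label is the internal `abdomen_chest` class is
#' relabeled to abdomen or chest, whichever is predominant (more argmax
#' slices) in the series; if neither occurs, to abdomen, and a tie also
#' resolves to abdomen (by analogy with that stated fallback). The
#' transitional class's probability mass is folded into the assigned class
#' so later probability-space smoothing cannot reintroduce it.
#'
#' @param seq a [prediction_sequence()] over internal classes.
#' @return the sequence with no `abdomen_chest` labels remaining.
#' @export
merge_abdomen_chest <- function(seq) {
  stopifnot(inherits(seq, "prediction_sequence"))
  if (!"abdomen_chest" %in% colnames(seq$probs)) return(seq)
  is_tr <- seq$labels == "abdomen_chest"
  if (any(is_tr)) {
    n_chest <- sum(seq$labels == "chest")
    n_abd <- sum(seq$labels == "abdomen")
    target <- if (n_chest > n_abd) "chest" else "abdomen"
    seq <- .relabel_mass(seq, which(is_tr), target)
  }
  seq
}

#' Breast-series rule (MRI)
#'
#' If at least the threshold fraction (default 50%) of a series' slices are
#' labeled breast, the whole series is labeled breast; otherwise the series
#' is unchanged. This suppresses spurious non-breast labels inside noisy
#' dedicated breast acquisitions. A no-op for CT.
#'
#' @param seq a [prediction_sequence()].
#' @param cfg a [postprocess_config()].
#' @export
breast_series_rule <- function(seq, cfg = postprocess_config()) {
  stopifnot(inherits(seq, "prediction_sequence"))
  if (seq$modality != "MRI" || !length(seq$labels)) return(seq)
  frac <- mean(seq$labels == "breast")
  if (frac >= cfg$breast_fraction_threshold)
    seq <- .relabel_mass(seq, seq_along(seq$labels), "breast")
  seq
}

#' Remove isolated outlier labels within a series
#'
#' Any interior run of length 1 whose two flanking labels agree is replaced
#' by the flanking label; endpoints are untouched. The rule is repeated to a
#' fixed point (capped at the sequence length), so alternating patterns
#' collapse to their surrounding label.
#'
#' @param seq a [prediction_sequence()].
#' @export
remove_outliers <- function(seq) {
  stopifnot(inherits(seq, "prediction_sequence"))
  n <- length(seq$labels)
  if (n < 3) return(seq)
  for (iter in seq_len(n)) {
    r <- rle(seq$labels)
    changed <- FALSE
    if (length(r$lengths) >= 3) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in 2:(length(r$lengths) - 1L)) {
        if (r$lengths[j] == 1L && r$values[j - 1L] == r$values[j + 1L]) {
          seq <- .relabel_mass(seq, starts[j], r$values[j - 1L])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  seq
}

#' Moving-average smoothing of per-class probabilities
#'
#' A moving average over labels is undefined for categorical data, so the
#' filter averages each class's probability sequence over a centered window
#' (default 3 slices; edge windows truncated), renormalizes each row and
#' re-takes the argmax. A constant sequence is unchanged and smoothing never
#' emits a class with zero probability mass in the window.
#'
#' @param seq a [prediction_sequence()].
#' @param cfg a [postprocess_config()].
#' @export
smooth_sequence <- function(seq, cfg = postprocess_config()) {
  stopifnot(inherits(seq, "prediction_sequence"))
  n <- length(seq$z)
  w <- cfg$smoothing_window
  if (n < 2 || w < 2) return(seq)
  half <- (w - 1L) %/% 2L
  cs <- rbind(0, apply(seq$probs, 2, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1)
  sm <- sm / rowSums(sm)
  colnames(sm) <- colnames(seq$probs)
  seq$probs <- sm
  seq$labels <- .argmax_labels(sm)
  seq$confidence <- .max_prob(sm)
  seq
}

#' Mark low-confidence slices as indeterminate
#'
#' Slices with confidence at or above the threshold are kept; below it they
#' are flagged indeterminate and excluded from confusion-matrix
#' accumulation. The boundary is inclusive: confidence exactly at the
#' threshold is kept.
#'
#' @param seq a [prediction_sequence()].
#' @param cfg a [postprocess_config()].
#' @export
apply_threshold <- function(seq, cfg = postprocess_config()) {
  stopifnot(inherits(seq, "prediction_sequence"))
  seq$indeterminate <- seq$confidence < cfg$confidence_threshold
  seq
}

#' Full series-level post-processing chain
#'
#' Applies, in order: [merge_abdomen_chest()], [breast_series_rule()],
#' [remove_outliers()], [smooth_sequence()], [apply_threshold()].
#'
#' @param seq a [prediction_sequence()].
#' @param cfg a [postprocess_config()].
#' @export
postprocess_sequence <- function(seq, cfg = postprocess_config()) {
  seq <- merge_abdomen_chest(seq)
  seq <- breast_series_rule(seq, cfg)
  seq <- remove_outliers(seq)
  seq <- smooth_sequence(seq, cfg)
  apply_threshold(seq, cfg)
}
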