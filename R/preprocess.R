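# Image-level preprocessing chain feeding the classifier:
# per-image statistics -> intensity clipping -> normalization -> channel
# replication -> aspect-preserving zero-padded resize to 224 x 224.
#
# Normalization maps mean to 0 and mean + 2*sd to +1; with clipping at
# mean +/- 4*sd the post-clip output range is [-2, 2] (not [-1, 1]: the
# stated formulas give (+/-4 sd)/(2 sd) = +/-2; we implement the formulas
# as written and document the range they actually produce). Padding is
# applied after normalization, so the pad value 0 codes mean intensity.

#' Per-image intensity statistics
#'
#' @param pixels numeric matrix of stored values (after any rescale).
#' @return list with `mean` and `sd` (population standard deviation over
#'   all pixels of this image).
#' @export
image_stats <- function(pixels) {
  m <- mean(pixels)
  s <- sqrt(mean((pixels - m)^2))
  list(mean = m, sd = s)
}

#' Clip intensities to mean +/- 4 standard deviations
#'
#' Values inside the interval are unchanged. A constant image (sd = 0) is
#' returned unchanged: the interval is degenerate and the slice carries no
#' signal anyway (its normalized output is all zeros).
#'
#' @param pixels numeric matrix.
#' @param stats statistics of this image from [image_stats()].
#' @export
clip_intensities <- function(pixels, stats = image_stats(pixels)) {
  if (stats$sd == 0) return(pixels)
  pmin(pmax(pixels, stats$mean - 4 * stats$sd), stats$mean + 4 * stats$sd)
}

#' Normalize intensities as (value - mean) / (2 * sd)
#'
#' @param pixels numeric matrix (clipping already applied).
#' @param stats statistics of the original image.
#' @export
normalize_intensities <- function(pixels, stats) {
  if (stats$sd == 0) return(pixels * 0)
  (pixels - stats$mean) / (2 * stats$sd)
}

#' Replicate a grayscale image to three identical channels
#'
#' @param pixels single-channel numeric matrix.
#' @return numeric array `nrow x ncol x 3` with identical channels.
#' @export
to_three_channel <- function(pixels) {
  if (length(dim(pixels)) != 2)
    abort_br("to_three_channel expects a single-channel matrix")
  array(pixels, dim = c(dim(pixels), 3L))
}

#' Aspect-preserving resize with centered zero padding
#'
#' The longer image side is scaled (bilinear) to `target`; the shorter side
#' scales by the same factor and the remainder is zero-padded symmetrically
#' so the content is centered. Applied after normalization, so the padding
#' value 0 equals the code for mean intensity.
#'
#' @param pixels 2D matrix or 3-channel array.
#' @param target output side length (default 224).
#' @return array `target x target x 3` (single-channel input is replicated).
#' @export
pad_resize <- function(pixels, target = 224L) {
  d <- dim(pixels)
  if (d[1] == 0 || d[2] == 0) abort_br("cannot resize a zero-area image")
  chan <- if (length(d) == 3) pixels[, , 1] else pixels
  scale <- target / max(d[1:2])
  new_h <- max(1L, round(d[1] * scale))
  new_w <- max(1L, round(d[2] * scale))
  resized <- if (new_h == d[1] && new_w == d[2]) chan else
    EBImage::resize(chan, w = new_h, h = new_w)  # EBImage: w = first dim
  out <- matrix(0, target, target)
  off_r <- floor((target - new_h) / 2)
  off_c <- floor((target - new_w) / 2)
  out[off_r + seq_len(new_h), off_c + seq_len(new_w)] <- resized
  to_three_channel(out)
}

#' Full preprocessing chain for one slice
#'
#' Composes [clip_intensities()], [normalize_intensities()],
#' [to_three_channel()] and [pad_resize()]. The output is deterministic,
#' lies in `[-2, 2]` and its padded margins are exactly 0.
#'
#' @param pixels raw single-channel numeric matrix.
#' @param target model input side length.
#' @return `target x target x 3` float array.
#' @export
preprocess_image <- function(pixels, target = 224L) {
  st <- image_stats(pixels)
  x <- clip_intensities(pixels, st)
  x <- normalize_intensities(x, st)
  pad_resize(x, target)
}
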