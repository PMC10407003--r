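# Spatial training-time augmentation: random rotation (+/- pi/10),
# translation and shear (each up to 10% of image size), scaling (up to 20%
# in both directions), bilinear resampling. Augmentation never changes the
# tensor shape or the label.

#' Augmentation policy
#'
#' @param rotation_max_rad maximum absolute rotation (default pi/10).
#' @param translate_max_frac maximum absolute translation as a fraction of
#'   image size, both axes (default 0.10).
#' @param shear_max_frac maximum absolute shear as a fraction of image size
#'   (default 0.10).
#' @param scale_max_frac maximum scaling deviation, i.e. scale factors are
#'   drawn from `[1 - f, 1 + f]` independently per axis (default 0.20).
#' @param apply_prob probability that a given image is deformed in a given
#'   epoch (the deformation set is re-drawn every epoch).
#' @export
augmentation_config <- function(rotation_max_rad = pi / 10,
                                translate_max_frac = 0.10,
                                shear_max_frac = 0.10,
                                scale_max_frac = 0.20,
                                apply_prob = 0.5) {
  stopifnot(rotation_max_rad >= 0, rotation_max_rad <= pi,
            translate_max_frac >= 0, translate_max_frac <= 1,
            shear_max_frac >= 0, shear_max_frac <= 1,
            scale_max_frac >= 0, scale_max_frac <= 1,
            apply_prob >= 0, apply_prob <= 1)
  structure(list(rotation_max_rad = rotation_max_rad,
                 translate_max_frac = translate_max_frac,
                 shear_max_frac = shear_max_frac,
                 scale_max_frac = scale_max_frac,
                 apply_prob = apply_prob), class = "augmentation_config")
}

# Sample one set of deformation parameters within the policy bounds.
sample_deformation <- function(cfg, size) {
  list(theta = runif(1, -cfg$rotation_max_rad, cfg$rotation_max_rad),
       tx = runif(1, -cfg$translate_max_frac, cfg$translate_max_frac) * size,
       ty = runif(1, -cfg$translate_max_frac, cfg$translate_max_frac) * size,
       shx = runif(1, -cfg$shear_max_frac, cfg$shear_max_frac),
       shy = runif(1, -cfg$shear_max_frac, cfg$shear_max_frac),
       sx = 1 + runif(1, -cfg$scale_max_frac, cfg$scale_max_frac),
       sy = 1 + runif(1, -cfg$scale_max_frac, cfg$scale_max_frac))
}

#' Apply a random spatial deformation to a model input
#'
#' Draws rotation, translation, shear and scale uniformly within the policy
#' bounds and resamples bilinearly about the image center; background is
#' filled with 0 (the mean-intensity code). Uses the current RNG stream, so
#' a fixed seed reproduces the deformation exactly. A policy with all maxima
#' zero is the identity.
#'
#' @param input `h x w x 3` array (or `h x w` matrix) from
#'   [preprocess_image()].
#' @param cfg an [augmentation_config()].
#' @return array of the same shape.
#' @export
augment <- function(input, cfg = augmentation_config()) {
  d <- dim(input)
  chan <- if (length(d) == 3) input[, , 1] else input
  n1 <- nrow(chan); n2 <- ncol(chan)
  p <- sample_deformation(cfg, max(n1, n2))
  if (p$theta == 0 && p$tx == 0 && p$ty == 0 && p$shx == 0 &&
      p$shy == 0 && p$sx == 1 && p$sy == 1) {
    out <- chan
  } else {
    # forward map about the image center: scale %*% shear %*% rotation
    ct <- cos(p$theta); st <- sin(p$theta)
    a <- matrix(c(ct, -st, st, ct), 2, 2) %*%
         matrix(c(1, p$shx, p$shy, 1), 2, 2) %*%
         diag(c(p$sx, p$sy))
    cx <- (n1 + 1) / 2; cy <- (n2 + 1) / 2
    off <- c(cx + p$tx, cy + p$ty) - a %*% c(cx, cy)
    m <- rbind(t(a), as.numeric(off))
    out <- EBImage::affine(chan, m, filter = "bilinear",
                           output.dim = c(n1, n2), bg.col = 0)
    out <- matrix(as.numeric(out), n1, n2)
  }
  if (length(d) == 3) to_three_channel(out) else out
}
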