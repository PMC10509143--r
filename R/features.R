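#' Segment blood-stained pixels within a sponge crop
#'
#' A pixel is classified as blood when its colour lies far from the clean
#' sponge colour (Euclidean RGB distance above `threshold`) and its red
#' channel dominates green and blue, which separates dark red stains from
#' shadows and background remnants.
#'
#' @param crop H x W x 3 array, a detected sponge region (8-bit or unit
#'   scale).
#' @param sponge_base_color RGB triple in `[0, 1]` of the clean sponge.
#' @param threshold colour-distance threshold on the `[0, 1]` scale.
#' @return Logical H x W mask; an empty mask is a valid result.
#' @export
segment_blood <- function(crop,
                          sponge_base_color = scene_params()$sponge_base_color,
                          threshold = 30 / 255) {
  img <- as_unit_pixels(crop)
  d2 <- (img[, , 1] - sponge_base_color[1])^2 +
    (img[, , 2] - sponge_base_color[2])^2 +
    (img[, , 3] - sponge_base_color[3])^2
  red_dom <- img[, , 1] > img[, , 2] & img[, , 1] > img[, , 3]
  d2 > threshold^2 & red_dom
}

#' Colour moments of an intensity sample
#'
#' The three low-order colour moments used as compact descriptors of a
#' pixel-intensity distribution: the mean (MEA, overall brightness), the
#' root-mean-square deviation (VAR, spread of the colour distribution) and
#' the signed cube root of the mean cubed deviation (SKE, asymmetry).
#' All three use population normalisation (divisor N) and share the units of
#' the input, so scaling intensities by `c` scales each moment by `c`.
#'
#' @param values numeric vector of intensities (conventionally in `[0, 1]`).
#' @return Named numeric vector `c(mea, var, ske)`.
#' @examples
#' color_moments(c(0, 1))     # mea 0.5, var 0.5, ske 0
#' color_moments(c(0, 0, 1))  # mea 1/3, var sqrt(2)/3, ske (2/27)^(1/3)
#' @export
color_moments <- function(values) {
  if (length(values) == 0L) {
    stop("cannot compute colour moments of an empty sample", call. = FALSE)
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("`values` must be finite numeric intensities", call. = FALSE)
  }
  mea <- mean(values)
  d <- values - mea
  v <- sqrt(mean(d^2))
  m3 <- mean(d^3)
  ske <- sign(m3) * abs(m3)^(1 / 3)
  c(mea = mea, var = v, ske = ske)
}

#' Extract the four-feature predictor vector from a sponge crop
#'
#' Computes the predictors used by the colour-feature regression model:
#' \describe{
#'   \item{x1 (MEA)}{mean intensity of the blood-stained pixels, averaged
#'     over the three channels;}
#'   \item{x2 (VAR)}{RMS deviation, likewise channel-averaged;}
#'   \item{x3 (SKE)}{signed cube-root third moment, channel-averaged;}
#'   \item{x4}{area ratio of the blood region to the sponge crop, in
#'     `[0, 1]`.}
#' }
#' Moments are computed over the blood pixels found by [segment_blood()];
#' when no pixel is classified as blood they fall back to the whole crop
#' (with `x4 = 0`), so clean sponges remain predictable.
#'
#' @inheritParams segment_blood
#' @return Named numeric vector `c(x1, x2, x3, x4)`.
#' @export
extract_features <- function(crop,
                             sponge_base_color = scene_params()$sponge_base_color,
                             threshold = 30 / 255) {
  img <- as_unit_pixels(crop)
  if (length(img) == 0L) stop("`crop` is empty", call. = FALSE)
  mask <- segment_blood(img, sponge_base_color, threshold)
  n_blood <- sum(mask)
  use_mask <- if (n_blood > 0L) mask else
    matrix(TRUE, dim(img)[1], dim(img)[2])
  moments <- vapply(1:3, function(ch) color_moments(img[, , ch][use_mask]),
                    numeric(3))
  c(x1 = mean(moments["mea", ]),
    x2 = mean(moments["var", ]),
    x3 = mean(moments["ske", ]),
    x4 = n_blood / (dim(img)[1] * dim(img)[2]))
}

#' Extract features for a batch of images through the detection stage
#'
#' Runs detect -> crop -> extract for each image and binds the feature rows.
#'
#' @param images list of H x W x 3 arrays (or `synthetic_image` objects).
#' @param background_color background RGB for [detect_sponge_region()].
#' @inheritParams segment_blood
#' @return data.frame with columns `x1..x4`.
#' @export
extract_features_batch <- function(images,
                                   background_color = scene_params()$background_color,
                                   sponge_base_color = scene_params()$sponge_base_color,
                                   threshold = 30 / 255) {
  rows <- lapply(images, function(im) {
    px <- if (inherits(im, "synthetic_image")) im$pixels else im
    box <- detect_sponge_region(px, background_color)
    extract_features(crop(px, box), sponge_base_color, threshold)
  })
  as.data.frame(do.call(rbind, rows))
}
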