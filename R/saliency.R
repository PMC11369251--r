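#' Soft-threshold saliency masks
#'
#' The saliency mask of an image is a per-pixel soft foreground indicator
#'
#'   m = 1 - sigmoid((v - threshold) * slope)
#'
#' computed on the 0-255 intensity scale. With the default slope of 100 the
#' sigmoid saturates within a single 8-bit level, so the mask is effectively
#' a hard threshold (dark pixels -> 1) that is still differentiable: it is
#' exactly 0.5 at the threshold intensity. The source-domain (inverted PAH)
#' mask uses threshold 90; the target-domain (H&E-style, after RGB-to-gray
#' averaging) mask uses threshold 170. Both thresholds were fixed manually;
#' nuclei are darker than these levels in both domains, so the mask
#' highlights nuclear morphology.
#'
#' @param image matrix, H x W x 3 array or [image_tile()], intensities on the
#'   0-255 scale. 3-channel input is first converted with [rgb_to_gray()].
#' @param threshold intensity threshold on the 0-255 scale.
#' @param slope sigmoid steepness (default 100).
#' @return object of class `saliency_mask`: H x W matrix of values in [0, 1].
#' @export
saliency_mask <- function(image, threshold, slope = 100) {
  px <- tile_pixels(image)
  if (length(dim(px)) == 3) px <- rgb_to_gray(px)
  if (threshold > 1 && max(px) <= 1 && any(px > 0 & px < 1))
    stop("image appears to be normalised to [0, 1]; rescale to 0-255 ",
         "before computing a saliency mask")
  if (threshold < 0 || threshold > 255) stop("threshold must lie in [0, 255]")
  if (slope <= 0) stop("slope must be positive")
  m <- 1 - stats::plogis((px - threshold) * slope)
  structure(m, class = c("saliency_mask", class(m)))
}

#' Average RGB channels to grayscale
#'
#' The unweighted mean of the three channels (not luma weighting), matching
#' how the target-domain saliency input is formed.
#'
#' @param tile H x W x 3 array or 3-channel [image_tile()].
#' @return H x W matrix.
#' @export
rgb_to_gray <- function(tile) {
  px <- tile_pixels(tile)
  if (n_channels(px) != 3L) stop("input must be 3-channel")
  m <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  dim(m) <- dim(px)[1:2]
  m
}

#' L1 distance between two saliency masks
#'
#' Mean absolute per-pixel difference; the structure-preservation loss term
#' that keeps the generated image's saliency mask close to the input's.
#'
#' @param mask_x,mask_y equally sized masks (matrices in [0, 1]).
#' @return scalar >= 0.
#' @export
saliency_loss <- function(mask_x, mask_y) {
  if (!identical(dim(mask_x), dim(mask_y)))
    stop("saliency masks differ in shape")
  mean(abs(unclass(mask_x) - unclass(mask_y)))
}

#' Default saliency thresholds
#'
#' @return list with `x_threshold` (source domain, 90), `y_threshold`
#'   (target domain, 170) and `slope` (100).
#' @export
saliency_thresholds <- function() list(x_threshold = 90, y_threshold = 170,
                                       slope = 100)
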