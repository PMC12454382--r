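## Data augmentation for the photograph archive: salt-and-pepper and
## gaussian noise, dimming/brightening, rotation, mirror flips and mix-up.

#' Augmentation configuration
#'
#' Collects the parameters of [augment()]. The identity configuration
#' (all defaults) leaves an image unchanged.
#'
#' @param salt_pepper_density fraction of pixels replaced by black or white,
#'   in `[0, 1]`.
#' @param gaussian_sigma standard deviation of additive gaussian noise, in
#'   intensity units (0..255 scale).
#' @param brightness_factor multiplicative intensity factor (> 0); values
#'   below 1 dim, above 1 brighten.
#' @param rotation_degrees rotation angle, counter-clockwise. The frame size
#'   is kept; exposed corners are filled black.
#' @param mirror_axis `NULL` (no flip), `"horizontal"` (reverse columns) or
#'   `"vertical"` (reverse rows).
#' @param mixup_lambda `NULL`, or the mix-up weight in `[0, 1]` of the primary
#'   image; requires a `partner` image in [augment()]. Labels are not
#'   interpolated: the dominant-weight image's label should be kept.
#' @param seed integer seed; all randomness in [augment()] derives from it.
#' @return an object of class `augmentation_config`.
#' @export
augmentation_config <- function(salt_pepper_density = 0,
                                gaussian_sigma = 0,
                                brightness_factor = 1,
                                rotation_degrees = 0,
                                mirror_axis = NULL,
                                mixup_lambda = NULL,
                                seed = 1L) {
  stopifnot(salt_pepper_density >= 0, salt_pepper_density <= 1,
            gaussian_sigma >= 0, brightness_factor > 0)
  if (!is.null(mirror_axis))
    mirror_axis <- match.arg(mirror_axis, c("horizontal", "vertical"))
  if (!is.null(mixup_lambda))
    stopifnot(mixup_lambda >= 0, mixup_lambda <= 1)
  structure(list(salt_pepper_density = salt_pepper_density,
                 gaussian_sigma = gaussian_sigma,
                 brightness_factor = brightness_factor,
                 rotation_degrees = rotation_degrees,
                 mirror_axis = mirror_axis,
                 mixup_lambda = mixup_lambda,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

## Nearest-neighbour rotation about the image centre, frame size kept,
## exposed corners black. Exact for multiples of 90 degrees (up to frame
## clipping on non-square images).
rotate_keep_frame <- function(img, degrees) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  theta <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ## inverse map: source = R(-theta) (dest - centre) + centre
  ## y is downward, so a CCW rotation in display space is CW in (row, col)
  dy <- rr - cy; dx <- cc - cx
  sx <- round(cos(theta) * dx - sin(theta) * dy + cx)
  sy <- round(sin(theta) * dx + cos(theta) * dy + cy)
  ok <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  out <- array(0, dim = d)
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    src <- img[, , ch]
    plane[ok] <- src[cbind(sy[ok], sx[ok])]
    out[, , ch] <- plane
  }
  out
}

#' Augment an image
#'
#' Applies, in a fixed order, mix-up, brightness scaling, rotation, mirror
#' flip, gaussian noise and salt-and-pepper noise, as configured. The output
#' is deterministic given `cfg$seed` and has the input's dimensions.
#'
#' @param img an [rgb_image()].
#' @param cfg an [augmentation_config()].
#' @param partner second [rgb_image()] of identical dimensions; required when
#'   `cfg$mixup_lambda` is set. The mixed image is
#'   `round(lambda * img + (1 - lambda) * partner)`.
#' @return an [rgb_image()].
#' @export
augment <- function(img, cfg, partner = NULL) {
  stopifnot(inherits(img, "rgb_image"), inherits(cfg, "augmentation_config"))
  x <- unclass(img)
  if (!is.null(cfg$mixup_lambda)) {
    if (is.null(partner)) stop("mix-up requires a partner image")
    if (!identical(dim(partner), dim(x)))
      stop("mix-up partner dimension mismatch: ",
           paste(dim(partner), collapse = "x"), " vs ",
           paste(dim(x), collapse = "x"))
    x <- round(cfg$mixup_lambda * x + (1 - cfg$mixup_lambda) * unclass(partner))
  }
  if (cfg$brightness_factor != 1)
    x <- clip8(round(cfg$brightness_factor * x))
  if (cfg$rotation_degrees %% 360 != 0)
    x <- rotate_keep_frame(x, cfg$rotation_degrees)
  if (!is.null(cfg$mirror_axis)) {
    x <- if (cfg$mirror_axis == "horizontal") x[, dim(x)[2]:1, , drop = FALSE]
         else x[dim(x)[1]:1, , , drop = FALSE]
  }
  if (cfg$gaussian_sigma > 0 || cfg$salt_pepper_density > 0) {
    x <- with_seed(cfg$seed, {
      if (cfg$gaussian_sigma > 0)
        x <- clip8(round(x + rnorm(length(x), 0, cfg$gaussian_sigma)))
      if (cfg$salt_pepper_density > 0) {
        npix <- prod(dim(x)[1:2])
        k <- round(cfg$salt_pepper_density * npix)
        if (k > 0) {
          at <- sample.int(npix, k)
          val <- sample(c(0, 255), k, replace = TRUE)
          for (ch in 1:3) {
            plane <- x[, , ch]
            plane[at] <- val
            x[, , ch] <- plane
          }
        }
      }
      x
    })
  }
  rgb_image(x)
}
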