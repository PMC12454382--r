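## Fuzzy-interval colour-proportion features for the nuclear branch: the
## fraction of lens pixels whose RGB values fall inside a tolerance box
## around a standard colour (cyan for opalescence NO, yellow for colour NC).

#' Fuzzy colour interval
#'
#' A standard colour `(r, g, b)` with a symmetric tolerance `offset` defines
#' the per-channel intervals `R = [r - offset, r + offset]`,
#' `G = [g - offset, g + offset]`, `B = [b - offset, b + offset]`. Interval
#' endpoints are not clamped; membership clamps implicitly because pixel
#' values live in `[0, 255]`.
#'
#' @param standard_color numeric length-3 RGB vector, channels in 0..255.
#' @param offset non-negative scalar tolerance.
#' @return an object of class `fuzzy_color_interval` with fields
#'   `standard_color`, `offset`, `lower`, `upper`.
#' @export
make_interval <- function(standard_color, offset) {
  stopifnot(length(standard_color) == 3, all(standard_color >= 0),
            all(standard_color <= 255), offset >= 0)
  structure(list(standard_color = as.numeric(standard_color),
                 offset = as.numeric(offset),
                 lower = as.numeric(standard_color) - offset,
                 upper = as.numeric(standard_color) + offset),
            class = "fuzzy_color_interval")
}

#' @export
print.fuzzy_color_interval <- function(x, ...) {
  cat(sprintf("<fuzzy_color_interval (%g,%g,%g) +/- %g>\n",
              x$standard_color[1], x$standard_color[2], x$standard_color[3],
              x$offset))
  invisible(x)
}

#' Colour proportion inside a fuzzy interval
#'
#' Counts the fraction of masked pixels whose three channel values all lie
#' inside the interval (endpoints inclusive).
#'
#' @param img an [rgb_image()].
#' @param mask a [binary_image()] of identical height/width with at least one
#'   white pixel; only white-mask pixels enter numerator and denominator.
#' @param interval a [make_interval()] object.
#' @param channel_tag optional label stored on the result.
#' @return an object of class `color_feature`: list with `proportion` in
#'   `[0, 1]` and `channel_tag`.
#' @export
color_proportion <- function(img, mask, interval, channel_tag = NA_character_) {
  stopifnot(inherits(img, "rgb_image"), inherits(mask, "binary_image"),
            inherits(interval, "fuzzy_color_interval"))
  if (!identical(dim(img)[1:2], dim(mask)))
    stop("mask dimensions must equal image dimensions")
  sel <- unclass(mask) == 255
  n <- sum(sel)
  if (n == 0L) stop("undefined feature: mask contains no white pixels")
  member <- rep(TRUE, n)
  for (ch in 1:3) {
    v <- unclass(img)[, , ch][sel]
    member <- member & v >= interval$lower[ch] & v <= interval$upper[ch]
  }
  structure(list(proportion = sum(member) / n, channel_tag = channel_tag),
            class = "color_feature")
}

#' Nuclear feature configuration
#'
#' Standard colours and offsets for the fuzzy-interval features. The defaults
#' use canonical cyan (0, 255, 255) and yellow (255, 255, 0) with two offsets
#' each, giving a length-4 feature vector (a crude radial colour profile).
#'
#' @param standard_cyan,standard_yellow length-3 RGB vectors.
#' @param offsets numeric vector of tolerances applied to both colours.
#' @param include_background if `TRUE`, the proportion denominators include
#'   every crop pixel rather than only the elliptical lens mask.
#' @return an object of class `nuclear_feature_config`.
#' @export
nuclear_feature_config <- function(standard_cyan = c(0, 255, 255),
                                   standard_yellow = c(255, 255, 0),
                                   offsets = c(40, 80),
                                   include_background = FALSE) {
  stopifnot(length(offsets) >= 1, all(offsets >= 0))
  structure(list(standard_cyan = standard_cyan,
                 standard_yellow = standard_yellow,
                 offsets = offsets,
                 include_background = isTRUE(include_background)),
            class = "nuclear_feature_config")
}

#' Nuclear feature vector
#'
#' Ordered fuzzy-interval colour proportions of the cropped lens: cyan
#' features (one per offset) first, then yellow. The vector length is fixed
#' by the configuration (`2 * length(offsets)`).
#'
#' @param img lens crop, an [rgb_image()].
#' @param mask lens mask from [crop_lens()].
#' @param cfg a [nuclear_feature_config()].
#' @return named numeric vector with attribute `schema = "nuclear"`.
#' @export
nuclear_feature_vector <- function(img, mask, cfg = nuclear_feature_config()) {
  stopifnot(inherits(cfg, "nuclear_feature_config"))
  if (cfg$include_background)
    mask <- binary_image(matrix(255, dim(img)[1], dim(img)[2]))
  vals <- c()
  for (off in cfg$offsets)
    vals <- c(vals, color_proportion(img, mask,
                                     make_interval(cfg$standard_cyan, off),
                                     "cyan_NO")$proportion)
  for (off in cfg$offsets)
    vals <- c(vals, color_proportion(img, mask,
                                     make_interval(cfg$standard_yellow, off),
                                     "yellow_NC")$proportion)
  names(vals) <- c(paste0("cyan_", cfg$offsets), paste0("yellow_", cfg$offsets))
  attr(vals, "schema") <- "nuclear"
  vals
}
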