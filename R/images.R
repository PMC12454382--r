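## Raster containers and colour conversion.
##
## Images are plain R arrays with 1-based (row, col) indexing: x runs
## rightward over columns, y downward over rows. Channel values are 8-bit
## integers stored as numeric (0..255).

#' Construct an RGB image
#'
#' An `rgb_image` is a `height x width x 3` numeric array of 8-bit channel
#' values (R, G, B) in `[0, 255]`, indexed `[row, col, channel]`.
#'
#' @param data numeric array with `dim = c(height, width, 3)`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L)
    stop("rgb_image requires an array with dim = c(height, width, 3)")
  if (dim(data)[1] < 1L || dim(data)[2] < 1L)
    stop("image must be at least 1x1")
  if (anyNA(data) || min(data) < 0 || max(data) > 255)
    stop("channel values must be finite and in [0, 255]")
  structure(round(data), class = "rgb_image")
}

#' Construct a grayscale image
#'
#' @param data numeric matrix of 8-bit intensities in `[0, 255]`.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(data) {
  if (!is.matrix(data)) stop("gray_image requires a matrix")
  if (anyNA(data) || min(data) < 0 || max(data) > 255)
    stop("intensities must be finite and in [0, 255]")
  structure(round(data), class = "gray_image")
}

#' Construct a binary image
#'
#' @param data numeric matrix containing only the values 0 and 255.
#' @return an object of class `binary_image`.
#' @export
binary_image <- function(data) {
  if (!is.matrix(data)) stop("binary_image requires a matrix")
  if (!all(data %in% c(0, 255))) stop("binary images contain only 0 and 255")
  structure(data, class = "binary_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d>\n", d[1], d[2]))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %d x %d, %d white px>\n",
              nrow(x), ncol(x), sum(x == 255)))
  invisible(x)
}

clip8 <- function(x) pmin(pmax(x, 0), 255)

## Evaluate expr with the RNG seeded locally; the caller's RNG state is
## untouched (all package randomness flows through this helper).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luma convention
#' `gray = round(0.299 R + 0.587 G + 0.114 B)`.
#'
#' @param img an [rgb_image()].
#' @return a [gray_image()] with the same dimensions.
#' @export
to_gray <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  gray_image(matrix(clip8(round(g)), d[1], d[2]))
}

#' Read a raster image file
#'
#' Reads PNG, TIFF or JPEG into an [rgb_image()]. Grayscale files are
#' replicated across the three channels; an alpha channel, if present, is
#' dropped.
#'
#' @param path file path.
#' @return an [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  arr <- tryCatch(EBImage::imageData(EBImage::readImage(path)),
                  error = function(e) stop("cannot read image ", path, ": ",
                                           conditionMessage(e)))
  ## EBImage stores (x, y[, c]) in [0, 1]; transpose to (row, col, channel)
  if (length(dim(arr)) == 2L) {
    m <- t(arr)
    arr <- array(rep(m, 3L), dim = c(dim(m), 3L))
  } else {
    if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
    if (dim(arr)[3] == 1L) arr <- array(rep(arr, 3L), dim = c(dim(arr)[1:2], 3L))
    arr <- aperm(arr, c(2, 1, 3))
  }
  rgb_image(round(arr * 255))
}

#' Write an image to disk
#'
#' PNG and TIFF round-trip losslessly through [read_image()]; JPEG is lossy.
#' The format is chosen from the file extension.
#'
#' @param img an [rgb_image()].
#' @param path destination path ending in .png, .tif/.tiff or .jpg/.jpeg.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  arr <- aperm(unclass(img), c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}
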