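## Slit-beam (nuclear) preprocessing: bright-spot suppression, dynamic
## binarization, and lens localization by maximum inscribed white-ellipse
## search inside the coarse lens bounding box.

#' Bounding box
#'
#' Axis-aligned pixel box: `x`/`y` are the column/row of the top-left corner
#' (1-based), `w`/`h` its width and height in pixels.
#'
#' @param x,y top-left corner (column, row).
#' @param w,h width and height, both at least 1.
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(x, y, w, h) {
  stopifnot(w >= 1, h >= 1, x >= 1, y >= 1)
  structure(list(x = x, y = y, w = w, h = h), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box x=%g y=%g w=%g h=%g>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' Axis-aligned ellipse region
#'
#' The inscribed ellipse of a [bounding_box()] has centre
#' `(x + w/2 - 0.5, y + h/2 - 0.5)` and semi-axes `(w/2, h/2)`.
#'
#' @param center_x,center_y sub-pixel centre coordinates (column, row).
#' @param semi_axis_x,semi_axis_y semi-axis lengths in pixels, both positive.
#' @return an object of class `ellipse_region`.
#' @export
ellipse_region <- function(center_x, center_y, semi_axis_x, semi_axis_y) {
  stopifnot(semi_axis_x > 0, semi_axis_y > 0)
  structure(list(center_x = center_x, center_y = center_y,
                 semi_axis_x = semi_axis_x, semi_axis_y = semi_axis_y),
            class = "ellipse_region")
}

#' @export
print.ellipse_region <- function(x, ...) {
  cat(sprintf("<ellipse_region centre=(%.2f, %.2f) semi-axes=(%.2f, %.2f)>\n",
              x$center_x, x$center_y, x$semi_axis_x, x$semi_axis_y))
  invisible(x)
}

inscribed_ellipse <- function(box) {
  ellipse_region(box$x + box$w / 2 - 0.5, box$y + box$h / 2 - 0.5,
                 box$w / 2, box$h / 2)
}

#' Suppress specular bright spots
#'
#' Draws black dots over saturated flash reflections: every pixel whose three
#' channel values all exceed `threshold` is set to (0, 0, 0); all other
#' pixels are unchanged. Idempotent.
#'
#' @param img an [rgb_image()].
#' @param threshold 8-bit strict lower bound; default 250, i.e. channels 251
#'   and above.
#' @return an [rgb_image()].
#' @export
suppress_bright_spots <- function(img, threshold = 250) {
  stopifnot(inherits(img, "rgb_image"))
  x <- unclass(img)
  hit <- x[, , 1] > threshold & x[, , 2] > threshold & x[, , 3] > threshold
  for (ch in 1:3) {
    plane <- x[, , ch]
    plane[hit] <- 0
    x[, , ch] <- plane
  }
  rgb_image(x)
}

#' Binarize a grayscale image with a dynamic threshold
#'
#' Otsu's method selects a global threshold `t` from the 256-bin histogram;
#' pixels strictly above `t` become white (255), the rest black (0). A
#' constant image yields an all-black result. An explicit `threshold`
#' overrides the dynamic choice.
#'
#' @param gray a [gray_image()].
#' @param threshold optional fixed threshold overriding Otsu.
#' @return a [binary_image()].
#' @export
dynamic_threshold_binarize <- function(gray, threshold = NULL) {
  stopifnot(inherits(gray, "gray_image"))
  m <- unclass(gray)
  if (is.null(threshold)) {
    if (diff(range(m)) == 0) return(binary_image(matrix(0, nrow(m), ncol(m))))
    threshold <- EBImage::otsu(EBImage::Image(m / 255), range = c(0, 1),
                               levels = 256) * 255
  }
  binary_image(ifelse(m > threshold, 255, 0))
}

#' Coarse lens bounding box
#'
#' Tight bounding box of the largest 8-connected white component — the
#' approximate lens position handed to [max_inscribed_white_ellipse()].
#'
#' @param binary a [binary_image()].
#' @return a [bounding_box()].
#' @export
approximate_lens_bbox <- function(binary) {
  stopifnot(inherits(binary, "binary_image"))
  mask <- unclass(binary) == 255
  if (!any(mask)) stop("no lens candidate: image contains no white pixels")
  comp <- largest_component(mask)
  rows <- range(which(apply(comp, 1, any)))
  cols <- range(which(apply(comp, 2, any)))
  bounding_box(cols[1], rows[1], diff(cols) + 1, diff(rows) + 1)
}

## Strictly-inside column run of an ellipse on pixel row `row`:
## returns c(c0, c1) or NULL when the row misses the open ellipse.
ellipse_row_run <- function(row, cx, cy, a, b) {
  dy <- (row - cy) / b
  if (dy * dy >= 1) return(NULL)
  hw <- a * sqrt(1 - dy * dy)
  c0 <- floor(cx - hw + 1e-9) + 1
  c1 <- ceiling(cx + hw - 1e-9) - 1
  if (c0 > c1) return(NULL)
  c(c0, c1)
}

## Exhaustive/strided search for the maximum-area inscribed white ellipse.
## Candidate rectangles (w2, h2) are visited in decreasing ellipse area
## (ties: larger width first), positions in increasing (y, x); the first
## valid candidate is therefore the optimum with the documented tie-break.
## Whiteness of a row run is tested with per-row prefix sums in O(1).
ellipse_search_grid <- function(cs, bw, bh, widths, heights, xs, ys) {
  sizes <- expand.grid(w = widths, h = heights)
  sizes <- sizes[sizes$w >= 2 & sizes$h >= 2, , drop = FALSE]
  if (nrow(sizes) == 0L) return(NULL)
  sizes <- sizes[order(-(sizes$w * sizes$h), -sizes$w), , drop = FALSE]
  for (k in seq_len(nrow(sizes))) {
    w2 <- sizes$w[k]; h2 <- sizes$h[k]
    a <- w2 / 2; b <- h2 / 2
    cxr <- (w2 + 1) / 2; cyr <- (h2 + 1) / 2
    runs <- lapply(seq_len(h2), ellipse_row_run,
                   cx = cxr, cy = cyr, a = a, b = b)
    rows_used <- which(!vapply(runs, is.null, logical(1)))
    oy_set <- ys[ys <= bh - h2]
    ox_set <- xs[xs <= bw - w2]
    if (!length(oy_set) || !length(ox_set)) next
    for (oy in oy_set) {
      ok <- rep(TRUE, length(ox_set))
      for (i in rows_used) {
        run <- runs[[i]]
        len <- run[2] - run[1] + 1
        r <- oy + i
        ok <- ok & (cs[r, ox_set + run[2] + 1] - cs[r, ox_set + run[1]] == len)
        if (!any(ok)) break
      }
      if (any(ok)) {
        ox <- ox_set[which(ok)[1]]
        return(list(ox = ox, oy = oy, w = w2, h = h2))
      }
    }
  }
  NULL
}

#' Maximum inscribed white ellipse
#'
#' Searches all axis-aligned rectangles inside `bbox` for the inscribed
#' ellipse of maximal area \eqn{\pi a b} whose strictly interior pixel
#' centres (\eqn{((px-cx)/a)^2 + ((py-cy)/b)^2 < 1}) are all white. Ties are
#' broken towards larger horizontal semi-axis, then smaller (y, x) of the
#' rectangle. With `stride = 1` the search is exhaustive; larger strides
#' search a coarse position/size grid and then refine at stride 1 around the
#' incumbent (falling back to the exhaustive search when the coarse grid
#' finds nothing).
#'
#' @param binary a [binary_image()].
#' @param bbox a [bounding_box()] from [approximate_lens_bbox()].
#' @param stride positive integer grid stride on position and size.
#' @return an [ellipse_region()] with the winning rectangle attached as
#'   attribute `"rect"` (a [bounding_box()]).
#' @export
max_inscribed_white_ellipse <- function(binary, bbox, stride = 2L) {
  stopifnot(inherits(binary, "binary_image"), inherits(bbox, "bounding_box"),
            stride >= 1)
  stride <- as.integer(stride)
  mask <- unclass(binary) == 255
  stopifnot(bbox$x >= 1, bbox$y >= 1,
            bbox$x + bbox$w - 1 <= ncol(mask), bbox$y + bbox$h - 1 <= nrow(mask))
  sub <- mask[bbox$y:(bbox$y + bbox$h - 1), bbox$x:(bbox$x + bbox$w - 1),
              drop = FALSE]
  bh <- nrow(sub); bw <- ncol(sub)
  ## cs[r, c+1] - cs[r, p] = number of white pixels in row r, cols p..c
  cs <- cbind(0, t(apply(sub, 1, cumsum)))
  all_w <- bw:2; all_h <- bh:2
  grid_w <- unique(c(seq(bw, 2, by = -stride), 2))
  grid_h <- unique(c(seq(bh, 2, by = -stride), 2))
  grid_x <- seq(0L, bw - 2L, by = stride)
  grid_y <- seq(0L, bh - 2L, by = stride)
  hit <- ellipse_search_grid(cs, bw, bh, grid_w, grid_h, grid_x, grid_y)
  if (stride > 1L) {
    if (is.null(hit)) {
      hit <- ellipse_search_grid(cs, bw, bh, all_w, all_h,
                                 0:(bw - 2L), 0:(bh - 2L))
    } else {
      ## stride-1 refinement in a window around the incumbent
      d <- stride
      ws <- max(2, hit$w - d):min(bw, hit$w + d)
      hs <- max(2, hit$h - d):min(bh, hit$h + d)
      xs <- max(0, hit$ox - d):min(bw - 2, hit$ox + d)
      ys <- max(0, hit$oy - d):min(bh - 2, hit$oy + d)
      ref <- ellipse_search_grid(cs, bw, bh, sort(ws, decreasing = TRUE),
                                 sort(hs, decreasing = TRUE), xs, ys)
      if (!is.null(ref) && ref$w * ref$h >= hit$w * hit$h) hit <- ref
    }
  }
  if (is.null(hit))
    stop("no lens found: no all-white ellipse with semi-axes >= 1 exists")
  rect <- bounding_box(bbox$x + hit$ox, bbox$y + hit$oy, hit$w, hit$h)
  e <- inscribed_ellipse(rect)
  attr(e, "rect") <- rect
  e
}

#' Expand (fine-tune) an ellipse
#'
#' Scales both semi-axes by `factor` about the unchanged centre, then clips
#' each semi-axis so the ellipse stays inside the image frame. The lens slice
#' is not strictly elliptical, so the localized ellipse is grown slightly to
#' cover it.
#'
#' @param e an [ellipse_region()].
#' @param factor positive scale factor (default 1.1).
#' @param img_dim image dimensions `c(height, width)` used for clipping;
#'   `NULL` skips clipping.
#' @return an [ellipse_region()].
#' @export
expand_ellipse <- function(e, factor = 1.1, img_dim = NULL) {
  stopifnot(inherits(e, "ellipse_region"), factor > 0)
  a <- e$semi_axis_x * factor
  b <- e$semi_axis_y * factor
  if (!is.null(img_dim)) {
    h <- img_dim[1]; w <- img_dim[2]
    a <- min(a, e$center_x - 0.5, w + 0.5 - e$center_x)
    b <- min(b, e$center_y - 0.5, h + 0.5 - e$center_y)
  }
  ellipse_region(e$center_x, e$center_y, a, b)
}

## Logical mask of pixel centres strictly inside the ellipse, over the given
## row/col ranges.
ellipse_mask <- function(rows, cols, e) {
  dy <- (rows - e$center_y) / e$semi_axis_y
  dx <- (cols - e$center_x) / e$semi_axis_x
  outer(dy^2, dx^2, `+`) < 1
}

#' Crop the lens region
#'
#' Cuts the bounding-box crop of the ellipse out of the image. Pixels inside
#' the crop but outside the ellipse are set to (0, 0, 0); the returned mask
#' marks the pixel centres strictly inside the ellipse.
#'
#' @param img an [rgb_image()].
#' @param e an [ellipse_region()] lying within the image.
#' @return a list with elements `image` (the masked [rgb_image()] crop) and
#'   `mask` (a [binary_image()] of the same size).
#' @export
crop_lens <- function(img, e) {
  stopifnot(inherits(img, "rgb_image"), inherits(e, "ellipse_region"))
  d <- dim(img)
  ## crop of exactly ceil(2a) x ceil(2b) pixels, anchored so it contains
  ## every strictly interior pixel centre (clamped at the frame)
  c0 <- max(1L, as.integer(ceiling(e$center_x - e$semi_axis_x - 1e-9)))
  c1 <- min(d[2], c0 + as.integer(ceiling(2 * e$semi_axis_x - 1e-9)) - 1L)
  r0 <- max(1L, as.integer(ceiling(e$center_y - e$semi_axis_y - 1e-9)))
  r1 <- min(d[1], r0 + as.integer(ceiling(2 * e$semi_axis_y - 1e-9)) - 1L)
  stopifnot(c0 <= c1, r0 <= r1)
  inside <- ellipse_mask(r0:r1, c0:c1, e)
  crop <- unclass(img)[r0:r1, c0:c1, , drop = FALSE]
  for (ch in 1:3) {
    plane <- crop[, , ch]
    plane[!inside] <- 0
    crop[, , ch] <- plane
  }
  list(image = rgb_image(crop),
       mask = binary_image(ifelse(inside, 255, 0)))
}
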