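## Lesion-preserving binarization and feature extraction on the segmented
## pupil: Hough line statistics for cortical spokes, contour statistics for
## posterior subcapsular plaques. Opacities silhouette dark against the
## bright red reflex, so the lesion polarity is dark-on-bright.

#' Adaptive (local-mean) lesion binarization
#'
#' Inside the pupil circle a pixel is foreground (lesion) iff its intensity
#' is below the local `block x block` mean minus `offset_c`; everything
#' outside the circle is background. The local threshold absorbs the smooth
#' illumination gradient of the red reflex.
#'
#' @param gray a [gray_image()].
#' @param circle the pupil [circle_region()], within the image.
#' @param block odd window size, at least 3; default `ncol(gray)/8` rounded
#'   to odd.
#' @param offset_c constant subtracted from the local mean (intensity units).
#' @param exclude optional [binary_image()] of pixels with synthetic
#'   intensities (e.g. filled flash highlights) that must never count as
#'   lesion; enclosed excluded areas are recovered by the hole filling.
#' @return a [binary_image()] (lesion pixels white).
#' @export
lesion_binarize <- function(gray, circle, block = NULL, offset_c = 5,
                            exclude = NULL) {
  stopifnot(inherits(gray, "gray_image"), inherits(circle, "circle_region"))
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(block)) {
    block <- round(w / 8)
    if (block %% 2 == 0) block <- block + 1
  }
  if (block < 3 || block %% 2 == 0)
    stop("block must be an odd integer >= 3")
  k <- matrix(1 / block^2, block, block)
  lm <- EBImage::filter2(unclass(gray) * 1, k, boundary = "replicate")
  inside <- circle_pixel_mask(h, w, circle)
  fg <- inside & (unclass(gray) < lm - offset_c)
  if (!is.null(exclude)) {
    stopifnot(identical(dim(unclass(exclude)), dim(unclass(gray))))
    fg <- fg & !(unclass(exclude) == 255)
  }
  ## the local mean sits close to the lesion intensity deep inside a large
  ## uniform opacity, which hollows out its interior; restore it by filling
  ## enclosed holes
  if (any(fg)) {
    fg <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(fg * 1))))) > 0
    fg <- fg & inside
  }
  binary_image(ifelse(fg, 255, 0))
}

## Standard (rho, theta) line Hough transform with iterative peak picking
## and segment extraction along each peak line. Points within `near_dist` of
## a peak line are projected onto it; runs separated by gaps larger than
## `max_gap` are split, runs shorter than `min_length` dropped. Consumed
## points are removed before the next peak.
hough_line_segments <- function(binary, vote_threshold = 20, min_length = 10,
                                max_gap = 3, near_dist = 2.5, max_lines = 25L,
                                theta_step = pi / 180) {
  stopifnot(inherits(binary, "binary_image"))
  idx <- which(unclass(binary) == 255, arr.ind = TRUE)
  segs <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                     y1 = numeric(0), length = numeric(0),
                     theta = numeric(0), rho = numeric(0))
  if (nrow(idx) == 0L) return(segs)
  x <- idx[, 2]; y <- idx[, 1]
  thetas <- seq(0, pi - theta_step / 2, by = theta_step)
  ct <- cos(thetas); st <- sin(thetas)
  active <- rep(TRUE, length(x))
  for (iter in seq_len(max_lines)) {
    if (sum(active) < vote_threshold) break
    xa <- x[active]; ya <- y[active]
    best <- list(votes = -1L)
    for (ti in seq_along(thetas)) {
      rho <- xa * ct[ti] + ya * st[ti]
      bin <- round(rho)
      tab <- tabulate(bin - min(bin) + 1L)
      m <- which.max(tab)
      if (tab[m] > best$votes)
        best <- list(votes = tab[m], ti = ti, rho = m + min(bin) - 1L)
    }
    if (best$votes < vote_threshold) break
    ct0 <- ct[best$ti]; st0 <- st[best$ti]
    near_act <- abs(xa * ct0 + ya * st0 - best$rho) <= near_dist
    near_idx <- which(active)[near_act]
    tproj <- -x[near_idx] * st0 + y[near_idx] * ct0
    ord <- order(tproj)
    tproj <- tproj[ord]; pix <- near_idx[ord]
    brk <- c(0L, which(diff(tproj) > max_gap), length(tproj))
    kept <- FALSE
    for (b in seq_len(length(brk) - 1L)) {
      lo <- brk[b] + 1L; hi <- brk[b + 1L]
      if (hi <= lo) next
      len <- tproj[hi] - tproj[lo]
      if (len >= min_length) {
        segs <- rbind(segs, data.frame(
          x0 = x[pix[lo]], y0 = y[pix[lo]],
          x1 = x[pix[hi]], y1 = y[pix[hi]],
          length = len, theta = thetas[best$ti], rho = best$rho))
        active[pix[lo:hi]] <- FALSE
        kept <- TRUE
      }
    }
    if (!kept) active[near_idx] <- FALSE   # suppress a peak with no runs
  }
  segs
}

## Euclidean distance from point (px, py) to the segment (x0,y0)-(x1,y1).
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) 0 else max(0, min(1, ((px - x0) * vx + (py - y0) * vy) / L2))
  sqrt((x0 + t * vx - px)^2 + (y0 + t * vy - py)^2)
}

#' Cortical line feature configuration
#'
#' Hough line parameters, expressed relative to the pupil radius where noted.
#'
#' @param vote_threshold minimum accumulator votes for a line.
#' @param min_length_factor minimum segment length as a fraction of the
#'   radius.
#' @param max_gap_factor maximum within-segment gap as a fraction of the
#'   radius (at least 2 px).
#' @return an object of class `cortical_feature_config`.
#' @export
cortical_feature_config <- function(vote_threshold = 20,
                                    min_length_factor = 0.2,
                                    max_gap_factor = 0.05) {
  structure(list(vote_threshold = vote_threshold,
                 min_length_factor = min_length_factor,
                 max_gap_factor = max_gap_factor),
            class = "cortical_feature_config")
}

#' Cortical (spoke) line features
#'
#' Detects line segments in the lesion binary image with a Hough transform
#' and aggregates them into a fixed length-6 vector:
#' `[segment count, total length / r, mean length / r, mean centre distance
#' / r, min centre distance / r, foreground fraction inside the circle]`.
#' Centre distance is the perpendicular distance from the segment to the
#' pupil centre. When no segment is detected the zero vector is returned.
#'
#' @param binary lesion [binary_image()] from [lesion_binarize()].
#' @param circle the pupil [circle_region()].
#' @param cfg a [cortical_feature_config()].
#' @return named numeric length-6 vector with attribute `schema = "cortical"`;
#'   the detected segments are attached as attribute `"segments"`.
#' @export
cortical_line_features <- function(binary, circle,
                                   cfg = cortical_feature_config()) {
  stopifnot(inherits(binary, "binary_image"), inherits(circle, "circle_region"),
            inherits(cfg, "cortical_feature_config"))
  r <- circle$radius
  segs <- hough_line_segments(binary,
                              vote_threshold = cfg$vote_threshold,
                              min_length = cfg$min_length_factor * r,
                              max_gap = max(2, cfg$max_gap_factor * r))
  inside <- circle_pixel_mask(nrow(binary), ncol(binary), circle)
  fg_frac <- sum(unclass(binary) == 255 & inside) / sum(inside)
  if (nrow(segs) == 0L) {
    v <- c(n_lines = 0, total_length = 0, mean_length = 0,
           mean_center_dist = 0, min_center_dist = 0, fg_fraction = 0)
  } else {
    cd <- mapply(point_segment_distance,
                 MoreArgs = list(px = circle$center_x, py = circle$center_y),
                 x0 = segs$x0, y0 = segs$y0, x1 = segs$x1, y1 = segs$y1)
    v <- c(n_lines = nrow(segs),
           total_length = sum(segs$length) / r,
           mean_length = mean(segs$length) / r,
           mean_center_dist = mean(cd) / r,
           min_center_dist = min(cd) / r,
           fg_fraction = fg_frac)
  }
  attr(v, "schema") <- "cortical"
  attr(v, "segments") <- segs
  v
}

## Perimeter of labelled objects by contour chain length with the
## Vossepoel-Smeulders correction (0.948 per straight step, 1.343 per
## diagonal step); the uncorrected chain length overestimates a smooth
## boundary by about 5%, the EBImage boundary-pixel count underestimates it
## by about 11%.
contour_perimeters <- function(lab) {
  oc <- EBImage::ocontour(EBImage::Image(t(lab)))
  vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(0)
    d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
    step <- sqrt(rowSums(d^2))
    sum(ifelse(step < 1.2, 0.948, 1.343))
  }, numeric(1))
}

#' Posterior subcapsular (plaque) contour features
#'
#' External contours of the lesion components inside the pupil, aggregated
#' into a fixed length-4 vector:
#' `[total area / circle area, total perimeter / circle perimeter,
#' area-weighted centroid offset / r, contour count]`.
#' With no lesion the vector is `[0, 0, 0, 0]`.
#'
#' @param binary lesion [binary_image()] from [lesion_binarize()].
#' @param circle the pupil [circle_region()].
#' @param min_area components smaller than this many pixels are ignored.
#' @return named numeric length-4 vector with attribute
#'   `schema = "posterior"`.
#' @export
posterior_contour_features <- function(binary, circle, min_area = 5) {
  stopifnot(inherits(binary, "binary_image"), inherits(circle, "circle_region"))
  inside <- circle_pixel_mask(nrow(binary), ncol(binary), circle)
  mask <- unclass(binary) == 255 & inside
  lab <- label_components(mask)
  out <- c(area_ratio = 0, perimeter_ratio = 0, centroid_offset = 0,
           n_contours = 0)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_area)
    if (length(keep)) {
      relab <- matrix(0L, nrow(lab), ncol(lab))
      relab[lab %in% keep] <- match(lab[lab %in% keep], keep)
      areas <- areas[keep]
      perims <- contour_perimeters(relab)
      idx <- which(relab > 0L, arr.ind = TRUE)
      lv <- relab[relab > 0L]
      cx <- tapply(idx[, 2], lv, mean)
      cy <- tapply(idx[, 1], lv, mean)
      offs <- sqrt((cx - circle$center_x)^2 + (cy - circle$center_y)^2)
      r <- circle$radius
      out <- c(area_ratio = sum(areas) / (pi * r^2),
               perimeter_ratio = sum(perims) / (2 * pi * r),
               centroid_offset = sum(areas * offs) / sum(areas) / r,
               n_contours = length(keep))
    }
  }
  attr(out, "schema") <- "posterior"
  out
}
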