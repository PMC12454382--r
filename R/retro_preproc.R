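## Retro-illumination preprocessing: minimum enclosing circle segmentation,
## flash-highlight filling by three-way colour clustering, and precise pupil
## localization with a circular Hough transform.

#' Circle region
#'
#' @param center_x,center_y sub-pixel centre coordinates (column, row).
#' @param radius radius in pixels, non-negative.
#' @return an object of class `circle_region`.
#' @export
circle_region <- function(center_x, center_y, radius) {
  stopifnot(radius >= 0)
  structure(list(center_x = center_x, center_y = center_y, radius = radius),
            class = "circle_region")
}

#' @export
print.circle_region <- function(x, ...) {
  cat(sprintf("<circle_region centre=(%.2f, %.2f) r=%.2f>\n",
              x$center_x, x$center_y, x$radius))
  invisible(x)
}

in_circle <- function(circ, p, tol = 1e-7) {
  sqrt((p[1] - circ$center_x)^2 + (p[2] - circ$center_y)^2) <=
    circ$radius + tol
}

circle_from_2 <- function(p, q) {
  circle_region((p[1] + q[1]) / 2, (p[2] + q[2]) / 2,
                sqrt(sum((p - q)^2)) / 2)
}

circle_from_3 <- function(p, q, r) {
  ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)   # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  circle_region(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
}

## Exact smallest enclosing circle by the incremental (Welzl-style)
## construction; P is an n x 2 matrix of (x, y) points.
mec_incremental <- function(P) {
  circ <- NULL
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    if (is.null(circ) || !in_circle(circ, p)) {
      ## smallest circle through p enclosing P[1:i, ]
      circ <- circle_region(p[1], p[2], 0)
      for (j in seq_len(i - 1)) {
        q <- P[j, ]
        if (!in_circle(circ, q)) {
          ## smallest circle through p and q enclosing P[1:j, ]
          circ <- circle_from_2(p, q)
          for (k in seq_len(j - 1)) {
            r <- P[k, ]
            if (!in_circle(circ, r)) {
              cc <- circle_from_3(p, q, r)
              circ <- if (is.null(cc)) {
                ## collinear triple: widest diameter circle
                cands <- list(circle_from_2(p, q), circle_from_2(p, r),
                              circle_from_2(q, r))
                cands[[which.max(vapply(cands, `[[`, 0, "radius"))]]
              } else cc
            }
          }
        }
      }
    }
  }
  circ
}

#' Minimum enclosing circle
#'
#' The unique smallest circle containing all foreground pixel centres (or
#' all supplied points). Points are reduced to their convex hull before the
#' exact incremental construction.
#'
#' @param x a [binary_image()] (white pixels are the foreground), or an
#'   `n x 2` matrix of (x, y) points.
#' @return a [circle_region()]; every input point lies within
#'   `radius + 1e-6` of its centre.
#' @export
min_enclosing_circle <- function(x) {
  if (inherits(x, "binary_image")) {
    idx <- which(unclass(x) == 255, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("minimum enclosing circle of an empty mask")
    P <- cbind(x = idx[, 2], y = idx[, 1])
  } else {
    P <- as.matrix(x)
    if (nrow(P) == 0L) stop("minimum enclosing circle of an empty point set")
    stopifnot(ncol(P) == 2)
  }
  P <- unique(P)
  if (nrow(P) > 3L) {
    hull <- chull(P[, 1], P[, 2])
    P <- P[hull, , drop = FALSE]
  }
  mec_incremental(P)
}

circle_pixel_mask <- function(h, w, circ) {
  dy2 <- (seq_len(h) - circ$center_y)^2
  dx2 <- (seq_len(w) - circ$center_x)^2
  outer(dy2, dx2, `+`) <= circ$radius^2
}

#' Detect flash bright spots
#'
#' Pixels inside the circular region whose minimum channel value exceeds the
#' threshold, dilated by one pixel to catch the surrounding halo, then
#' re-intersected with the region.
#'
#' @param img an [rgb_image()].
#' @param region a [circle_region()] within the image.
#' @param threshold 8-bit strict lower bound on min(R, G, B); default 240.
#' @return a [binary_image()] bright-spot mask.
#' @export
detect_bright_spots <- function(img, region, threshold = 240) {
  stopifnot(inherits(img, "rgb_image"), inherits(region, "circle_region"))
  d <- dim(img)
  inside <- circle_pixel_mask(d[1], d[2], region)
  minch <- pmin(img[, , 1], img[, , 2], img[, , 3])
  spot <- inside & minch > threshold
  if (any(spot)) {
    dil <- EBImage::dilate(EBImage::Image(t(spot * 1)),
                           EBImage::makeBrush(3, "box"))
    spot <- t(EBImage::imageData(dil)) > 0 & inside
  }
  binary_image(ifelse(spot, 255, 0))
}

## Greedy agglomerative merging of colour clusters: repeatedly merge the two
## clusters whose mean RGB vectors are closest (Euclidean), replacing them by
## their member-weighted mean, until `k` clusters remain. Starts from the
## distinct sampled colours weighted by multiplicity (merging exact
## duplicates first is a zero-distance no-op, so this is equivalent to
## starting from the individual pixels). Returns list(means, sizes).
agglomerate_colors <- function(cols, k = 3L) {
  key <- paste(cols[, 1], cols[, 2], cols[, 3])
  tab <- table(key)
  first <- !duplicated(key)
  M <- cols[first, , drop = FALSE]
  s <- as.numeric(tab[match(key[first], names(tab))])
  n <- nrow(M)
  if (n <= k) return(list(means = M, sizes = s))
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf
  active <- rep(TRUE, n)
  rowwhich <- max.col(-D, ties.method = "first")
  rowmin <- D[cbind(seq_len(n), rowwhich)]
  for (iter in seq_len(n - k)) {
    i <- which.min(replace(rowmin, !active, Inf))
    j <- rowwhich[i]
    if (j < i) { tmp <- i; i <- j; j <- tmp }
    M[i, ] <- (s[i] * M[i, ] + s[j] * M[j, ]) / (s[i] + s[j])
    s[i] <- s[i] + s[j]
    active[j] <- FALSE
    newd <- sqrt(colSums((t(M) - M[i, ])^2))
    newd[!active] <- Inf
    newd[i] <- Inf
    D[i, ] <- newd
    D[, i] <- newd
    D[j, ] <- Inf
    D[, j] <- Inf
    act <- which(active)
    ## rows whose cached nearest neighbour was i or j must be recomputed;
    ## for the rest the only candidate improvement is the new row i
    stale <- act[act == i | rowwhich[act] == i | rowwhich[act] == j]
    fresh <- act[!(act %in% stale)]
    upd <- fresh[newd[fresh] < rowmin[fresh]]
    rowmin[upd] <- newd[upd]
    rowwhich[upd] <- i
    if (length(stale)) {
      rowwhich[stale] <- max.col(-D[stale, , drop = FALSE],
                                 ties.method = "first")
      rowmin[stale] <- D[cbind(stale, rowwhich[stale])]
    }
  }
  list(means = M[active, , drop = FALSE], sizes = s[active])
}

#' Fill bright spots by three-way colour clustering
#'
#' Samples non-spot pixels inside the circular region, merges them into three
#' colour clusters (nominally yellow, white and black) by greedy agglomerative
#' merging of cluster means, identifies the yellow cluster as the one
#' maximizing `(R + G)/2 - B`, and paints every bright-spot pixel with the
#' rounded yellow-cluster mean `Avg`. Pixels outside the mask are unchanged.
#'
#' @param img an [rgb_image()].
#' @param region a [circle_region()].
#' @param mask bright-spot [binary_image()] from [detect_bright_spots()].
#' @param sample_n maximum number of pixels sampled for clustering.
#' @param seed integer seed for the pixel sample.
#' @param yellow_score function mapping a length-3 cluster mean to its
#'   "yellowness"; the cluster with the largest score supplies the fill.
#' @return the filled [rgb_image()], with the clustering result attached as
#'   attribute `"cluster_state"` (list with `cluster_means`, `sizes`,
#'   `yellow_mean`, `fill`, `membership` of the sampled pixels).
#' @export
cluster_fill_bright_spots <- function(img, region, mask, sample_n = 600,
                                      seed = 1L,
                                      yellow_score = function(m)
                                        (m[1] + m[2]) / 2 - m[3]) {
  stopifnot(inherits(img, "rgb_image"), inherits(region, "circle_region"),
            inherits(mask, "binary_image"))
  d <- dim(img)
  spot <- unclass(mask) == 255
  if (!any(spot)) return(img)
  inside <- circle_pixel_mask(d[1], d[2], region)
  cand <- which(inside & !spot)
  if (length(cand) == 0L) stop("no sample pixels inside the region")
  if (length(cand) > sample_n)
    cand <- with_seed(seed, sort(sample(cand, sample_n)))
  cols <- cbind(unclass(img)[, , 1][cand], unclass(img)[, , 2][cand],
                unclass(img)[, , 3][cand])
  n_distinct <- nrow(unique(cols))
  if (n_distinct < 3L) {
    warning("degenerate clustering: fewer than 3 distinct colours; ",
            "filling with the overall mean")
    fill <- round(colMeans(cols))
    state <- list(cluster_means = matrix(colMeans(cols), 1),
                  sizes = nrow(cols), yellow_mean = colMeans(cols),
                  fill = fill, membership = rep(0L, nrow(cols)))
  } else {
    cl <- agglomerate_colors(cols, 3L)
    scores <- apply(cl$means, 1, yellow_score)
    yc <- which.max(scores)
    fill <- round(cl$means[yc, ])
    dists <- vapply(seq_len(nrow(cl$means)),
                    function(i) rowSums((cols - matrix(cl$means[i, ],
                                                       nrow(cols), 3,
                                                       byrow = TRUE))^2),
                    numeric(nrow(cols)))
    state <- list(cluster_means = cl$means, sizes = cl$sizes,
                  yellow_mean = cl$means[yc, ], fill = fill,
                  membership = max.col(-dists) - 1L)
  }
  x <- unclass(img)
  for (ch in 1:3) {
    plane <- x[, , ch]
    plane[spot] <- fill[ch]
    x[, , ch] <- plane
  }
  out <- rgb_image(x)
  attr(out, "cluster_state") <- state
  out
}

## Gradient-magnitude edge map (central differences) with a fixed threshold.
edge_map <- function(gray, threshold) {
  m <- unclass(gray)
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  sqrt(gx^2 + gy^2) > threshold
}

#' Circular Hough transform
#'
#' Detects the strongest circle over a range of radii. Edge pixels (gradient
#' magnitude above a fixed threshold) vote through a one-pixel-wide ring
#' kernel; accumulator scores are normalized by ring size so radii compete
#' fairly, and the global maximum wins.
#'
#' @param gray a [gray_image()].
#' @param radius_range numeric length-2, min and max radius in pixels.
#' @param edge_threshold fixed gradient threshold for the edge map.
#' @param min_vote_frac minimum normalized accumulator score (fraction of the
#'   ring supported by edge pixels) below which no circle is reported.
#' @return a [circle_region()]; errors with "no circle" when no accumulator
#'   peak reaches `min_vote_frac`.
#' @export
hough_circle <- function(gray, radius_range, edge_threshold = 40,
                         min_vote_frac = 0.25) {
  stopifnot(inherits(gray, "gray_image"), length(radius_range) == 2)
  h <- nrow(gray); w <- ncol(gray)
  stopifnot(radius_range[1] <= radius_range[2],
            radius_range[2] <= sqrt(h^2 + w^2))
  edges <- edge_map(gray, edge_threshold)
  if (!any(edges)) stop("no circle: empty edge map")
  em <- edges * 1
  radii <- seq(max(1L, ceiling(radius_range[1])), floor(radius_range[2]))
  best <- list(score = -Inf)
  for (r in radii) {
    half <- r + 1L
    off <- -half:half
    ring <- abs(sqrt(outer(off^2, off^2, `+`)) - r) <= 0.5
    votes <- EBImage::filter2(em, ring * 1, boundary = 0)
    score <- votes / sum(ring)
    m <- which.max(score)
    if (score[m] > best$score) {
      best <- list(score = score[m],
                   row = ((m - 1) %% h) + 1,
                   col = ((m - 1) %/% h) + 1,
                   r = r)
    }
  }
  if (best$score < min_vote_frac)
    stop("no circle: strongest accumulator peak below the vote threshold")
  circle_region(best$col, best$row, best$r)
}

#' Retro-preprocessing configuration
#'
#' @param spot_threshold bright-spot threshold for [detect_bright_spots()].
#' @param sample_n,seed clustering sample size and seed for
#'   [cluster_fill_bright_spots()].
#' @param edge_threshold,min_vote_frac parameters of [hough_circle()].
#' @param radius_factors search band for the precise circle, as multiples of
#'   the coarse minimum-enclosing-circle radius.
#' @return an object of class `retro_preproc_config`.
#' @export
retro_preproc_config <- function(spot_threshold = 240, sample_n = 600,
                                 seed = 1L, edge_threshold = 40,
                                 min_vote_frac = 0.25,
                                 radius_factors = c(0.7, 1.15)) {
  structure(list(spot_threshold = spot_threshold, sample_n = sample_n,
                 seed = as.integer(seed), edge_threshold = edge_threshold,
                 min_vote_frac = min_vote_frac,
                 radius_factors = radius_factors),
            class = "retro_preproc_config")
}

#' Segment the eyeball from a retro-illumination image
#'
#' Composition of the retro-illumination preprocessing chain: coarse
#' foreground (Otsu on the grayscale image, largest component) -> minimum
#' enclosing circle -> bright-spot detection -> cluster fill -> circular
#' Hough refinement. Returns the filled image cropped to the precise
#' circle's bounding box.
#'
#' @param img an [rgb_image()].
#' @param cfg a [retro_preproc_config()].
#' @return list with `image` (filled [rgb_image()] crop), `circle` (the
#'   precise [circle_region()] in crop coordinates), `circle_full` (the same
#'   circle in original image coordinates) and `coarse_circle`.
#' @export
segment_eyeball <- function(img, cfg = retro_preproc_config()) {
  stopifnot(inherits(img, "rgb_image"), inherits(cfg, "retro_preproc_config"))
  d <- dim(img)
  gray <- to_gray(img)
  fg <- dynamic_threshold_binarize(gray)
  ## dark radial opacities can slice the pupil into sectors; close the mask
  ## so the largest component is the whole pupil, not one sector
  m <- unclass(fg) == 255
  if (any(m)) {
    closed <- EBImage::closing(EBImage::Image(t(m * 1)),
                               EBImage::makeBrush(5, "disc"))
    m <- t(EBImage::imageData(closed)) > 0
  }
  comp <- largest_component(m)
  if (!any(comp)) stop("no circle: empty coarse foreground")
  coarse <- min_enclosing_circle(binary_image(ifelse(comp, 255, 0)))
  spots <- detect_bright_spots(img, coarse, cfg$spot_threshold)
  filled <- cluster_fill_bright_spots(img, coarse, spots,
                                      sample_n = cfg$sample_n,
                                      seed = cfg$seed)
  rng <- pmax(3, cfg$radius_factors * coarse$radius)
  precise <- hough_circle(to_gray(filled), rng,
                          edge_threshold = cfg$edge_threshold,
                          min_vote_frac = cfg$min_vote_frac)
  c0 <- max(1L, as.integer(ceiling(precise$center_x - precise$radius - 1e-9)))
  c1 <- min(d[2], as.integer(floor(precise$center_x + precise$radius + 1e-9)))
  r0 <- max(1L, as.integer(ceiling(precise$center_y - precise$radius - 1e-9)))
  r1 <- min(d[1], as.integer(floor(precise$center_y + precise$radius + 1e-9)))
  crop <- rgb_image(unclass(filled)[r0:r1, c0:c1, , drop = FALSE])
  list(image = crop,
       circle = circle_region(precise$center_x - c0 + 1,
                              precise$center_y - r0 + 1, precise$radius),
       circle_full = precise,
       coarse_circle = coarse,
       spot_mask = binary_image(unclass(spots)[r0:r1, c0:c1, drop = FALSE]))
}
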