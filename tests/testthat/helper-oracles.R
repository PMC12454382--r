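# Independent reference implementations (oracles) used to validate the
# package's optimized routines, plus small fixture builders. Everything here
# favours transparency over speed.

rand_rgb <- function(h, w, seed) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

gray_from <- function(m) gray_image(m)

# blobby random binary mask: union of random discs and rectangles plus salt,
# guaranteeing structure an inscribed ellipse can live in
rand_blob_mask <- function(h, w, seed) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  for (i in seq_len(sample(1:3, 1))) {
    cy <- runif(1, 2, h - 1); cx <- runif(1, 2, w - 1)
    r <- runif(1, 2, min(h, w) / 2)
    m <- m | (outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`) <= r^2)
  }
  if (runif(1) < 0.5) {
    r0 <- sort(sample(seq_len(h), 2)); c0 <- sort(sample(seq_len(w), 2))
    m[r0[1]:r0[2], c0[1]:c0[2]] <- TRUE
  }
  salt <- matrix(runif(h * w) < 0.03, h, w)
  binary_image(ifelse(xor(m, salt), 255, 0))
}

# Exhaustive maximum inscribed white ellipse: every rectangle inside `bbox`
# is tested with a direct per-pixel strict-interior scan. Rectangles are
# visited in decreasing ellipse area so the search can stop as soon as the
# remaining candidates are provably smaller than the incumbent (a sound
# bound: validity only removes candidates). Returns the maximal area pi*a*b,
# or 0 when no valid ellipse with semi-axes >= 1 exists.
oracle_max_ellipse_area <- function(binary, bbox) {
  mask <- unclass(binary) == 255
  ys <- bbox$y:(bbox$y + bbox$h - 1)
  xs <- bbox$x:(bbox$x + bbox$w - 1)
  sub <- mask[ys, xs, drop = FALSE]
  bh <- nrow(sub); bw <- ncol(sub)
  R <- matrix(seq_len(bh), bh, bw)
  C <- matrix(seq_len(bw), bh, bw, byrow = TRUE)
  sizes <- expand.grid(w = 2:bw, h = 2:bh)
  sizes <- sizes[order(-(sizes$w * sizes$h)), , drop = FALSE]
  best <- 0
  for (k in seq_len(nrow(sizes))) {
    w2 <- sizes$w[k]; h2 <- sizes$h[k]
    area <- pi * w2 * h2 / 4
    if (area <= best) break
    a <- w2 / 2; b <- h2 / 2
    for (oy in 0:(bh - h2)) {
      cy <- oy + (h2 + 1) / 2
      for (ox in 0:(bw - w2)) {
        cx <- ox + (w2 + 1) / 2
        inside <- ((C - cx) / a)^2 + ((R - cy) / b)^2 < 1
        if (all(sub[inside])) {
          best <- area
          break
        }
      }
      if (best == area) break
    }
  }
  best
}

# Breadth-first flood fill labelling (8-connected); independent of the
# igraph-based implementation.
oracle_label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (c in seq_len(w)) for (r in seq_len(h)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, c))
      lab[r, c] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# O(n^3) smallest enclosing circle: every pair (as diameter) and every
# triple (as circumcircle) is a candidate; the smallest covering circle wins.
oracle_mec <- function(P) {
  n <- nrow(P)
  covers <- function(cx, cy, r) {
    all(sqrt((P[, 1] - cx)^2 + (P[, 2] - cy)^2) <= r + 1e-7)
  }
  best <- NULL
  consider <- function(cx, cy, r) {
    if (covers(cx, cy, r) && (is.null(best) || r < best$r))
      best <<- list(cx = cx, cy = cy, r = r)
  }
  if (n == 1) return(list(cx = P[1, 1], cy = P[1, 2], r = 0))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    consider((P[i, 1] + P[j, 1]) / 2, (P[i, 2] + P[j, 2]) / 2,
             sqrt(sum((P[i, ] - P[j, ])^2)) / 2)
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      ax <- P[i, 1]; ay <- P[i, 2]; bx <- P[j, 1]; by <- P[j, 2]
      cx <- P[k, 1]; cy <- P[k, 2]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(d) > 1e-12) {
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
        consider(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
      }
    }
  }
  best
}

# Brute-force three-cluster agglomeration: distinct colours (weighted by
# multiplicity) merged by minimum centroid distance, the full distance
# matrix recomputed from scratch at every iteration. Ties: first row, then
# first column. Returns list(means, sizes).
oracle_agglomerate <- function(cols, k = 3) {
  key <- paste(cols[, 1], cols[, 2], cols[, 3])
  first <- !duplicated(key)
  M <- cols[first, , drop = FALSE]
  s <- as.numeric(table(key)[match(key[first], names(table(key)))])
  while (nrow(M) > k) {
    n <- nrow(M)
    D <- matrix(Inf, n, n)
    for (i in 1:n) for (j in 1:n) if (i != j)
      D[i, j] <- sqrt(sum((M[i, ] - M[j, ])^2))
    rmin <- apply(D, 1, min)
    i <- which.min(rmin)
    j <- which.min(D[i, ])
    lo <- min(i, j); hi <- max(i, j)
    M[lo, ] <- (s[lo] * M[lo, ] + s[hi] * M[hi, ]) / (s[lo] + s[hi])
    s[lo] <- s[lo] + s[hi]
    M <- M[-hi, , drop = FALSE]
    s <- s[-hi]
  }
  list(means = M, sizes = s)
}

# Direct per-pixel fuzzy-interval membership count.
oracle_color_proportion <- function(img, mask, standard, offset) {
  sel <- which(unclass(mask) == 255)
  x <- unclass(img)
  hit <- 0L
  for (i in sel) {
    px <- c(x[, , 1][i], x[, , 2][i], x[, , 3][i])
    if (all(px >= standard - offset) && all(px <= standard + offset))
      hit <- hit + 1L
  }
  hit / length(sel)
}

# Box-filter local mean with edge replication, written as explicit loops.
oracle_box_mean <- function(m, block) {
  h <- nrow(m); w <- ncol(m)
  half <- (block - 1) / 2
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    rr <- pmin(pmax(r + (-half:half), 1), h)
    cc <- pmin(pmax(c + (-half:half), 1), w)
    out[r, c] <- mean(m[rr, cc])
  }
  out
}

# render a clean retro-style pupil fixture with one centred dark disc
disc_lesion_fixture <- function(n = 121, R = 45, r_lesion = 18,
                                pupil = 150, bg = 15, lesion = 50) {
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  m <- matrix(bg, n, n)
  m[d2 <= R^2] <- pupil
  m[d2 <= r_lesion^2] <- lesion
  list(gray = gray_image(m), circle = circle_region(ctr, ctr, R))
}
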