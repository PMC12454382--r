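test_that("minimum enclosing circle handles the degenerate cases", {
  c1 <- min_enclosing_circle(cbind(5, 7))
  expect_equal(c(c1$center_x, c1$center_y, c1$radius), c(5, 7, 0))
  c2 <- min_enclosing_circle(cbind(c(0, 6), c(0, 8)))
  expect_equal(c(c2$center_x, c2$center_y, c2$radius), c(3, 4, 5))
  expect_error(min_enclosing_circle(matrix(numeric(0), 0, 2)), "empty")
})

test_that("minimum enclosing circle equals the O(n^3) oracle on random sets", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(5:40, 1)
    P <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    got <- min_enclosing_circle(P)
    want <- oracle_mec(P)
    expect_equal(got$radius, want$r, tolerance = 1e-6)
    expect_equal(got$center_x, want$cx, tolerance = 1e-5)
    expect_equal(got$center_y, want$cy, tolerance = 1e-5)
    d <- sqrt((P[, 1] - got$center_x)^2 + (P[, 2] - got$center_y)^2)
    expect_true(all(d <= got$radius + 1e-6))
  }
})

test_that("bright-spot detection bounds the mask by the dilated patch", {
  img <- rgb_image(array(100, c(30, 30, 3)))
  region <- circle_region(15, 15, 12)
  expect_equal(sum(detect_bright_spots(img, region, 240) == 255), 0)
  x <- unclass(img)
  for (ch in 1:3) x[14:16, 14:16, ch] <- 255
  spot <- detect_bright_spots(rgb_image(x), region, 240)
  m <- unclass(spot) == 255
  expect_true(all(m[14:16, 14:16]))            # contains the patch
  expect_true(all(which(m, arr.ind = TRUE) >= 13) &&
              all(which(m, arr.ind = TRUE) <= 17))  # within 1-px dilation
  expect_equal(sum(detect_bright_spots(rgb_image(x), region, 255) == 255), 0)
})

test_that("cluster fill recovers the yellow class exactly on a 3-colour region", {
  n <- 40
  img <- array(0, c(n, n, 3))
  region <- circle_region(20.5, 20.5, 17)
  inside <- which(outer((1:n - 20.5)^2, (1:n - 20.5)^2, `+`) <= 17^2)
  set.seed(3)
  lab <- sample(rep(c("y", "w", "b"), c(500, 40, length(inside) - 540)))
  colmap <- rbind(y = c(200, 170, 60), w = c(250, 250, 250), b = c(15, 10, 10))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- colmap[lab, ch]
    img[, , ch] <- plane
  }
  img <- rgb_image(img)
  ## the detected spot mask covers most, not all, of the white patch, so the
  ## clustering still sees all three colours
  mask <- matrix(0, n, n)
  mask[inside[lab == "w"][1:25]] <- 255
  out <- cluster_fill_bright_spots(img, region, binary_image(mask), seed = 2)
  filled <- sapply(1:3, function(ch) unique(unclass(out)[, , ch][mask == 255]))
  expect_equal(as.numeric(filled), c(200, 170, 60))
  # pixels outside the mask are untouched
  expect_identical(unclass(out)[mask != 255], unclass(img)[mask != 255])
  # empty mask: identity
  none <- binary_image(matrix(0, n, n))
  expect_identical(unclass(cluster_fill_bright_spots(img, region, none)),
                   unclass(img))
})

test_that("cluster fill matches the brute-force agglomeration oracle on jitter", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 24
    region <- circle_region(12.5, 12.5, 9)
    inside <- which(outer((1:n - 12.5)^2, (1:n - 12.5)^2, `+`) <= 9^2)
    n_in <- length(inside)
    lab <- sample(rep(c("y", "w", "b"), c(round(0.6 * n_in), 20,
                                          n_in - round(0.6 * n_in) - 20)))
    base <- rbind(y = c(200, 170, 60), w = c(250, 250, 250),
                  b = c(15, 10, 10))
    img <- array(0, c(n, n, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- pmin(pmax(round(base[lab, ch] +
                                       rnorm(n_in, 0, 6)), 0), 255)
      img[, , ch] <- plane
    }
    img <- rgb_image(img)
    mask <- matrix(0, n, n)
    mask[inside[lab == "w"]] <- 255
    out <- cluster_fill_bright_spots(img, region, binary_image(mask),
                                     sample_n = 300, seed = seed)
    st <- attr(out, "cluster_state")
    # every candidate pixel fits in the sample, so the oracle sees the same set
    cand <- which(outer((1:n - 12.5)^2, (1:n - 12.5)^2, `+`) <= 9^2 &
                  mask != 255)
    cols <- cbind(unclass(img)[, , 1][cand], unclass(img)[, , 2][cand],
                  unclass(img)[, , 3][cand])
    ocl <- oracle_agglomerate(cols, 3)
    oy <- which.max(apply(ocl$means, 1, function(m) (m[1] + m[2]) / 2 - m[3]))
    expect_equal(st$fill, round(ocl$means[oy, ]))
  }
})

test_that("degenerate clustering falls back to the overall mean with a warning", {
  img <- rgb_image(array(80, c(20, 20, 3)))
  region <- circle_region(10, 10, 8)
  mask <- matrix(0, 20, 20)
  mask[9:11, 9:11] <- 255
  expect_warning(out <- cluster_fill_bright_spots(img, region,
                                                  binary_image(mask)),
                 "degenerate")
  expect_true(all(unclass(out)[, , 1][mask == 255] == 80))
})

test_that("circular Hough transform recovers rendered circles", {
  render_circle <- function(n, cy, cx, r, fg = 200, bg = 20) {
    d2 <- outer((1:n - cy)^2, (1:n - cx)^2, `+`)
    gray_image(matrix(ifelse(d2 <= r^2, fg, bg), n, n))
  }
  g <- render_circle(80, 40, 40, 20)
  circ <- hough_circle(g, c(10, 30))
  expect_lt(abs(circ$center_x - 40), 2.01)
  expect_lt(abs(circ$center_y - 40), 2.01)
  expect_lt(abs(circ$radius - 20), 2.01)
  expect_error(hough_circle(gray_image(matrix(50, 40, 40)), c(5, 15)),
               "no circle")
  # a full circle beats one with half its boundary missing
  m <- unclass(render_circle(100, 30, 30, 15))
  d2 <- outer((1:100 - 70)^2, (1:100 - 70)^2, `+`)
  ring <- d2 <= 15.5^2 & d2 >= 14.5^2
  cols <- matrix(1:100, 100, 100, byrow = TRUE)
  m[ring & cols <= 70] <- 200   # half-dashed second circle
  circ2 <- hough_circle(gray_image(m), c(10, 20))
  expect_lt(abs(circ2$center_x - 30), 3)
  expect_lt(abs(circ2$center_y - 30), 3)
})

test_that("eyeball segmentation finds the generated pupil and is deterministic", {
  o <- gen_retro(retro_spec(c_grade = 2, p_grade = 0, seed = 31))
  seg <- segment_eyeball(o$image)
  tru <- o$truth$circle
  expect_lt(abs(seg$circle_full$center_x - tru$center_x), 3.01)
  expect_lt(abs(seg$circle_full$center_y - tru$center_y), 3.01)
  expect_lt(abs(seg$circle_full$radius - tru$radius), 3.01)
  seg2 <- segment_eyeball(o$image)
  expect_identical(unclass(seg$image), unclass(seg2$image))
  # crop is the circle bounding box (clipped): about 2r on each side
  expect_lte(abs(dim(seg$image)[1] - ceiling(2 * seg$circle_full$radius)), 1)
  # no bright spots: the fill is the identity
  o2 <- gen_retro(retro_spec(c_grade = 0, p_grade = 0, n_flash = 0,
                             seed = 32))
  seg3 <- segment_eyeball(o2$image)
  expect_lt(abs(seg3$circle_full$radius - o2$truth$circle$radius), 3.01)
})
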