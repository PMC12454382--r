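test_that("bright-spot suppression blackens exactly the all-channels->250 pixels", {
  one <- function(rgb) rgb_image(array(rgb, c(1, 1, 3)))
  expect_true(all(suppress_bright_spots(one(c(251, 251, 251))) == 0))
  expect_equal(as.numeric(suppress_bright_spots(one(c(251, 249, 251)))),
               c(251, 249, 251))
  expect_equal(as.numeric(suppress_bright_spots(one(c(250, 250, 250)))),
               c(250, 250, 250))  # "above 250" is strict
  black <- rgb_image(array(0, c(4, 4, 3)))
  expect_identical(unclass(suppress_bright_spots(black)), unclass(black))
})

test_that("bright-spot suppression matches brute force and is idempotent", {
  for (seed in 1:5) {
    img <- rand_rgb(32, 32, seed)
    out <- suppress_bright_spots(img)
    minch <- pmin(out[, , 1], out[, , 2], out[, , 3])
    expect_equal(sum(minch > 250), 0)
    should <- img[, , 1] > 250 & img[, , 2] > 250 & img[, , 3] > 250
    changed <- !(out[, , 1] == img[, , 1] & out[, , 2] == img[, , 2] &
                 out[, , 3] == img[, , 3])
    expect_identical(changed, should)
    expect_identical(unclass(suppress_bright_spots(out)), unclass(out))
  }
})

test_that("dynamic binarization separates a bimodal image and handles edge cases", {
  m <- matrix(rep(c(40, 200), each = 50), 10, 10)
  bin <- dynamic_threshold_binarize(gray_image(m))
  expect_identical(unclass(bin) == 255, m == 200)
  expect_true(all(dynamic_threshold_binarize(gray_image(matrix(77, 5, 5))) == 0))
  m2 <- matrix(sample(c(0, 255), 64, TRUE), 8, 8)
  bin2 <- dynamic_threshold_binarize(gray_image(m2))
  expect_identical(unclass(bin2), m2, ignore_attr = TRUE)
  # explicit override
  bin3 <- dynamic_threshold_binarize(gray_image(m), threshold = 100)
  expect_identical(unclass(bin3) == 255, m > 100)
})

test_that("coarse lens bbox is the tight box of the largest 8-connected component", {
  m <- matrix(0, 10, 12)
  m[3 + 1, 5 + 1] <- 255   # single pixel at row 4, col 6
  bb <- approximate_lens_bbox(binary_image(m))
  expect_equal(c(bb$x, bb$y, bb$w, bb$h), c(6, 4, 1, 1))
  m2 <- matrix(0, 12, 16)
  m2[3:10, 5:14] <- 255
  bb2 <- approximate_lens_bbox(binary_image(m2))
  expect_equal(c(bb2$x, bb2$y, bb2$w, bb2$h), c(5, 3, 10, 8))
  expect_error(approximate_lens_bbox(binary_image(matrix(0, 4, 4))),
               "no lens candidate")
})

test_that("largest-component selection agrees with a flood-fill oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- matrix(runif(30 * 30) < 0.35, 30, 30)
    bb <- tryCatch(approximate_lens_bbox(binary_image(ifelse(m, 255, 0))),
                   error = function(e) NULL)
    lab <- oracle_label_components(m)
    if (max(lab) == 0) {
      expect_null(bb)
    } else {
      areas <- tabulate(lab[lab > 0])
      big <- lab == which.max(areas)
      rows <- range(which(apply(big, 1, any)))
      cols <- range(which(apply(big, 2, any)))
      if (sum(areas == max(areas)) == 1) {
        expect_equal(c(bb$x, bb$y, bb$w, bb$h),
                     c(cols[1], rows[1], diff(cols) + 1, diff(rows) + 1))
      }
    }
  }
})

test_that("max inscribed ellipse of an all-white box is the box's inscribed ellipse", {
  m <- matrix(0, 14, 24)
  m[3:12, 3:22] <- 255
  bin <- binary_image(m)
  bb <- approximate_lens_bbox(bin)
  e <- max_inscribed_white_ellipse(bin, bb, stride = 1)
  expect_equal(e$semi_axis_x, 10)
  expect_equal(e$semi_axis_y, 5)
  expect_equal(e$center_x, 3 + 20 / 2 - 0.5)
  expect_equal(e$center_y, 3 + 10 / 2 - 0.5)
})

test_that("ellipse search matches the exhaustive oracle on discs", {
  n <- 31
  d2 <- outer((1:n - 15)^2, (1:n - 15)^2, `+`)
  m <- ifelse(d2 <= 8^2, 255, 0)
  bin <- binary_image(m)
  bb <- approximate_lens_bbox(bin)
  e <- max_inscribed_white_ellipse(bin, bb, stride = 1)
  area <- pi * e$semi_axis_x * e$semi_axis_y
  expect_equal(area, oracle_max_ellipse_area(bin, bb))
  # two discs: the search must live in the bigger one
  m2 <- matrix(0, 36, 36)
  m2[outer((1:36 - 10)^2, (1:36 - 8)^2, `+`) <= 16] <- 255
  m2[outer((1:36 - 24)^2, (1:36 - 24)^2, `+`) <= 81] <- 255
  bin2 <- binary_image(m2)
  bb2 <- approximate_lens_bbox(bin2)
  e2 <- max_inscribed_white_ellipse(bin2, bb2, stride = 1)
  expect_equal(pi * e2$semi_axis_x * e2$semi_axis_y,
               oracle_max_ellipse_area(bin2, bb2))
  expect_gt(e2$center_x, 18)  # inside the radius-9 disc
  expect_gt(e2$center_y, 18)
})

test_that("returned ellipse never contains a black pixel centre", {
  for (seed in 1:10) {
    bin <- rand_blob_mask(24, 24, seed)
    bb <- tryCatch(approximate_lens_bbox(bin), error = function(e) NULL)
    if (is.null(bb)) next
    e <- tryCatch(max_inscribed_white_ellipse(bin, bb, stride = 1),
                  error = function(e) NULL)
    if (is.null(e)) next
    h <- nrow(bin); w <- ncol(bin)
    dy <- (seq_len(h) - e$center_y) / e$semi_axis_y
    dx <- (seq_len(w) - e$center_x) / e$semi_axis_x
    inside <- outer(dy^2, dx^2, `+`) < 1
    expect_true(all(unclass(bin)[inside] == 255))
  }
})

test_that("adding white pixels never shrinks the maximal ellipse", {
  for (seed in 1:6) {
    bin <- rand_blob_mask(22, 22, seed)
    if (!any(bin == 255)) next
    bb <- approximate_lens_bbox(bin)
    a0 <- tryCatch({
      e <- max_inscribed_white_ellipse(bin, bb, stride = 1)
      pi * e$semi_axis_x * e$semi_axis_y
    }, error = function(e) 0)
    m <- unclass(bin)
    set.seed(seed + 100)
    m[sample(which(m == 0), min(30, sum(m == 0)))] <- 255
    bin2 <- binary_image(m)
    bb2 <- approximate_lens_bbox(bin2)
    a1 <- tryCatch({
      e <- max_inscribed_white_ellipse(bin2, bb2, stride = 1)
      pi * e$semi_axis_x * e$semi_axis_y
    }, error = function(e) 0)
    expect_gte(a1, a0)
  }
})

test_that("strided search with refinement stays close to the exhaustive result", {
  for (seed in 1:6) {
    bin <- rand_blob_mask(30, 30, seed + 50)
    bb <- tryCatch(approximate_lens_bbox(bin), error = function(e) NULL)
    if (is.null(bb)) next
    e1 <- tryCatch(max_inscribed_white_ellipse(bin, bb, stride = 1),
                   error = function(e) NULL)
    e2 <- tryCatch(max_inscribed_white_ellipse(bin, bb, stride = 2),
                   error = function(e) NULL)
    expect_equal(is.null(e1), is.null(e2))
    if (!is.null(e1)) {
      a1 <- pi * e1$semi_axis_x * e1$semi_axis_y
      a2 <- pi * e2$semi_axis_x * e2$semi_axis_y
      expect_lte(a2, a1 + 1e-9)
      expect_gte(a2, 0.6 * a1)
    }
  }
})

test_that("ellipse expansion scales about the centre and clips at borders", {
  e <- ellipse_region(20, 15, 10, 5)
  expect_equal(expand_ellipse(e, 1, img_dim = c(40, 60)), e)
  e2 <- expand_ellipse(e, 1.1, img_dim = c(40, 60))
  expect_equal(e2$semi_axis_x, 11)
  expect_equal(e2$semi_axis_y, 5.5)
  e3 <- expand_ellipse(e, 2, img_dim = c(22, 30))
  expect_equal(e3$semi_axis_x, 30 + 0.5 - 20)  # clipped to the right border
  expect_equal(e3$semi_axis_y, 22 + 0.5 - 15)
  expect_lte(e3$center_x + e3$semi_axis_x, 30.5)
})

test_that("lens crop has ceil(2a) x ceil(2b) pixels and an exact interior mask", {
  img <- rand_rgb(40, 50, 9)
  e <- ellipse_region(25.5, 20.5, 12.3, 8.7)
  out <- crop_lens(img, e)
  expect_equal(dim(out$image)[1:2], c(ceiling(2 * 8.7), ceiling(2 * 12.3)))
  # brute-force interior count over the full image
  dy <- (1:40 - e$center_y) / e$semi_axis_y
  dx <- (1:50 - e$center_x) / e$semi_axis_x
  expect_equal(sum(out$mask == 255), sum(outer(dy^2, dx^2, `+`) < 1))
  # outside-ellipse crop pixels are black
  expect_true(all(out$image[, , 1][unclass(out$mask) != 255] == 0))
  # whole-image ellipse keeps every pixel of the frame
  efull <- ellipse_region(25.5, 20.5, 25, 20)
  expect_equal(dim(crop_lens(img, efull)$image)[1:2], c(40, 50))
})
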