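test_that("lesion binarization: uniform region yields no foreground; params validated", {
  g <- gray_image(matrix(150, 60, 60))
  circ <- circle_region(30, 30, 25)
  expect_equal(sum(lesion_binarize(g, circ) == 255), 0)
  expect_error(lesion_binarize(g, circ, block = 4), "odd")
  expect_error(lesion_binarize(g, circ, block = 1), "odd")
})

test_that("local mean equals a direct box-filter oracle (replicated edges)", {
  set.seed(8)
  m <- matrix(sample(0:255, 256, TRUE), 16, 16)
  k <- matrix(1 / 25, 5, 5)
  lm <- EBImage::filter2(m * 1, k, boundary = "replicate")
  expect_equal(as.numeric(lm), as.numeric(oracle_box_mean(m, 5)),
               tolerance = 1e-8)
})

test_that("a dark disc on a bright gradient is segmented within tight bounds", {
  n <- 101; R <- 42; rl <- 12
  ctr <- 51
  d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, `+`)
  m <- matrix(15, n, n)
  m[d2 <= R^2] <- 150
  # vertical illumination gradient on the pupil
  grad <- matrix(rep(round(seq(20, -20, length.out = n)), n), n, n)
  m[d2 <= R^2] <- m[d2 <= R^2] + grad[d2 <= R^2]
  lesion_true <- d2 <= rl^2
  m[lesion_true] <- m[lesion_true] - 70
  bin <- lesion_binarize(gray_image(pmin(pmax(m, 0), 255)),
                         circle_region(ctr, ctr, R))
  fg <- unclass(bin) == 255
  expect_gt(sum(fg & lesion_true) / sum(lesion_true), 0.9)
  dil <- d2 <= (rl + 2)^2
  expect_true(all(!fg[!dil]))
})

test_that("cortical features: blank image gives the zero vector", {
  bin <- binary_image(matrix(0, 60, 60))
  v <- cortical_line_features(bin, circle_region(30, 30, 25))
  expect_length(v, 6)
  expect_true(all(v == 0))
})

test_that("a single rendered spoke through the centre is recovered", {
  n <- 101; ctr <- 51; R <- 45
  m <- matrix(0, n, n)
  ang <- 0.43
  L <- 70  # total chord length through the centre
  for (t in seq(-L / 2, L / 2, by = 0.4)) {
    r0 <- round(ctr + t * sin(ang)); c0 <- round(ctr + t * cos(ang))
    m[r0 + (-1:1), c0 + (-1:1)] <- 255
  }
  v <- cortical_line_features(binary_image(m), circle_region(ctr, ctr, R))
  expect_gte(v[["n_lines"]], 1)
  expect_lt(v[["min_center_dist"]], 0.05)
  expect_lt(abs(v[["total_length"]] - L / R) / (L / R), 0.15)
})

test_that("posterior features: closed forms for a centred disc lesion", {
  fx <- disc_lesion_fixture(n = 121, R = 45, r_lesion = 18)
  bin <- lesion_binarize(fx$gray, fx$circle)
  v <- posterior_contour_features(bin, fx$circle)
  expect_lt(abs(v[["area_ratio"]] - (18 / 45)^2) / (18 / 45)^2, 0.05)
  expect_lt(abs(v[["perimeter_ratio"]] - 18 / 45) / (18 / 45), 0.05)
  expect_lt(v[["centroid_offset"]], 0.02)
  expect_equal(v[["n_contours"]], 1)
  # no lesion
  clean <- gray_image(matrix(150, 60, 60))
  v0 <- posterior_contour_features(lesion_binarize(clean,
                                                   circle_region(30, 30, 25)),
                                   circle_region(30, 30, 25))
  expect_equal(as.numeric(v0), c(0, 0, 0, 0))
})

test_that("off-centre blob centroid offset matches the raw image moments", {
  n <- 81; ctr <- 41; R <- 35
  m <- matrix(0, n, n)
  d2 <- outer((1:n - 30)^2, (1:n - 52)^2, `+`)  # blob centred (row 30, col 52)
  m[d2 <= 8^2] <- 255
  circ <- circle_region(ctr, ctr, R)
  v <- posterior_contour_features(binary_image(m), circ)
  idx <- which(m == 255, arr.ind = TRUE)
  want <- sqrt((mean(idx[, 2]) - ctr)^2 + (mean(idx[, 1]) - ctr)^2) / R
  expect_lt(abs(v[["centroid_offset"]] - want), 0.01)
})

test_that("area ratio grows monotonically under lesion dilation", {
  fx <- disc_lesion_fixture(n = 101, R = 40, r_lesion = 10)
  bin0 <- lesion_binarize(fx$gray, fx$circle)
  m <- unclass(bin0) == 255
  a_prev <- posterior_contour_features(bin0, fx$circle)[["area_ratio"]]
  for (i in 1:3) {
    m <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(m * 1)),
                                              EBImage::makeBrush(3, "box")))) > 0
    a <- posterior_contour_features(binary_image(ifelse(m, 255, 0)),
                                    fx$circle)[["area_ratio"]]
    expect_gte(a, a_prev)
    a_prev <- a
  }
})

test_that("feature vectors are finite on generated fixtures at every grade", {
  for (g in c(0, 3, 5)) {
    oc <- gen_retro(retro_spec(c_grade = g, seed = 60 + g))
    vc <- extract_retro_features(oc$image, "cortical")$features
    expect_true(all(is.finite(vc)))
    op <- gen_retro(retro_spec(p_grade = g, seed = 70 + g))
    vp <- extract_retro_features(op$image, "posterior")$features
    expect_true(all(is.finite(vp)))
  }
})

test_that("ratio features are stable under integer upscaling of the fixture", {
  fx <- disc_lesion_fixture(n = 61, R = 22, r_lesion = 9)
  v1 <- posterior_contour_features(lesion_binarize(fx$gray, fx$circle),
                                   fx$circle)
  fx2 <- disc_lesion_fixture(n = 122, R = 44, r_lesion = 18)
  fx2$circle <- circle_region(61.5, 61.5, 44)
  v2 <- posterior_contour_features(lesion_binarize(fx2$gray, fx2$circle),
                                   fx2$circle)
  expect_lt(abs(v1[["area_ratio"]] - v2[["area_ratio"]]) /
            max(v2[["area_ratio"]], 1e-9), 0.10)
  expect_lt(abs(v1[["perimeter_ratio"]] - v2[["perimeter_ratio"]]) /
            max(v2[["perimeter_ratio"]], 1e-9), 0.10)
})
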