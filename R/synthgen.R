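## Grade-controlled synthetic image generator: the reproducible stand-in for
## a hospital photograph archive. Slit-beam images carry an elliptical bright
## lens slice whose cyan/yellow pixel fractions grow linearly with the NO/NC
## grade; retro-illumination images carry an orange-red pupil with radial
## spoke opacities (C), a central plaque (P), an illumination gradient and
## saturated flash spots. Every image is deterministic given its seed.

#' Slit-beam image specification
#'
#' The NO grade drives the fraction of lens pixels tinted cyan, the NC grade
#' the fraction tinted yellow; both maps are linear
#' (`fraction = 0.04 + 0.065 * grade`), the simplest monotone choice.
#'
#' @param no_grade,nc_grade integer grades 0..6.
#' @param width,height image size in pixels.
#' @param n_white_spots corneal specular highlights (all channels >= 252).
#' @param n_yellow_spots peri-ocular yellow skin spots.
#' @param noise_sd pixel noise standard deviation (intensity units).
#' @param seed integer seed.
#' @return an object of class `slit_beam_spec`.
#' @export
slit_beam_spec <- function(no_grade = 0L, nc_grade = 0L, width = 128L,
                           height = 96L, n_white_spots = 2L,
                           n_yellow_spots = 2L, noise_sd = 6, seed = 1L) {
  stopifnot(no_grade %in% 0:6, nc_grade %in% 0:6, width >= 64, height >= 48,
            noise_sd >= 0)
  structure(list(no_grade = as.integer(no_grade),
                 nc_grade = as.integer(nc_grade),
                 width = as.integer(width), height = as.integer(height),
                 n_white_spots = as.integer(n_white_spots),
                 n_yellow_spots = as.integer(n_yellow_spots),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "slit_beam_spec")
}

## linear grade -> target pixel-fraction map shared by NO (cyan) and NC
## (yellow); strictly increasing in the grade
grade_fraction <- function(grade) 0.04 + 0.065 * grade

## bounded per-image biological variability: a clamped gaussian multiplier /
## offset keeps adjacent grades overlapping without ever reordering them at
## a fixed seed (the draw position in the RNG stream is grade-independent)
clamped_norm <- function(sd, clamp) max(-clamp, min(clamp, rnorm(1, 0, sd)))

disc_indices <- function(h, w, cy, cx, radius) {
  which(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`) <= radius^2)
}

set_pixels <- function(x, idx, color, jitter_sd) {
  n <- length(idx)
  if (n == 0L) return(x)
  for (ch in 1:3) {
    plane <- x[, , ch]
    plane[idx] <- clip8(round(color[ch] + rnorm(n, 0, jitter_sd)))
    x[, , ch] <- plane
  }
  x
}

#' Generate a slit-beam image
#'
#' @param spec a [slit_beam_spec()].
#' @return list with `image` (an [rgb_image()]), `labels` (list of NO and NC
#'   [grade_label()]s) and `truth` (ground-truth lens [ellipse_region()] and
#'   rendered pixel counts).
#' @export
gen_slit_beam <- function(spec) {
  stopifnot(inherits(spec, "slit_beam_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    cx <- w / 2 + runif(1, -3, 3)
    cy <- h / 2 + runif(1, -2, 2)
    a <- 0.27 * w + runif(1, -2, 2)
    b <- 0.23 * h + runif(1, -1.5, 1.5)
    lens <- ellipse_region(cx, cy, a, b)
    x <- array(0, dim = c(h, w, 3))
    x <- set_pixels(x, seq_len(h * w), c(14, 11, 9), spec$noise_sd / 2)
    ## peri-ocular yellow skin spots, outside the lens
    for (i in seq_len(spec$n_yellow_spots)) {
      for (try in 1:20) {
        sy <- runif(1, 5, h - 5); sx <- runif(1, 5, w - 5)
        if (((sx - cx) / (1.35 * a))^2 + ((sy - cy) / (1.35 * b))^2 > 1) break
      }
      x <- set_pixels(x, disc_indices(h, w, sy, sx, runif(1, 3, 5)),
                      c(185, 155, 65), 6)
    }
    inside <- ellipse_mask(seq_len(h), seq_len(w), lens)
    lens_idx <- which(inside)
    x <- set_pixels(x, lens_idx, c(95, 92, 80), spec$noise_sd)
    perm <- sample(lens_idx)
    jit_no <- clamped_norm(0.012, 0.02)
    jit_nc <- clamped_norm(0.012, 0.02)
    n_cyan <- round(max(0, grade_fraction(spec$no_grade) + jit_no) *
                    length(lens_idx))
    n_yell <- round(max(0, grade_fraction(spec$nc_grade) + jit_nc) *
                    length(lens_idx))
    x <- set_pixels(x, perm[seq_len(n_cyan)], c(20, 235, 235), 8)
    x <- set_pixels(x, perm[n_cyan + seq_len(n_yell)], c(235, 235, 20), 8)
    ## corneal white highlights on the lens boundary
    for (i in seq_len(spec$n_white_spots)) {
      ang <- runif(1, 0, 2 * pi)
      sx <- cx + 0.95 * a * cos(ang)
      sy <- cy + 0.95 * b * sin(ang)
      idx <- disc_indices(h, w, sy, sx, runif(1, 2, 4))
      for (ch in 1:3) {
        plane <- x[, , ch]
        plane[idx] <- sample(252:255, length(idx), replace = TRUE)
        x[, , ch] <- plane
      }
    }
    list(image = rgb_image(x),
         labels = list(NO = grade_label("NO", spec$no_grade),
                       NC = grade_label("NC", spec$nc_grade)),
         truth = list(lens = lens, n_lens_px = length(lens_idx),
                      n_cyan_px = n_cyan, n_yellow_px = n_yell))
  })
}

#' Retro-illumination image specification
#'
#' The C grade drives the number (`2 * grade`) and length of radial spoke
#' opacities, the P grade the central plaque area fraction
#' (`0.032 * grade` of the pupil disc); both strictly increasing, zero at
#' grade 0.
#'
#' @param c_grade,p_grade integer grades 0..5.
#' @param size square image side in pixels.
#' @param radius nominal pupil radius in pixels.
#' @param gradient_amp amplitude of the vertical illumination gradient
#'   (intensity units across one radius).
#' @param noise_sd pupil pixel noise standard deviation.
#' @param n_flash number of saturated flash spots (channels >= 250).
#' @param seed integer seed.
#' @return an object of class `retro_spec`.
#' @export
retro_spec <- function(c_grade = 0L, p_grade = 0L, size = 120L, radius = 42,
                       gradient_amp = 25, noise_sd = 2, n_flash = 2L,
                       seed = 1L) {
  stopifnot(c_grade %in% 0:5, p_grade %in% 0:5, size >= 64,
            radius >= 16, radius <= size / 2 - 4)
  structure(list(c_grade = as.integer(c_grade),
                 p_grade = as.integer(p_grade),
                 size = as.integer(size), radius = radius,
                 gradient_amp = gradient_amp, noise_sd = noise_sd,
                 n_flash = as.integer(n_flash), seed = as.integer(seed)),
            class = "retro_spec")
}

#' Generate a retro-illumination image
#'
#' @param spec a [retro_spec()].
#' @return list with `image`, `labels` (C and P [grade_label()]s) and
#'   `truth` (pupil [circle_region()], spoke angles, spoke and plaque pixel
#'   counts, plaque area fraction).
#' @export
gen_retro <- function(spec) {
  stopifnot(inherits(spec, "retro_spec"))
  with_seed(spec$seed, {
    n <- spec$size
    cx <- n / 2 + runif(1, -2, 2)
    cy <- n / 2 + runif(1, -2, 2)
    r <- spec$radius + runif(1, -2, 2)
    circ <- circle_region(cx, cy, r)
    x <- array(0, dim = c(n, n, 3))
    x <- set_pixels(x, seq_len(n * n), c(18, 12, 10), 2)
    inside <- circle_pixel_mask(n, n, circ)
    pupil_idx <- which(inside)
    x <- set_pixels(x, pupil_idx, c(190, 115, 60), spec$noise_sd)
    ## vertical illumination gradient: top brighter, bottom darker
    rows <- ((pupil_idx - 1L) %% n) + 1L
    shade <- round(spec$gradient_amp * (cy - rows) / r)
    for (ch in 1:3) {
      plane <- x[, , ch]
      plane[pupil_idx] <- clip8(plane[pupil_idx] + shade)
      x[, , ch] <- plane
    }
    dark <- c(75, 45, 30)
    lesion <- matrix(FALSE, n, n)
    n_spokes <- 2L * spec$c_grade
    angles <- numeric(0)
    if (n_spokes > 0) {
      base <- runif(1, 0, 2 * pi)
      angles <- (base + 2 * pi * (seq_len(n_spokes) - 1) / n_spokes +
                 rnorm(n_spokes, 0, 0.03)) %% (2 * pi)
      len0 <- (0.45 + 0.08 * spec$c_grade) * r
      for (ang in angles) {
        len <- len0 * exp(clamped_norm(0.10, 0.25))
        tt <- seq(0.18 * r, 0.18 * r + len, by = 0.4)
        for (t in tt)
          lesion[disc_indices(n, n, cy + t * sin(ang), cx + t * cos(ang),
                              1.2)] <- TRUE
      }
    }
    plaque_frac <- 0.032 * spec$p_grade * exp(clamped_norm(0.08, 0.2))
    if (spec$p_grade > 0) {
      rp <- r * sqrt(plaque_frac)
      pcy <- cy + runif(1, -2, 2); pcx <- cx + runif(1, -2, 2)
      lesion[disc_indices(n, n, pcy, pcx, rp)] <- TRUE
    }
    lesion <- lesion & inside
    x <- set_pixels(x, which(lesion), dark, 4)
    for (i in seq_len(spec$n_flash)) {
      ang <- runif(1, 0, 2 * pi); d <- runif(1, 0.15, 0.55) * r
      idx <- disc_indices(n, n, cy + d * sin(ang), cx + d * cos(ang),
                          runif(1, 2, 3))
      for (ch in 1:3) {
        plane <- x[, , ch]
        plane[idx] <- sample(250:255, length(idx), replace = TRUE)
        x[, , ch] <- plane
      }
    }
    list(image = rgb_image(x),
         labels = list(C = grade_label("C", spec$c_grade),
                       P = grade_label("P", spec$p_grade)),
         truth = list(circle = circ, spoke_angles = angles,
                      n_spokes = n_spokes, n_spoke_px = sum(lesion),
                      plaque_frac = plaque_frac))
  })
}

#' Generate a balanced labelled dataset
#'
#' For every type (NO, NC, C, P) and every grade in the type's range,
#' `n_per_grade` images are generated, each with the other same-modality
#' grade fixed at 0 so every image carries one designated label. The
#' manifest records type, grade, per-image seed and the ground-truth
#' geometry; images regenerate bit-identically from their manifest seeds.
#'
#' @param n_per_grade images per (type, grade) cell, at least 1.
#' @param seed master seed; per-image seeds are drawn from it.
#' @param types subset of `c("NO", "NC", "C", "P")`.
#' @param write_dir optional directory; when given, images are written as
#'   PNG files and the manifest as `manifest.csv`.
#' @param ... overrides passed to [slit_beam_spec()] / [retro_spec()]
#'   (e.g. `noise_sd`), applied to every image.
#' @return list with `images` (named list of [rgb_image()]), `manifest`
#'   (data frame: id, path, type, grade, modality, seed, geometry columns)
#'   and `truths` (named list).
#' @export
gen_dataset <- function(n_per_grade, seed = 1L,
                        types = c("NO", "NC", "C", "P"), write_dir = NULL,
                        ...) {
  stopifnot(n_per_grade >= 1)
  types <- match.arg(types, several.ok = TRUE)
  cells <- do.call(rbind, lapply(types, function(ty) {
    rng <- grade_range(ty)
    expand.grid(type = ty, grade = rng[1]:rng[2], rep = seq_len(n_per_grade),
                stringsAsFactors = FALSE)
  }))
  seeds <- with_seed(seed, sample.int(2^31 - 2, nrow(cells)))
  extra <- list(...)
  images <- list(); truths <- list()
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ty <- cells$type[i]; g <- cells$grade[i]
    id <- sprintf("%s%d_%03d", ty, g, cells$rep[i])
    if (ty %in% c("NO", "NC")) {
      args <- c(list(no_grade = if (ty == "NO") g else 0L,
                     nc_grade = if (ty == "NC") g else 0L,
                     seed = seeds[i]), extra)
      out <- gen_slit_beam(do.call(slit_beam_spec, args))
      geom <- with(out$truth$lens,
                   c(center_x, center_y, semi_axis_x, semi_axis_y))
      modality <- "slit_beam"
      n_spokes <- NA_integer_; plaque_frac <- NA_real_
    } else {
      args <- c(list(c_grade = if (ty == "C") g else 0L,
                     p_grade = if (ty == "P") g else 0L,
                     seed = seeds[i]), extra)
      out <- gen_retro(do.call(retro_spec, args))
      geom <- with(out$truth$circle,
                   c(center_x, center_y, radius, radius))
      modality <- "retro"
      n_spokes <- out$truth$n_spokes
      plaque_frac <- out$truth$plaque_frac
    }
    images[[id]] <- out$image
    truths[[id]] <- out$truth
    rows[[i]] <- data.frame(id = id, path = NA_character_, type = ty,
                            grade = g, modality = modality, seed = seeds[i],
                            geom_cx = geom[1], geom_cy = geom[2],
                            geom_ax = geom[3], geom_ay = geom[4],
                            n_spokes = n_spokes, plaque_frac = plaque_frac,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(write_dir, paste0(manifest$id, ".png"))
    for (i in seq_len(nrow(manifest)))
      write_image(images[[manifest$id[i]]], manifest$path[i])
    write.csv(manifest, file.path(write_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(images = images, manifest = manifest, truths = truths)
}
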