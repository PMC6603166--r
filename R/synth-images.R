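# Seeded generators for download-free pseudo-CLE and pseudo-H&E fixtures.
# Each generator is a pure function of (params, seed) and attaches a
# ground-truth manifest so downstream tests have an exact oracle.

draw_ellipse <- function(canvas, cx, cy, rx, ry, angle, value, mode = "max") {
  h <- nrow(canvas); w <- ncol(canvas)
  r0 <- max(1L, floor(cy - max(rx, ry))); r1 <- min(h, ceiling(cy + max(rx, ry)))
  c0 <- max(1L, floor(cx - max(rx, ry))); c1 <- min(w, ceiling(cx + max(rx, ry)))
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, nrow = length(rows), ncol = length(cols))
  dx <- matrix(cols - cx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  u <- (dx * cos(angle) + dy * sin(angle)) / rx
  v <- (-dx * sin(angle) + dy * cos(angle)) / ry
  inside <- u^2 + v^2 <= 1
  patch <- canvas[rows, cols, drop = FALSE]
  patch[inside] <- if (mode == "max") pmax(patch[inside], value) else value
  canvas[rows, cols] <- patch
  canvas
}

# low-frequency random field in [0,1]: coarse uniform grid, bilinear upscale
smooth_field <- function(size, coarse = 8L) {
  g <- matrix(runif(coarse^2), coarse, coarse)
  img <- stain_image(array(rep(g, 3L), dim = c(coarse, coarse, 3L)))
  unclass(resize_image(img, size, size))[, , 1]
}

#' Generate a pseudo-CLE content image
#'
#' Emulates the structure of a fluorescein-driven confocal laser
#' endomicroscopy micrograph: a dark background with Gaussian noise, bright
#' elliptical cellular textures, and occluding artifacts (dark disks standing
#' in for red blood cells, elongated bright streaks standing in for motion
#' blur) covering roughly `artifact_density` of the area. The image is
#' grayscale, stored with three equal channels as real CLE enters the
#' pipeline.
#'
#' @param size image side length in pixels.
#' @param n_cells number of cellular ellipses.
#' @param cell_radius_range min/max cell radius in pixels.
#' @param background_noise_sd standard deviation of the background noise.
#' @param artifact_density target fraction of area covered by artifacts, in
#'   `[0, 1]`.
#' @param seed integer; the generator is a pure function of seed and params.
#' @return A [stain_image()] with attribute `manifest`: list with `cells`
#'   (tibble of ellipse centers, radii, angles, intensities), `artifacts`
#'   (tibble), and `artifact_fraction` actually covered.
#' @export
make_cle_image <- function(size = 256L, n_cells = 40L,
                           cell_radius_range = c(4, 12),
                           background_noise_sd = 0.05,
                           artifact_density = 0.1, seed = 0L) {
  stopifnot(size >= 16L, n_cells >= 0L, all(cell_radius_range > 0),
            background_noise_sd >= 0,
            artifact_density >= 0, artifact_density <= 1)
  run_with_preserved_rng(seed, {
    canvas <- matrix(0.12, size, size) +
      matrix(rnorm(size^2, sd = background_noise_sd), size, size)
    cells <- tibble::tibble(
      cx = runif(n_cells, 1, size), cy = runif(n_cells, 1, size),
      rx = runif(n_cells, cell_radius_range[1], cell_radius_range[2]),
      ry = runif(n_cells, cell_radius_range[1], cell_radius_range[2]),
      angle = runif(n_cells, 0, pi),
      intensity = runif(n_cells, 0.45, 0.9))
    for (i in seq_len(n_cells)) {
      canvas <- draw_ellipse(canvas, cells$cx[i], cells$cy[i], cells$rx[i],
                             cells$ry[i], cells$angle[i], cells$intensity[i])
    }
    artifacts <- tibble::tibble(cx = numeric(), cy = numeric(), rx = numeric(),
                                ry = numeric(), angle = numeric(),
                                kind = character())
    covered <- matrix(FALSE, size, size)
    while (artifact_density > 0 && mean(covered) < artifact_density &&
           nrow(artifacts) < 200L) {
      kind <- sample(c("disk", "streak"), 1L)
      cx <- runif(1, 1, size); cy <- runif(1, 1, size)
      if (kind == "disk") {            # dark red-blood-cell-like occlusion
        rx <- ry <- runif(1, size / 40, size / 14); angle <- 0
        value <- runif(1, 0.02, 0.08)
      } else {                          # bright elongated blur streak
        rx <- runif(1, size / 8, size / 3); ry <- runif(1, size / 80, size / 30)
        angle <- runif(1, 0, pi); value <- runif(1, 0.75, 0.95)
      }
      canvas <- draw_ellipse(canvas, cx, cy, rx, ry, angle, value, mode = "set")
      covered <- draw_ellipse(covered * 1, cx, cy, rx, ry, angle, 1,
                              mode = "set") > 0
      artifacts <- dplyr::bind_rows(artifacts,
                                    tibble::tibble(cx = cx, cy = cy, rx = rx,
                                                   ry = ry, angle = angle,
                                                   kind = kind))
    }
    img <- stain_image(pmin(pmax(canvas, 0), 1),
                       source_id = sprintf("cle_seed%d", seed))
    attr(img, "manifest") <- list(cells = cells, artifacts = artifacts,
                                  artifact_fraction = mean(covered),
                                  params = list(size = size, n_cells = n_cells,
                                                seed = seed))
    img
  })
}

#' Generate a pseudo-H&E style image
#'
#' Emulates the appearance of a hematoxylin-and-eosin-stained micrograph: a
#' pink-dominant eosin background with low-frequency texture and purple
#' elliptical nuclei. The generator asserts the H&E gamut (mean red channel
#' exceeds mean green channel).
#'
#' @param size image side length in pixels (at least 32).
#' @param n_nuclei number of nuclei ellipses.
#' @param seed integer seed.
#' @return An RGB [stain_image()] with attribute `manifest` (tibble `nuclei`
#'   and the params).
#' @export
make_he_style_image <- function(size = 256L, n_nuclei = 60L, seed = 0L) {
  stopifnot(size >= 32L, n_nuclei >= 0L)
  run_with_preserved_rng(seed, {
    field <- smooth_field(size)
    base <- list(r = 0.93, g = 0.72, b = 0.80)
    px <- array(0, dim = c(size, size, 3L))
    px[, , 1] <- base$r - 0.10 * field + rnorm(size^2, sd = 0.015)
    px[, , 2] <- base$g - 0.18 * field + rnorm(size^2, sd = 0.015)
    px[, , 3] <- base$b - 0.08 * field + rnorm(size^2, sd = 0.015)
    nuclei <- tibble::tibble(
      cx = runif(n_nuclei, 1, size), cy = runif(n_nuclei, 1, size),
      rx = runif(n_nuclei, size / 70, size / 28),
      ry = runif(n_nuclei, size / 70, size / 28),
      angle = runif(n_nuclei, 0, pi),
      shade = runif(n_nuclei, 0, 0.15))
    nucleus_rgb <- c(0.42, 0.22, 0.55)   # hematoxylin purple
    for (i in seq_len(n_nuclei)) {
      for (ch in 1:3) {
        px[, , ch] <- draw_ellipse(px[, , ch], nuclei$cx[i], nuclei$cy[i],
                                   nuclei$rx[i], nuclei$ry[i], nuclei$angle[i],
                                   nucleus_rgb[ch] - nuclei$shade[i],
                                   mode = "set")
      }
    }
    px <- pmin(pmax(px, 0), 1)
    stopifnot(mean(px[, , 1]) > mean(px[, , 2]))  # pink/purple gamut
    img <- stain_image(px, source_id = sprintf("he_seed%d", seed))
    attr(img, "manifest") <- list(nuclei = nuclei,
                                  params = list(size = size,
                                                n_nuclei = n_nuclei,
                                                seed = seed))
    img
  })
}
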