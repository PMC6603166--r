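# Seeded generator for rating tables with planted statistics, so that the
# whole rater-score analysis can be tested against exact ground truth.

default_planted_categories <- function(n_images) {
  if (n_images == 100L) {
    return(c(improved_both = 84L, improved_removed_only = 6L,
             improved_added_only = 5L, degraded_removed_only = 2L,
             degraded_added_only = 2L, degraded_both = 1L, neutral = 0L))
  }
  base <- c(improved_both = 0.84, improved_removed_only = 0.06,
            improved_added_only = 0.05, degraded_removed_only = 0.02,
            degraded_added_only = 0.02, degraded_both = 0.01, neutral = 0)
  counts <- floor(base * n_images)
  counts["improved_both"] <- counts["improved_both"] + n_images - sum(counts)
  stats::setNames(as.integer(counts), names(base))
}

# axis plant: base score and rater jitter that provably keeps the per-image
# mean inside the planted status region
plant_axis_scores <- function(status, base_cell, n_raters, dispersion) {
  if (status == "neutral") {
    scores <- rep(3L, n_raters)
    if (dispersion > 0 && n_raters >= 2L && runif(1) < dispersion) {
      pick <- sample(n_raters, 2L)
      scores[pick[1]] <- 4L
      scores[pick[2]] <- 2L   # zero-sum: mean stays exactly 3
    }
    return(scores)
  }
  base <- if (status == "improved") base_cell else 6L - base_cell
  jitter <- ifelse(runif(n_raters) < dispersion,
                   sample(c(-1L, 1L), n_raters, replace = TRUE), 0L)
  scores <- base + jitter
  if (status == "improved") pmin(pmax(scores, 4L), 6L) else pmin(pmax(scores, 0L), 2L)
}

#' Generate a rating table with planted statistics
#'
#' Emulates the evaluation design of a rater study — `n_raters` raters (five
#' by default) each score `n_images` stylized images (100 by default) on the
#' two 0-6 axes — while planting ground truth that downstream analysis must
#' recover exactly: a per-image improvement category, a modal (added,
#' removed) score cell per color group, and the implied overall modal cell.
#'
#' Images in a category whose axis is "improved" receive rater scores
#' concentrated at the group's modal cell component (jittered scores are
#' clamped to stay above the neutral score); "degraded" axes mirror the modal
#' component below neutral (`6 - modal`); "neutral" axes use zero-sum jitter
#' around 3 so the mean stays exactly 3. `dispersion` is the per-score
#' probability of a +/-1 jitter.
#'
#' @param n_raters number of raters (default 5).
#' @param n_images number of images (default 100).
#' @param modal_cell fallback (added, removed) modal cell for groups not
#'   named in `group_modal_cells`.
#' @param group_modal_cells named list of per-color-group modal cells; the
#'   defaults are the per-group modes the evaluation design targets.
#' @param dispersion per-score jitter probability in `[0, 1)`.
#' @param planted_categories named integer vector over the seven categories
#'   of [categorize_images()], summing to `n_images`. `NULL` picks a default
#'   led by 84 improved-both per 100 images.
#' @param seed integer seed; the generator is pure in (params, seed).
#' @return A validated score tibble of `n_raters * n_images` records with
#'   attribute `manifest`: list with `assignment` (tibble of each image's
#'   color group, category, and base cell) and the parameters.
#' @export
make_rating_table <- function(n_raters = 5L, n_images = 100L,
                              modal_cell = c(5L, 4L),
                              group_modal_cells = list(gray = c(5L, 4L),
                                                       green = c(5L, 5L),
                                                       red = c(5L, 4L),
                                                       intact = c(5L, 4L)),
                              dispersion = 0.15,
                              planted_categories = NULL,
                              seed = 0L) {
  stopifnot(n_raters >= 1L, n_images >= 1L, dispersion >= 0, dispersion < 1)
  if (is.null(planted_categories)) {
    planted_categories <- default_planted_categories(n_images)
  }
  if (!setequal(names(planted_categories), category_levels) ||
      any(planted_categories < 0)) {
    abort(sprintf("`planted_categories` must name exactly: %s",
                  paste(category_levels, collapse = ", ")),
          class = "hestain_domain_error")
  }
  if (sum(planted_categories) != n_images) {
    abort(sprintf("planted category counts sum to %d, not n_images = %d",
                  sum(planted_categories), n_images),
          class = "hestain_generation_error")
  }
  cells <- lapply(color_groups, function(g) {
    cell <- group_modal_cells[[g]] %||% modal_cell
    if (length(cell) != 2L || any(cell < 0) || any(cell > 6)) {
      abort(sprintf("modal cell for group '%s' must be two scores in 0-6", g),
            class = "hestain_domain_error")
    }
    as.integer(cell)
  })
  names(cells) <- color_groups
  # feasibility: an improved plant needs a modal component above neutral
  # (its mirror is then automatically below neutral)
  needs_improved <- any(planted_categories[c("improved_both",
                                             "improved_removed_only",
                                             "improved_added_only",
                                             "degraded_removed_only",
                                             "degraded_added_only",
                                             "degraded_both")] > 0)
  if (needs_improved && any(vapply(cells, function(x) any(x <= 3L), logical(1)))) {
    abort("infeasible plant: every group modal cell component must exceed 3",
          class = "hestain_generation_error")
  }

  status_for <- list(
    improved_both = c("improved", "improved"),
    improved_removed_only = c("neutral", "improved"),
    improved_added_only = c("improved", "neutral"),
    degraded_removed_only = c("improved", "degraded"),
    degraded_added_only = c("degraded", "improved"),
    degraded_both = c("degraded", "degraded"),
    neutral = c("neutral", "neutral"))

  image_ids <- sprintf("img%03d", seq_len(n_images))
  rater_ids <- sprintf("rater%d", seq_len(n_raters))
  groups <- assign_color_groups(image_ids, seed = seed)

  run_with_preserved_rng(seed + 1L, {
    category <- sample(rep(names(planted_categories), planted_categories))
    assignment <- dplyr::left_join(
      tibble::tibble(image_id = image_ids, category = category),
      groups, by = "image_id")
    assignment$base_added <- NA_integer_
    assignment$base_removed <- NA_integer_
    rows <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      g <- as.character(assignment$group[i])
      cell <- cells[[g]]
      st <- status_for[[assignment$category[i]]]
      added <- plant_axis_scores(st[1], cell[1], n_raters, dispersion)
      removed <- plant_axis_scores(st[2], cell[2], n_raters, dispersion)
      assignment$base_added[i] <- if (st[1] == "neutral") 3L else
        if (st[1] == "improved") cell[1] else 6L - cell[1]
      assignment$base_removed[i] <- if (st[2] == "neutral") 3L else
        if (st[2] == "improved") cell[2] else 6L - cell[2]
      rows[[i]] <- tibble::tibble(rater_id = rater_ids,
                                  image_id = image_ids[i],
                                  color_group = g,
                                  added_score = added,
                                  removed_score = removed)
    }
    tab <- validate_scores(dplyr::bind_rows(rows), context = "generated table")
    attr(tab, "manifest") <- list(
      assignment = assignment,
      params = list(n_raters = n_raters, n_images = n_images,
                    group_modal_cells = cells, dispersion = dispersion,
                    planted_categories = planted_categories, seed = seed))
    tab
  })
}

#' Generate a paired sample with a planted mean gap
#'
#' Simulates paired per-rating scores whose difference `added - removed` is
#' normal with the given mean gap and standard deviation — the fixture used
#' to check that the paired t-test detects a planted effect.
#'
#' @param n number of pairs.
#' @param gap true mean of `added - removed`.
#' @param sd standard deviation of the paired difference.
#' @param seed integer seed.
#' @return A tibble with numeric columns `added` and `removed`.
#' @export
make_paired_gap_sample <- function(n = 500L, gap = 0.8, sd = 1, seed = 0L) {
  stopifnot(n >= 2L, sd >= 0)
  run_with_preserved_rng(seed, {
    removed <- rnorm(n, mean = 3, sd = 0.5)
    tibble::tibble(removed = removed,
                   added = removed + rnorm(n, mean = gap, sd = sd))
  })
}
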