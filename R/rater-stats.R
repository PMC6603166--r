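score_levels <- 0:6
color_groups <- c("gray", "green", "red", "intact")

validate_scores <- function(df, context = "score table") {
  required <- c("rater_id", "image_id", "color_group", "added_score",
                "removed_score")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s lacks column(s): %s", context,
                  paste(missing, collapse = ", ")),
          class = "hestain_validation_error")
  }
  bad_group <- which(!df$color_group %in% color_groups)
  if (length(bad_group)) {
    abort(sprintf("%s row %d: unknown color group '%s'", context,
                  bad_group[1], df$color_group[bad_group[1]]),
          class = "hestain_validation_error")
  }
  for (axis in c("added_score", "removed_score")) {
    v <- df[[axis]]
    bad <- which(!is.finite(v) | v != as.integer(v) | v < 0 | v > 6)
    if (length(bad)) {
      abort(sprintf("%s row %d: %s %s outside the 0-6 scale", context,
                    bad[1], axis, v[bad[1]]),
            class = "hestain_validation_error")
    }
  }
  dup <- which(duplicated(df[c("rater_id", "image_id")]))
  if (length(dup)) {
    abort(sprintf("%s row %d: duplicate (rater_id, image_id) pair (%s, %s)",
                  context, dup[1], df$rater_id[dup[1]], df$image_id[dup[1]]),
          class = "hestain_validation_error")
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(rater_id = as.character(.data$rater_id),
                  image_id = as.character(.data$image_id),
                  color_group = factor(as.character(.data$color_group),
                                       levels = color_groups),
                  added_score = as.integer(.data$added_score),
                  removed_score = as.integer(.data$removed_score))
}

#' Read a dual-axis rater score table
#'
#' Reads and validates a CSV of rating events. Each record is one rater's
#' judgement of one stylized image on two 0-6 axes: `added_score` (did the
#' stylization add structures that were hard to notice — positive — or unreal
#' ones — negative) and `removed_score` (did it remove artifacts — positive —
#' or critical structures — negative). 3 means no significant impact.
#'
#' @param path CSV file with header
#'   `rater_id,image_id,color_group,added_score,removed_score`.
#' @return A validated tibble of score records.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read scores: no such file '%s'", path),
          class = "hestain_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_scores(df, context = basename(path))
}

#' Write a score table as CSV
#' @param scores validated score tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

filter_group <- function(scores, group) {
  if (is.null(group)) return(scores)
  if (!group %in% color_groups) {
    abort(sprintf("unknown color group '%s'", group),
          class = "hestain_domain_error")
  }
  dplyr::filter(scores, .data$color_group == group)
}

#' Histogram of scores on one axis
#'
#' @param scores validated score tibble (see [read_scores()]).
#' @param axis `"added"` or `"removed"`.
#' @param group optional color group filter (`"gray"`, `"green"`, `"red"`,
#'   `"intact"`).
#' @return A tibble with columns `score` (0-6) and `n`; the counts sum to the
#'   number of selected records.
#' @export
score_histogram <- function(scores, axis = c("added", "removed"),
                            group = NULL) {
  axis <- match.arg(axis)
  scores <- validate_scores(scores)
  sel <- filter_group(scores, group)
  if (nrow(sel) == 0L) {
    abort("no records after filtering", class = "hestain_domain_error")
  }
  v <- sel[[paste0(axis, "_score")]]
  tibble::tibble(score = score_levels,
                 n = vapply(score_levels, function(k) sum(v == k), integer(1)))
}

#' Score co-occurrence (intensity) map
#'
#' 7x7 table counting how many times a rater scored an image with each
#' (added, removed) score combination.
#'
#' @inheritParams score_histogram
#' @return An object of class `intensity_map`: a 7x7 integer matrix with
#'   added score 0-6 on rows and removed score 0-6 on columns, attribute
#'   `n_records`.
#' @export
intensity_map <- function(scores, group = NULL) {
  scores <- validate_scores(scores)
  sel <- filter_group(scores, group)
  if (nrow(sel) == 0L) {
    abort("no records after filtering", class = "hestain_domain_error")
  }
  counts <- matrix(0L, 7L, 7L, dimnames = list(added = score_levels,
                                               removed = score_levels))
  for (i in seq_len(nrow(sel))) {
    a <- sel$added_score[i] + 1L; r <- sel$removed_score[i] + 1L
    counts[a, r] <- counts[a, r] + 1L
  }
  structure(counts, n_records = nrow(sel), class = c("intensity_map", "matrix"))
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %d rating events (rows added 0-6, cols removed 0-6)\n",
              attr(x, "n_records")))
  print(unclass(x)[, ])
  invisible(x)
}

#' @method tidy intensity_map
#' @export
tidy.intensity_map <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(added = rep(score_levels, times = 7L),
                 removed = rep(score_levels, each = 7L),
                 n = as.integer(m))
}

#' @method autoplot intensity_map
#' @export
autoplot.intensity_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$added, y = .data$removed,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "added structures score", y = "removed artifacts score",
                  fill = "count")
}

#' Most frequent score combination
#'
#' The (added, removed) cell with the highest count in an intensity map.
#' Ties are broken toward the larger added score, then the larger removed
#' score, and flagged.
#'
#' @param map an [intensity_map()].
#' @return A one-row tibble with `added`, `removed`, `count`, `tied`.
#' @export
modal_combination <- function(map) {
  m <- unclass(map)
  if (sum(m) == 0L) {
    abort("intensity map holds no records", class = "hestain_domain_error")
  }
  top <- max(m)
  hits <- which(m == top, arr.ind = TRUE)
  # tie-break: larger added (row), then larger removed (col)
  ord <- order(-hits[, 1], -hits[, 2])
  pick <- hits[ord[1], ]
  tibble::tibble(added = as.integer(pick[1] - 1L),
                 removed = as.integer(pick[2] - 1L),
                 count = as.integer(top),
                 tied = nrow(hits) > 1L)
}

#' One-way chi-square test against the uniform distribution
#'
#' `X^2 = sum (O_i - E)^2 / E` with `E = sum(O) / k`, `df = k - 1`, and an
#' upper-tail p-value. Used to test whether ratings above the neutral score
#' outnumber the rest beyond chance.
#'
#' @param counts non-negative integer observed counts, at least 2 bins.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_uniform <- function(counts) {
  if (length(counts) < 2L || any(counts < 0) || !all(is.finite(counts))) {
    abort("`counts` must be >= 2 finite non-negative values",
          class = "hestain_domain_error")
  }
  total <- sum(counts)
  if (total <= 0) {
    abort("all counts are zero", class = "hestain_domain_error")
  }
  k <- length(counts)
  e <- total / k
  statistic <- sum((counts - e)^2 / e)
  df <- k - 1L
  tibble::tibble(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE))
}

#' Paired t-test between the two score axes
#'
#' Two-sided paired t-test on `d = added - removed`, pairing by rating event:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `sd` the n-1 sample standard
#' deviation and `df = n - 1`.
#'
#' @param added,removed equal-length numeric vectors of paired scores.
#' @return A one-row tibble with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t_test <- function(added, removed) {
  n <- length(added)
  if (n < 2L || length(removed) != n) {
    abort("`added` and `removed` must have equal length >= 2",
          class = "hestain_domain_error")
  }
  d <- added - removed
  s <- sd(d)
  if (s == 0) {
    abort("differences have zero variance; the paired t-test is degenerate",
          class = "hestain_degenerate_error")
  }
  mean_diff <- mean(d)
  t_stat <- mean_diff / (s / sqrt(n))
  df <- n - 1L
  tibble::tibble(t = t_stat, df = df,
                 p_value = 2 * pt(abs(t_stat), df, lower.tail = FALSE),
                 mean_diff = mean_diff)
}

category_levels <- c("improved_both", "improved_removed_only",
                     "improved_added_only", "degraded_removed_only",
                     "degraded_added_only", "degraded_both", "neutral")

axis_status <- function(mean_score) {
  dplyr::case_when(mean_score > 3 ~ "improved",
                   mean_score < 3 ~ "degraded",
                   TRUE ~ "neutral")
}

assign_category <- function(added_status, removed_status) {
  dplyr::case_when(
    added_status == "improved" & removed_status == "improved" ~ "improved_both",
    added_status == "degraded" & removed_status == "degraded" ~ "degraded_both",
    added_status == "degraded" ~ "degraded_added_only",
    removed_status == "degraded" ~ "degraded_removed_only",
    added_status == "improved" ~ "improved_added_only",
    removed_status == "improved" ~ "improved_removed_only",
    TRUE ~ "neutral")
}

#' Categorize images by mean rater score on both axes
#'
#' Averages each image's scores over raters on both axes and classifies the
#' image by the pair of axis statuses: mean above 3 is improvement on that
#' axis, below 3 degradation, exactly 3 neutral. Both axes improved gives
#' `improved_both`, both degraded `degraded_both`; a single degraded axis
#' gives the `degraded_<axis>_only` cell regardless of the other axis (so a
#' mixed improved/degraded image counts as degraded on the offending axis);
#' a single improved axis with the other neutral gives
#' `improved_<axis>_only`; otherwise `neutral`. The seven categories
#' partition the image set exactly.
#'
#' @param scores validated score tibble.
#' @return An object of class `image_categories`: list with `images` (tibble
#'   of per-image means and category) and `counts` (tibble of the seven
#'   category counts, summing to the number of images).
#' @export
categorize_images <- function(scores) {
  scores <- validate_scores(scores)
  if (nrow(scores) == 0L) {
    abort("no score records", class = "hestain_domain_error")
  }
  per_image <- scores |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(mean_added = mean(.data$added_score),
                     mean_removed = mean(.data$removed_score),
                     .groups = "drop") |>
    dplyr::mutate(
      category = factor(assign_category(axis_status(.data$mean_added),
                                        axis_status(.data$mean_removed)),
                        levels = category_levels))
  counts <- per_image |>
    dplyr::count(.data$category, .drop = FALSE, name = "n")
  structure(list(images = per_image, counts = counts),
            class = "image_categories")
}

#' @export
print.image_categories <- function(x, ...) {
  cat(sprintf("<image_categories> %d images\n", nrow(x$images)))
  print(x$counts)
  invisible(x)
}

#' @method tidy image_categories
#' @export
tidy.image_categories <- function(x, ...) x$images

#' @method glance image_categories
#' @export
glance.image_categories <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "category", values_from = "n")
}

#' Two-bin improvement counts for one axis
#'
#' Counts images whose mean score on the given axis is above 3 (improved)
#' versus not, the contrast fed to [chi_square_uniform()].
#'
#' @param scores validated score tibble.
#' @param axis `"added"` or `"removed"`.
#' @return Named integer vector `c(improved, not_improved)`.
#' @export
improvement_counts <- function(scores, axis = c("added", "removed")) {
  axis <- match.arg(axis)
  cats <- categorize_images(scores)
  m <- cats$images[[paste0("mean_", axis)]]
  c(improved = sum(m > 3), not_improved = sum(m <= 3))
}
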