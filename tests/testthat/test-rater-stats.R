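test_that("read_scores validates ranges, uniqueness, and groups", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "scores.csv")
  ok <- tiny_score_table()
  write_scores(ok, p)
  rt <- read_scores(p)
  expect_equal(nrow(rt), 6L)
  expect_s3_class(rt$color_group, "factor")

  bad <- ok; bad$added_score[2] <- 7L
  write_scores(bad, p)
  expect_error(read_scores(p), class = "hestain_validation_error")

  dup <- dplyr::bind_rows(ok, ok[1, ])
  write_scores(dup, p)
  expect_error(read_scores(p), class = "hestain_validation_error")

  badgroup <- ok; badgroup$color_group[1] <- "sepia"
  write_scores(badgroup, p)
  expect_error(read_scores(p), class = "hestain_validation_error")

  big <- make_rating_table(seed = 1)
  write_scores(big, p)
  expect_equal(nrow(read_scores(p)), 500L)   # 5 raters x 100 images
})

test_that("score histograms count and conserve records", {
  tab <- tiny_score_table()
  h <- score_histogram(tab, "added")
  expect_equal(h$n, c(0L, 0L, 0L, 1L, 2L, 1L, 2L))
  expect_equal(sum(h$n), nrow(tab))
  hg <- score_histogram(tab, "added", group = "gray")
  expect_equal(sum(hg$n), 2L)
  expect_equal(hg$n[5 + 1], 1L)   # the gray records scored 4 and 5
  expect_error(score_histogram(tab, "added", group = "intact"),
               class = "hestain_domain_error")
})

test_that("intensity map counts co-occurrences and cross-checks histograms", {
  tab <- tiny_score_table()
  m <- intensity_map(tab)
  expect_equal(sum(m), nrow(tab))
  expect_equal(unclass(m)[4 + 1, 4 + 1], 1L)   # one record scored (4,4)
  # marginal over removed equals the added-axis histogram
  expect_equal(as.integer(rowSums(unclass(m))), score_histogram(tab, "added")$n)
  expect_equal(as.integer(colSums(unclass(m))), score_histogram(tab, "removed")$n)

  single <- tab[3, ]
  ms <- intensity_map(single)
  expect_equal(unclass(ms)[6 + 1, 4 + 1], 1L)
  expect_equal(sum(ms), 1L)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(sum(tidy(m)$n), nrow(tab))
})

test_that("modal_combination picks the max and applies the tie rule", {
  tab <- make_rating_table(seed = 3)
  m <- intensity_map(tab)
  top <- modal_combination(m)
  expect_equal(unclass(m)[top$added + 1, top$removed + 1], max(unclass(m)))

  tie <- matrix(0L, 7, 7); tie[5 + 1, 4 + 1] <- 3L; tie[4 + 1, 5 + 1] <- 3L
  tie_map <- structure(tie, n_records = 6L, class = c("intensity_map", "matrix"))
  res <- modal_combination(tie_map)
  expect_equal(c(res$added, res$removed), c(5L, 4L))  # larger added wins
  expect_true(res$tied)

  uni <- structure(matrix(1L, 7, 7), n_records = 49L,
                   class = c("intensity_map", "matrix"))
  res_u <- modal_combination(uni)
  expect_equal(c(res_u$added, res_u$removed), c(6L, 6L))
  expect_true(res_u$tied)
})

test_that("chi_square_uniform matches closed forms and stats::chisq.test", {
  expect_equal(chi_square_uniform(c(50, 50))$statistic, 0)
  expect_equal(chi_square_uniform(c(50, 50))$df, 1L)
  expect_equal(chi_square_uniform(c(90, 10))$statistic, 64)
  expect_equal(chi_square_uniform(c(30, 30, 30))$statistic, 0)
  expect_equal(chi_square_uniform(c(30, 30, 30))$df, 2L)

  set.seed(19)
  for (rep in 1:25) {
    k <- sample(2:7, 1)
    counts <- rpois(k, lambda = 20) + 1L
    mine <- chi_square_uniform(counts)
    ref <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / k, k)))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
  expect_error(chi_square_uniform(c(0, 0)), class = "hestain_domain_error")
  expect_error(chi_square_uniform(5), class = "hestain_domain_error")
})

test_that("paired_t_test matches hand arithmetic and stats::t.test", {
  res <- paired_t_test(c(1, 2, 3), c(0, 0, 0))   # d = (1, 2, 3)
  expect_equal(res$mean_diff, 2)
  expect_equal(res$df, 2L)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)

  set.seed(23)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    a <- rnorm(n, mean = 4); r <- rnorm(n, mean = 3.5)
    mine <- paired_t_test(a, r)
    ref <- stats::t.test(a, r, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(mine$mean_diff, unname(ref$estimate), tolerance = 1e-10)
  }
  expect_error(paired_t_test(c(2, 2, 2), c(1, 1, 1)),
               class = "hestain_degenerate_error")
  expect_error(paired_t_test(1, 1), class = "hestain_domain_error")
})

test_that("categorize_images partitions by the dual-axis status pair", {
  mk <- function(id, added, removed) {
    tibble::tibble(rater_id = sprintf("r%d", seq_along(added)), image_id = id,
                   color_group = "gray", added_score = added,
                   removed_score = removed)
  }
  tab <- dplyr::bind_rows(
    mk("both", c(5L, 5L), c(4L, 4L)),        # means (5, 4): improved both
    mk("mixed", c(2L, 2L), c(4L, 4L)),       # (2, 4): added degraded
    mk("radd", c(3L, 3L), c(5L, 5L)),        # (3, 5): removed-only improvement
    mk("neut", c(3L, 3L), c(3L, 3L)),        # (3, 3): neutral
    mk("dboth", c(1L, 1L), c(2L, 2L)))       # (1, 2): degraded both
  cats <- categorize_images(tab)
  got <- setNames(as.character(cats$images$category), cats$images$image_id)
  expect_equal(got[["both"]], "improved_both")
  expect_equal(got[["mixed"]], "degraded_added_only")
  expect_equal(got[["radd"]], "improved_removed_only")
  expect_equal(got[["neut"]], "neutral")
  expect_equal(got[["dboth"]], "degraded_both")
  expect_equal(sum(cats$counts$n), 5L)       # categories partition the images
  expect_s3_class(glance(cats), "tbl_df")
})
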