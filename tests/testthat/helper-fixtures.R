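# shared fixtures and independent oracles

random_feature_map <- function(channels, h, w) {
  array(rnorm(h * w * channels), dim = c(h, w, channels))
}

# explicit double-loop Gram oracle: G[i,j] = sum over positions of Fi * Fj
gram_oracle <- function(fmap) {
  d <- dim(fmap)
  f <- matrix(fmap, nrow = d[1] * d[2], ncol = d[3])
  cc <- ncol(f)
  g <- matrix(0, cc, cc)
  for (i in seq_len(cc)) {
    for (j in seq_len(cc)) {
      s <- 0
      for (p in seq_len(nrow(f))) s <- s + f[p, i] * f[p, j]
      g[i, j] <- s
    }
  }
  g
}

# independent scalar recomputation of the composite loss
loss_oracle <- function(ct, cs, gt_list, gs_list, alpha, w, m_list) {
  content <- 0.5 * sum((ct - cs)^2)
  style <- 0
  for (i in seq_along(gt_list)) {
    cc <- nrow(gt_list[[i]])
    style <- style + w[i] * sum((gt_list[[i]] - gs_list[[i]])^2) /
      (4 * cc^2 * m_list[[i]]^2)
  }
  content + alpha * style
}

# enumerate all height-out windows and pick the centered one with slack on
# the bottom/right (independent of the center_crop index arithmetic)
crop_window_oracle <- function(d, out) {
  starts <- seq_len(d - out + 1L)
  slack_top <- starts - 1L
  slack_bottom <- d - out - slack_top
  ok <- which(slack_bottom >= slack_top & (slack_bottom - slack_top) <= 1L)
  starts[ok[1]]
}

tiny_score_table <- function() {
  tibble::tibble(
    rater_id = rep(c("r1", "r2"), each = 3),
    image_id = rep(c("a", "b", "c"), times = 2),
    color_group = rep(c("gray", "green", "red"), times = 2),
    added_score = c(4L, 4L, 6L, 5L, 3L, 6L),
    removed_score = c(4L, 5L, 4L, 4L, 3L, 5L))
}

expect_monotone_nonincreasing <- function(x) {
  expect_true(all(diff(x) <= 0))
}
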