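test_that("gram_matrix matches the double-loop oracle on random maps", {
  set.seed(101)
  for (rep in 1:25) {
    cc <- sample(1:6, 1); h <- sample(1:4, 1); w <- sample(1:4, 1)
    fmap <- random_feature_map(cc, h, w)
    g <- gram_matrix(fmap)
    o <- gram_oracle(fmap)
    expect_lt(max(abs(g$values - o)) / max(max(abs(o)), 1e-12), 1e-10)
    expect_equal(g$n_positions, h * w)
    expect_equal(g$n_channels, cc)
  }
})

test_that("gram matrices are symmetric, PSD, and position-invariant", {
  set.seed(55)
  for (rep in 1:10) {
    fmap <- random_feature_map(sample(2:5, 1), 3, 4)
    g <- gram_matrix(fmap)$values
    expect_equal(g, t(g))
    expect_true(all(diag(g) >= 0))
    expect_gt(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    # permuting spatial positions leaves the Gram unchanged
    d <- dim(fmap)
    f <- matrix(fmap, nrow = d[1] * d[2])
    perm <- f[sample(nrow(f)), , drop = FALSE]
    expect_equal(gram_matrix(perm)$values, g, tolerance = 1e-12)
  }
  # hand example: two channels, orthogonal unit activations -> identity
  f <- rbind(c(1, 0), c(0, 1))
  expect_equal(gram_matrix(f)$values, diag(2))
  # all-zero map -> zero Gram
  expect_equal(gram_matrix(array(0, dim = c(2, 2, 3)))$values, matrix(0, 3, 3))
  expect_error(gram_matrix(matrix(c(1, NaN), 1)), class = "hestain_numeric_error")
})

test_that("content and style representations project the feature map set", {
  bb <- build_test_backbone(0)
  img <- make_cle_image(size = 32, seed = 1)
  fm <- extract_features(img, bb)
  cr <- content_representation(fm)
  expect_identical(cr$activations, fm[["Conv4_2"]])
  sr <- style_representation(fm)
  expect_length(sr$grams, 5L)
  expect_equal(vapply(sr$grams, `[[`, character(1), "layer"),
               sprintf("ReLU%d_1", 1:5))

  truncated <- fm[c("ReLU1_1", "ReLU2_1")]
  class(truncated) <- "feature_map_set"
  expect_error(content_representation(truncated), class = "hestain_config_error")
  expect_error(style_representation(truncated), class = "hestain_config_error")
})

test_that("mirror-symmetric tied kernels give equal layer-1 grams for mirrored input", {
  # kernel symmetric in the column (mirror) direction, shared across channels
  k <- array(0, dim = c(3, 3, 3, 2))
  base <- matrix(c(0.2, -0.4, 0.2,
                   0.5,  1.0, 0.5,
                  -0.3,  0.1, -0.3), 3, 3, byrow = TRUE)
  for (cin in 1:3) for (cout in 1:2) k[, , cin, cout] <- base * cout
  layers <- list(
    hestain:::conv_layer("Conv1_1", hestain:::pack_kernel(k), 3L),
    list(name = "ReLU1_1", type = "relu"))
  bb <- hestain:::new_backbone(layers,
                               preprocess = list(mean = rep(0, 3), sd = rep(1, 3)),
                               kind = "test")
  set.seed(77)
  px <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
  mir <- px[, 20:1, , drop = FALSE]
  g1 <- gram_matrix(extract_features(stain_image(px), bb, layers = "ReLU1_1")[[1]])
  g2 <- gram_matrix(extract_features(stain_image(mir), bb, layers = "ReLU1_1")[[1]])
  expect_equal(g1$values, g2$values, tolerance = 1e-12)
})

test_that("total_loss satisfies its identities and matches a scalar oracle", {
  set.seed(31)
  ct <- array(rnorm(8), dim = c(2, 2, 2))
  cs <- array(rnorm(8), dim = c(2, 2, 2))
  mk_style <- function(maps) {
    structure(list(grams = lapply(seq_along(maps), function(i) {
      gram_matrix(maps[[i]], layer = paste0("L", i))
    })), class = "style_representation")
  }
  maps_t <- list(random_feature_map(2, 2, 2), random_feature_map(3, 2, 1))
  maps_s <- list(random_feature_map(2, 2, 2), random_feature_map(3, 2, 1))
  cw <- function(a) structure(list(activations = a, layer = "Conv4_2"),
                              class = "content_representation")
  w <- loss_weights(alpha = 100, layer_weights = c(0.2, 0.8))

  # zero at identity
  res0 <- total_loss(cw(ct), cw(ct), mk_style(maps_t), mk_style(maps_t), w)
  expect_equal(res0$total, 0)

  # alpha = 0 reduces to the content term
  w0 <- loss_weights(alpha = 0, layer_weights = c(0.2, 0.8))
  resc <- total_loss(cw(ct), cw(cs), mk_style(maps_t), mk_style(maps_s), w0)
  expect_equal(resc$total, resc$content)
  expect_equal(resc$content, 0.5 * sum((ct - cs)^2))

  # full loss against the independent scalar oracle
  res <- total_loss(cw(ct), cw(cs), mk_style(maps_t), mk_style(maps_s), w)
  expected <- loss_oracle(ct, cs,
                          lapply(maps_t, gram_oracle), lapply(maps_s, gram_oracle),
                          alpha = 100, w = c(0.2, 0.8), m_list = list(4, 2))
  expect_lt(abs(res$total - expected) / max(expected, 1e-12), 1e-10)
  expect_gte(res$total, 0)

  # shape mismatch names the layer
  bad <- cw(array(rnorm(4), dim = c(2, 1, 2)))
  expect_error(total_loss(bad, cw(cs), mk_style(maps_t), mk_style(maps_s), w),
               class = "hestain_dimension_error")
})

test_that("loss is non-negative and zero only at matched representations", {
  set.seed(61)
  for (rep in 1:10) {
    cc <- sample(2:4, 1)
    ct <- random_feature_map(cc, 2, 3); cs <- random_feature_map(cc, 2, 3)
    st <- list(random_feature_map(cc, 2, 2)); ss <- list(random_feature_map(cc, 2, 2))
    mk <- function(maps) structure(list(grams = lapply(maps, gram_matrix)),
                                   class = "style_representation")
    cw <- function(a) structure(list(activations = a, layer = "x"),
                                class = "content_representation")
    w <- loss_weights(alpha = runif(1, 0, 50), layer_weights = runif(1))
    expect_gte(total_loss(cw(ct), cw(cs), mk(st), mk(ss), w)$total, 0)
    expect_equal(total_loss(cw(ct), cw(ct), mk(st), mk(st), w)$total, 0)
  }
})

test_that("stylize reduces the loss and leaves its inputs untouched", {
  bb <- build_test_backbone(0)
  content <- make_cle_image(size = 32, seed = 1)
  style <- make_he_style_image(size = 32, seed = 2)
  content_before <- unclass(content)[, , ]
  weights_before <- lapply(bb$layers, function(l) l$wmat)

  cfg <- transfer_config(n_iterations = 15)
  res <- stylize(content, style, bb, cfg)

  expect_s3_class(res$image, "stain_image")
  expect_equal(dim(res$image), dim(content))
  expect_equal(res$initial$content, 0)                    # content-copy init
  expect_lt(res$final$total, res$initial$total)
  expect_lt(res$final$style, res$initial$style)
  expect_monotone_nonincreasing(res$trace$total)
  expect_lte(nrow(res$trace), cfg$n_iterations + 0)

  # source immutability
  expect_equal(unclass(content)[, , ], content_before)
  expect_identical(lapply(bb$layers, function(l) l$wmat), weights_before)

  # tidy/glance accessors
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$final_loss, res$final$total)
})

test_that("stylize at the self-style fixed point returns the input", {
  bb <- build_test_backbone(3)
  img <- make_cle_image(size = 24, seed = 5)
  res <- stylize(img, img, bb, transfer_config(n_iterations = 10))
  expect_equal(res$initial$total, 0)
  expect_equal(max(abs(unclass(res$image) - unclass(img))), 0)
})

test_that("noise initialization is seeded and reproducible", {
  bb <- build_test_backbone(0)
  content <- make_cle_image(size = 16, seed = 1)
  style <- make_he_style_image(size = 32, seed = 2)
  cfg <- transfer_config(n_iterations = 3, init = "noise", init_seed = 9)
  r1 <- stylize(content, style, bb, cfg)
  r2 <- stylize(content, style, bb, cfg)
  expect_equal(unclass(r1$image)[, , ], unclass(r2$image)[, , ])
  expect_gt(r1$initial$content, 0)
})
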