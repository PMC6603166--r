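test_that("PNG and TIFF load with rescaling and channel replication", {
  dir <- withr::local_tempdir()
  # 8-bit grayscale PNG with known byte values
  gray <- matrix(c(0, 128, 255, 17) / 255, 2, 2)
  p1 <- file.path(dir, "gray.png")
  png::writePNG(gray, p1)
  img <- load_image(p1)
  expect_s3_class(img, "stain_image")
  expect_equal(dim(img), c(2L, 2L, 3L))
  expect_equal(unclass(img)[1, 2, ], rep(1, 3))            # byte 255 -> 1
  expect_equal(unclass(img)[2, 1, ], rep(128 / 255, 3))
  expect_equal(max(apply(unclass(img), c(1, 2), max) -
                   apply(unclass(img), c(1, 2), min)), 0)  # channels equal

  # 8-bit RGB PNG
  rgb <- array(0, dim = c(1, 1, 3)); rgb[1, 1, ] <- c(0, 128, 255) / 255
  p2 <- file.path(dir, "rgb.png")
  png::writePNG(rgb, p2)
  expect_equal(as.numeric(unclass(load_image(p2))[1, 1, ]),
               c(0, 128 / 255, 1))

  # 16-bit TIFF, max value maps to 1
  t1 <- file.path(dir, "deep.tiff")
  tiff::writeTIFF(matrix(c(0, 1, 0.5, 1), 2, 2), t1, bits.per.sample = 16L)
  img16 <- load_image(t1)
  expect_equal(unclass(img16)[2, 1, ], rep(1, 3))   # sample 65535 -> 1
  expect_equal(unclass(img16)[1, 2, ], rep(0.5, 3), tolerance = 1 / 65535)

  expect_error(load_image(file.path(dir, "absent.png")),
               class = "hestain_io_error")
  writeLines("not an image", file.path(dir, "bad.txt"))
  expect_error(load_image(file.path(dir, "bad.txt")),
               class = "hestain_format_error")
})

test_that("save_image quantizes with round-half-away-from-zero and clamps", {
  dir <- withr::local_tempdir()
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- 1
  px[1, 2, ] <- 0.5
  px[1, 3, ] <- 0   # clamp case exercised separately below
  p <- file.path(dir, "q.png")
  save_image(stain_image(px), p)
  bytes <- png::readPNG(p) * 255
  expect_equal(as.numeric(bytes[1, 1, ]), c(255, 255, 255))
  expect_equal(as.numeric(bytes[1, 2, ]), c(128, 128, 128))  # round(127.5) -> 128

  # out-of-range values are clamped before quantization
  raw <- array(c(-0.2, 1.3, 0.5), dim = c(1, 1, 3))
  img <- structure(raw, source_id = "clamp", class = "stain_image")
  save_image(img, p)
  expect_equal(as.numeric(png::readPNG(p)[1, 1, ] * 255), c(0, 255, 128))

  expect_error(save_image(stain_image(px), file.path(dir, "nodir", "x.png")),
               class = "hestain_io_error")
})

test_that("load -> save -> load round-trips within 1/255 per channel", {
  dir <- withr::local_tempdir()
  set.seed(11)
  img <- stain_image(array(runif(12 * 12 * 3), dim = c(12, 12, 3)))
  p <- file.path(dir, "rt.png")
  save_image(img, p)
  back <- load_image(p)
  expect_lt(max(abs(unclass(back) - unclass(img))), 1 / 255 + 1e-12)
  # a second round-trip is exact (already quantized)
  save_image(back, p)
  expect_equal(unclass(load_image(p))[, , ], unclass(back)[, , ])
})

test_that("center_crop follows the slack rule and composes", {
  set.seed(3)
  img <- stain_image(array(runif(512 * 512 * 3), dim = c(512, 512, 3)))
  half <- center_crop(img, 0.5)
  expect_equal(dim(half)[1:2], c(256L, 256L))
  expect_equal(unclass(half)[, , ], unclass(img)[129:384, 129:384, ])

  expect_equal(unclass(center_crop(img, 1))[, , ], unclass(img)[, , ])

  # 5x5 at 0.6 -> 3x3 window starting at the oracle-derived offset
  small <- stain_image(array(runif(75), dim = c(5, 5, 3)))
  out <- center_crop(small, 0.6)
  start <- crop_window_oracle(5L, 3L)
  expect_equal(start, 2L)
  expect_equal(unclass(out)[, , ], unclass(small)[start:(start + 2), start:(start + 2), ])

  # odd slack goes to the bottom/right
  rect <- stain_image(array(runif(6 * 4 * 3), dim = c(6, 4, 3)))
  out2 <- center_crop(rect, 0.5)     # 6 -> 3: slack 3, top 1, bottom 2
  expect_equal(unclass(out2)[, , ],
               unclass(rect)[crop_window_oracle(6L, 3L) + 0:2,
                             crop_window_oracle(4L, 2L) + 0:1, ])

  # composition of crops matches the round arithmetic
  ab <- center_crop(center_crop(img, 0.7), 0.4)
  expect_equal(dim(ab)[1], round(0.4 * round(0.7 * 512)))

  expect_error(center_crop(img, 0), class = "hestain_domain_error")
  expect_error(center_crop(img, 1.2), class = "hestain_domain_error")
})

test_that("stain_image enforces range, finiteness, and layout", {
  expect_error(stain_image(array(2, dim = c(1, 1, 3))),
               class = "hestain_domain_error")
  expect_error(stain_image(array(NA_real_, dim = c(1, 1, 3))),
               class = "hestain_numeric_error")
  expect_error(stain_image(array(0.5, dim = c(1, 1, 2))),
               class = "hestain_format_error")
  g <- stain_image(matrix(0.3, 2, 2))
  expect_equal(dim(g), c(2L, 2L, 3L))
})
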