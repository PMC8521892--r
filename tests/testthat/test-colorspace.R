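test_that("rgb_to_hsb reproduces the canonical anchor colors", {
  expect_equal(rgb_to_hsb(single_px(255, 0, 0))[1, 1, ], c(0, 255, 255))
  expect_equal(rgb_to_hsb(single_px(0, 255, 0))[1, 1, ], c(85, 255, 255))
  expect_equal(rgb_to_hsb(single_px(0, 0, 255))[1, 1, ], c(170, 255, 255))
  expect_equal(rgb_to_hsb(single_px(255, 255, 255))[1, 1, ], c(0, 0, 255))
  expect_equal(rgb_to_hsb(single_px(0, 0, 0))[1, 1, ], c(0, 0, 0))
  expect_equal(rgb_to_hsb(single_px(128, 128, 128))[1, 1, ], c(0, 0, 128))
})

test_that("rgb_to_hsb agrees exactly with the integer-exact hexcone oracle", {
  # all 256 gray levels and the 6 primary/secondary colors
  grays <- cbind(0:255, 0:255, 0:255)
  prims <- rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                 c(255, 255, 0), c(0, 255, 255), c(255, 0, 255))
  # a deterministic sample of the RGB cube, including tie-prone triples
  set.seed(20240101)
  rand <- matrix(sample(0:255, 3 * 3000, replace = TRUE), ncol = 3)
  triples <- rbind(grays, prims, rand)
  expect_identical(hsb_pkg(triples), hsb_oracle(triples))
})

test_that("threshold bounds are inclusive and wraparound hue works", {
  band <- fibrosis_band()
  mk_hsb <- function(h, s, b) {
    a <- array(0L, dim = c(1, 1, 3)); a[1, 1, ] <- c(h, s, b); a
  }
  expect_true(threshold_hsb(mk_hsb(170, 200, 180), band)[1, 1])
  expect_false(threshold_hsb(mk_hsb(170, 0, 255), band)[1, 1])   # white fill
  expect_false(threshold_hsb(mk_hsb(139, 200, 180), band)[1, 1])
  expect_true(threshold_hsb(mk_hsb(140, 200, 180), band)[1, 1])
  expect_true(threshold_hsb(mk_hsb(190, 200, 180), band)[1, 1])
  expect_false(threshold_hsb(mk_hsb(191, 200, 180), band)[1, 1])
  expect_true(threshold_hsb(mk_hsb(170, 200, 248), band)[1, 1])
  expect_false(threshold_hsb(mk_hsb(170, 200, 249), band)[1, 1])

  wrap <- hsb_band(240, 20, 0, 255, 0, 255)
  expect_true(threshold_hsb(mk_hsb(250, 10, 10), wrap)[1, 1])
  expect_true(threshold_hsb(mk_hsb(5, 10, 10), wrap)[1, 1])
  expect_false(threshold_hsb(mk_hsb(100, 10, 10), wrap)[1, 1])
})

test_that("the full band selects everything; brightness 0-0 selects black only", {
  set.seed(7)
  img <- array(sample(0:255, 10 * 10 * 3, replace = TRUE), dim = c(10, 10, 3))
  hsb <- rgb_to_hsb(img)
  expect_true(all(threshold_hsb(hsb, hsb_band(0, 255, 0, 255, 0, 255))))
  dark <- threshold_hsb(hsb, hsb_band(0, 255, 0, 255, 0, 0))
  expect_identical(dark, matrix(hsb[, , 3] == 0L, 10, 10))
})

test_that("enlarging a band never deselects a pixel (monotone thresholding)", {
  set.seed(11)
  img <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), dim = c(20, 20, 3))
  hsb <- rgb_to_hsb(img)
  for (i in 1:20) {
    lo <- sort(sample(0:255, 2)); so <- sort(sample(0:255, 2))
    bo <- sort(sample(0:255, 2))
    small <- hsb_band(lo[1], lo[2], so[1], so[2], bo[1], bo[2])
    grow <- function(x, d) as.integer(min(max(x + d, 0), 255))
    big <- hsb_band(grow(lo[1], -10), grow(lo[2], 10), grow(so[1], -10),
                    grow(so[2], 10), grow(bo[1], -10), grow(bo[2], 10))
    m1 <- threshold_hsb(hsb, small); m2 <- threshold_hsb(hsb, big)
    expect_true(all(m2[m1]))
  }
})

test_that("band construction enforces bound ordering and range", {
  expect_error(hsb_band(0, 255, 200, 100, 0, 255), "sat_lo")
  expect_error(hsb_band(0, 255, 0, 255, 249, 248), "bri_lo")
  expect_error(hsb_band(-1, 255, 0, 255, 0, 255), "0, 255")
  expect_silent(hsb_band(200, 10, 0, 255, 0, 255))  # hue wraparound allowed
})

test_that("3x3 mean smoothing matches hand arithmetic and stays bounded", {
  expect_identical(smooth_rgb(flat_img(37, 201, 99)), flat_img(37, 201, 99))

  img <- array(0L, dim = c(3, 3, 3))
  img[2, 2, ] <- 255L
  sm <- smooth_rgb(img)
  expect_equal(sm[2, 2, ], c(28, 28, 28))          # 255/9 rounded half-up
  expect_equal(sm[1, 1, ], c(64, 64, 64))          # corner: 255/4
  expect_equal(sm[1, 2, ], c(43, 43, 43))          # edge: 255/6 = 42.5, half-up

  set.seed(3)
  rimg <- array(sample(0:255, 15 * 12 * 3, replace = TRUE), dim = c(15, 12, 3))
  sm <- smooth_rgb(rimg)
  for (k in 1:3) {
    expect_gte(min(sm[, , k]), min(rimg[, , k]))
    expect_lte(max(sm[, , k]), max(rimg[, , k]))
  }
})

test_that("smoothing commutes with a constant channel offset up to rounding", {
  set.seed(5)
  img <- array(sample(0:200, 9 * 9 * 3, replace = TRUE), dim = c(9, 9, 3))
  shifted <- img + 50L
  d <- smooth_rgb(shifted) - (smooth_rgb(img) + 50L)
  expect_lte(max(abs(d)), 1)
})
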