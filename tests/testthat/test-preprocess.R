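test_that("identity resample returns the input values", {
  set.seed(1)
  v <- ct_volume(array(rnorm(12^3), c(12, 12, 12)), spacing = c(1, 1, 2))
  r <- resample_volume(v, c(1, 1, 2))
  expect_equal(r$values, v$values, tolerance = 1e-12)
  expect_identical(dim(r), dim(v))
})

test_that("resampling a constant volume preserves the constant", {
  v <- ct_volume(array(37, c(10, 12, 14)), spacing = c(1, 1, 1))
  r <- resample_volume(v, c(0.7, 1.3, 2.1))
  expect_true(all(abs(r$values - 37) < 1e-12))
  expect_equal(r$spacing, c(0.7, 1.3, 2.1))
})

test_that("trilinear resampling is exact for an affine ramp", {
  # values linear in z (mm): downsampling 2x must reproduce the line at the
  # new voxel centers exactly (linear interpolation preserves affine maps)
  n <- 16L; sp <- 1
  zmm <- (seq_len(n) - 0.5) * sp
  v <- ct_volume(aperm(array(rep(5 + 3 * zmm, each = n * n), c(n, n, n)),
                       c(1, 2, 3)), spacing = c(1, 1, sp))
  r <- resample_volume(v, c(1, 1, 2))
  zmm_out <- (seq_len(dim(r)[3]) - 0.5) * 2
  expected <- 5 + 3 * zmm_out
  for (k in seq_along(zmm_out))
    expect_equal(unique(as.numeric(r$values[, , k])), expected[k],
                 tolerance = 1e-10)
})

test_that("resample validates its arguments", {
  v <- ct_volume(array(0, c(8, 8, 8)))
  expect_error(resample_volume(v, c(1, 1, -2)), "positive")
  expect_error(resample_volume(ct_volume(array(0, c(1, 8, 8))), c(1, 1, 1)),
               "at least 2 voxels")
})

test_that("HU clip and scale hits the documented endpoints", {
  v <- ct_volume(array(c(-1200, -1000, 0, 500, 1000, 1700), c(6, 1, 1)))
  s <- clip_scale_hu(v)
  expect_equal(as.numeric(s$values), c(-1, -1, 0, 0.5, 1, 1))
  expect_identical(s$units, "normalized")
})

test_that("inverse_scale round-trips in-range values", {
  set.seed(2)
  v <- ct_volume(array(runif(64, -1000, 1000), c(4, 4, 4)))
  back <- inverse_scale(clip_scale_hu(v))
  expect_equal(back$values, v$values, tolerance = 1e-9)
  expect_identical(back$units, "HU")
  # idempotence through the round trip
  again <- clip_scale_hu(back)
  expect_equal(again$values, clip_scale_hu(v)$values, tolerance = 1e-12)
})

test_that("body mask reproduces hand-simulated morphology", {
  # all-air slice -> empty mask
  air <- matrix(-1000, 32, 32)
  expect_false(any(body_mask(air)))
  # solid 20x20 block at 0 HU survives a 5x5 opening unchanged
  sl <- matrix(-1000, 32, 32)
  sl[6:25, 6:25] <- 0
  m <- body_mask(sl)
  expect_identical(m, sl > -500)
  # interior 3x3 pocket at -800 HU is hole-filled; detached 2x2 speck removed
  sl2 <- sl
  sl2[12:14, 12:14] <- -800          # pocket inside the block
  sl2[29:30, 29:30] <- 0             # speck away from the block
  m2 <- body_mask(sl2)
  expect_true(all(m2[12:14, 12:14]))   # hole filled
  expect_false(any(m2[29:30, 29:30]))  # speck opened away
})

test_that("body contouring fills lungs at full slice resolution", {
  # a chest-like slice at CT-native resolution: the chest wall is many
  # pixels thick, survives the 5x5 opening, and the lung interiors are
  # recovered by hole filling
  n <- 160L
  ell <- function(cx, cy, a, b) {
    outer(seq_len(n), seq_len(n),
          function(x, y) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
  }
  body <- ell(80, 80, 70, 60)
  lungs <- ell(46, 80, 26, 40) | ell(114, 80, 26, 40)
  sl <- matrix(-1000, n, n)
  sl[body] <- 40
  sl[lungs] <- -800
  m <- body_mask(sl)
  expect_true(all(m[lungs]))            # holes filled
  expect_gt(mean(m[body]), 0.99)        # body kept (opening may shave the rim)
  expect_false(any(m[!body]))           # background untouched
})

test_that("body mask works per axial slice of a volume and is monotone", {
  p <- tiny_pair(seed = 7, noise = 0)
  m <- body_mask(p$contrast)
  expect_identical(dim(m), dim(p$contrast$values))
  # raising the threshold never grows the mask
  m_hi <- body_mask(p$contrast, threshold_hu = -200)
  expect_true(all(m >= m_hi))
})

test_that("byte normalization maps the documented endpoints", {
  y <- vgg_byte_normalize(matrix(c(-1000, -1500, 0, 1000, 1500), 1))
  expect_identical(dim(y), c(1L, 5L, 3L))
  expect_equal(y[1, , 1], c(0L, 0L, 127L, 255L, 255L))
  # replicated across the three channels
  expect_identical(y[, , 1], y[, , 2])
  expect_identical(y[, , 1], y[, , 3])
  # non-decreasing in the input
  x <- seq(-1100, 1100, by = 7)
  yy <- vgg_byte_normalize(matrix(x, 1))[1, , 1]
  expect_true(all(diff(yy) >= 0))
})
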