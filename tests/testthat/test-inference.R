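test_that("weight kernel is a floored separable tent", {
  for (s in c(2L, 4L, 7L, 16L)) {
    w <- make_weight_kernel(s, eps = 0.05)
    expect_identical(dim(w), rep(s, 3L))
    expect_true(all(w > 0))
    expect_equal(max(w), 1)
    # center planes carry the maximum; corners the floor cubed
    expect_equal(w[1, 1, 1], if (s == 2L) 1 else 0.05^3)
    # symmetric under reflection of every axis
    expect_equal(w, w[s:1, , ], tolerance = 1e-15)
    expect_equal(w, w[, s:1, ], tolerance = 1e-15)
    expect_equal(w, w[, , s:1], tolerance = 1e-15)
  }
  # even size: the two central planes tie at the maximum
  w4 <- make_weight_kernel(4L)
  expect_equal(w4[2, 2, 2], 1)
  expect_equal(w4[3, 3, 3], 1)
  expect_error(make_weight_kernel(1L), "at least 2")
})

test_that("identity generator is recovered exactly by the blending", {
  set.seed(20)
  v <- array(runif(40^3, -1, 1), c(40, 40, 40))
  out <- sliding_window_translate(v, function(p) p, patch_size = 16L,
                                  stride = 8L)
  expect_lt(max(abs(out - v)), 1e-6)
})

test_that("a constant shift commutes with the weighted averaging", {
  set.seed(21)
  v <- array(runif(40^3, -1, 0.8), c(40, 40, 40))
  out <- sliding_window_translate(v, function(p) p + 0.1, patch_size = 16L,
                                  stride = 8L)
  expect_lt(max(abs(out - (v + 0.1))), 1e-6)
})

# brute-force oracle: materialize every window, accumulate weighted
# predictions and weights in two full-size buffers, divide
oracle_translate <- function(v, g, ps, stride, eps = 0.05) {
  d <- dim(v)
  w <- make_weight_kernel(ps, eps)
  num <- array(0, d); den <- array(0, d)
  starts <- function(n) unique(c(seq(1L, n - ps + 1L, by = stride),
                                 n - ps + 1L))
  for (i in starts(d[1])) for (j in starts(d[2])) for (k in starts(d[3])) {
    ix <- i:(i + ps - 1L); jx <- j:(j + ps - 1L); kx <- k:(k + ps - 1L)
    pred <- g(v[ix, jx, kx])
    num[ix, jx, kx] <- num[ix, jx, kx] + w * pred
    den[ix, jx, kx] <- den[ix, jx, kx] + w
  }
  num / den
}

test_that("sliding window matches the brute-force accumulation oracle", {
  set.seed(22)
  v <- array(runif(36^3, -1, 1), c(36, 36, 36))
  # a nonlinear, window-position-sensitive mapping
  g <- function(p) tanh(0.8 * p + 0.2 * mean(p)^2)
  for (stride in c(5L, 12L)) {
    out <- sliding_window_translate(v, g, patch_size = 12L, stride = stride)
    ref <- oracle_translate(v, g, 12L, stride)
    expect_lt(max(abs(out - ref)), 1e-6)
  }
  # stride = patch size degenerates to exact tiling and still matches
  out <- sliding_window_translate(v, g, patch_size = 12L, stride = 12L)
  ref <- oracle_translate(v, g, 12L, 12L)
  expect_lt(max(abs(out - ref)), 1e-6)
})

test_that("every voxel is covered for any stride", {
  v <- array(0.5, c(20, 23, 29))
  for (stride in c(1L, 3L, 7L, 8L)) {
    out <- sliding_window_translate(v, function(p) p, patch_size = 8L,
                                    stride = stride)
    expect_true(all(is.finite(out)))   # den > 0 everywhere
    expect_lt(max(abs(out - 0.5)), 1e-9)
  }
})

test_that("inference validates its inputs", {
  v <- array(0, c(10, 10, 10))
  expect_error(sliding_window_translate(v, function(p) p, patch_size = 16L),
               "pad")
  expect_error(sliding_window_translate(v, function(p) p, patch_size = 8L,
                                        stride = 9L), "stride")
  expect_error(sliding_window_translate(v, function(p) p[1:2, 1:2, 1:2],
                                        patch_size = 8L, stride = 4L),
               "different shape")
})

test_that("difference maps clip and antisymmetrize", {
  a <- array(c(0.1, 0.9, -0.2), c(3, 1, 1))
  b <- array(c(0.1, -0.5, 0.1), c(3, 1, 1))
  dm <- difference_map(a, b)
  expect_s3_class(dm, "difference_map")
  expect_equal(as.numeric(dm$values), c(0, 0.4, -0.3))  # 1.4 clipped to 0.4
  dm_rev <- difference_map(b, a)
  inside <- abs(a - b) <= 0.4
  expect_equal(dm$values[inside], -dm_rev$values[inside])
  expect_error(difference_map(a, array(0, c(2, 1, 1))), "mismatch")
})
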