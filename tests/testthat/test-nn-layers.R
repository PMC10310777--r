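# Gradient correctness of the layer primitives (double-precision path):
# every analytic gradient is checked against central finite differences.

fd_layer_check <- function(layers, x, n_checks = 4L, tol = 1e-5) {
  params <- decontrast:::nn_init(layers)
  f <- decontrast:::nn_forward(layers, params, x, float32 = FALSE)
  gy <- array(rnorm(length(f$y)), dim(f$y))
  bk <- decontrast:::nn_backward(layers, params, f$caches, gy,
                                 float32 = FALSE)
  loss <- function(p) sum(decontrast:::nn_forward(layers, p, x,
                                                  float32 = FALSE)$y * gy)
  eps <- 1e-6
  for (li in seq_along(layers)) {
    pl <- params[[li]]
    if (is.null(pl)) next
    leaves <- if (!is.null(pl$w) || !is.null(pl$W)) list(pl) else pl
    for (nm in names(pl)) {
      target <- pl[[nm]]
      if (is.list(target)) next
      for (i in sample(length(target), min(n_checks, length(target)))) {
        p1 <- params; p1[[li]][[nm]][i] <- p1[[li]][[nm]][i] + eps
        p2 <- params; p2[[li]][[nm]][i] <- p2[[li]][[nm]][i] - eps
        num <- (loss(p1) - loss(p2)) / (2 * eps)
        expect_equal(bk$grads[[li]][[nm]][i], num, tolerance = tol)
      }
    }
  }
  # input gradient
  i <- sample(length(x), 1L)
  x1 <- x; x1[i] <- x1[i] + eps
  x2 <- x; x2[i] <- x2[i] - eps
  num <- (sum(decontrast:::nn_forward(layers, params, x1, FALSE)$y * gy) -
            sum(decontrast:::nn_forward(layers, params, x2, FALSE)$y * gy)) /
    (2 * eps)
  expect_equal(bk$gx[i], num, tolerance = tol)
}

test_that("conv, transposed conv, norm and activations backpropagate correctly", {
  set.seed(11)
  x <- array(rnorm(8^3 * 2, sd = 0.4), c(8, 8, 8, 2))
  cases <- list(
    conv_s1 = list(decontrast:::nn_refpad(1L),
                   decontrast:::nn_conv(2L, 3L, 3L)),
    conv_s2 = list(decontrast:::nn_conv(2L, 4L, 3L, stride = 2L, pad = 1L),
                   decontrast:::nn_inorm(), decontrast:::nn_relu()),
    convtr = list(decontrast:::nn_convtr(2L, 3L),
                  decontrast:::nn_inorm(), decontrast:::nn_lrelu(0.2)),
    residual = list(decontrast:::nn_res(list(
      decontrast:::nn_refpad(1L), decontrast:::nn_conv(2L, 2L, 3L),
      decontrast:::nn_inorm(), decontrast:::nn_relu(),
      decontrast:::nn_refpad(1L), decontrast:::nn_conv(2L, 2L, 3L),
      decontrast:::nn_inorm()))),
    disc_head = list(decontrast:::nn_conv(2L, 1L, 3L, pad = 1L),
                     decontrast:::nn_sigmoid()),
    squash = list(decontrast:::nn_refpad(1L),
                  decontrast:::nn_conv(2L, 1L, 3L), decontrast:::nn_tanh()))
  for (case in cases) fd_layer_check(case, x)
})

test_that("down-up convolution round trip restores the spatial side", {
  set.seed(12)
  for (s in c(8L, 12L, 16L, 32L)) {
    x <- array(rnorm(s^3 * 2), c(s, s, s, 2))
    down <- list(decontrast:::nn_conv(2L, 4L, 3L, stride = 2L, pad = 1L))
    up <- list(decontrast:::nn_convtr(4L, 2L))
    pd <- decontrast:::nn_init(down)
    pu <- decontrast:::nn_init(up)
    mid <- decontrast:::nn_forward(down, pd, x)$y
    expect_identical(dim(mid)[1:3], rep(s %/% 2L, 3L))
    back <- decontrast:::nn_forward(up, pu, mid)$y
    expect_identical(dim(back)[1:3], rep(s, 3L))
  }
})

test_that("float32 and float64 conv paths agree to single precision", {
  set.seed(13)
  x <- array(rnorm(12^3 * 3), c(12, 12, 12, 3))
  w <- array(rnorm(27 * 3 * 5, sd = 0.1), c(3, 3, 3, 3, 5))
  b <- rnorm(5)
  y32 <- decontrast:::cn_conv3d_fwd(x, dim(x), w, dim(w), b,
                                    rep(1L, 3), rep(1L, 3), TRUE)
  y64 <- decontrast:::cn_conv3d_fwd(x, dim(x), w, dim(w), b,
                                    rep(1L, 3), rep(1L, 3), FALSE)
  expect_lt(max(abs(y32 - y64)), 1e-5)
})

test_that("reflection padding and its adjoint are transposes", {
  set.seed(14)
  x <- array(rnorm(6^3 * 2), c(6, 6, 6, 2))
  for (p in 1:3) {
    y <- decontrast:::cn_refpad_fwd(x, dim(x), p)
    expect_identical(dim(y)[1:3], dim(x)[1:3] + 2L * p)
    g <- array(rnorm(length(y)), dim(y))
    gx <- decontrast:::cn_refpad_adj(g, dim(g), p)
    expect_equal(sum(y * g), sum(x * gx), tolerance = 1e-10)
  }
})
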