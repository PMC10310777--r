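test_that("generator preserves shape and maps into (-1, 1)", {
  g <- fixed_tiny_generator()
  p <- array(runif(16^3, -1, 1), c(16, 16, 16))
  out <- predict(g, p)
  expect_identical(dim(out), dim(p))
  expect_true(all(out > -1 & out < 1))
  # deterministic forward pass
  expect_identical(out, predict(g, p))
})

test_that("generator rejects patch sides not divisible by 4", {
  g <- fixed_tiny_generator()
  expect_error(predict(g, array(0, c(18, 18, 18))), "divisible by 4")
})

test_that("tiny generator parameter count matches the layer-wise closed form", {
  g <- fixed_tiny_generator()
  f <- 8L; n_res <- 2L
  counts <- c(
    enc = 5^3 * 1 * f + f,
    down1 = 3^3 * f * 2 * f + 2 * f,
    down2 = 3^3 * 2 * f * 4 * f + 4 * f,
    res = n_res * 2 * (3^3 * 4 * f * 4 * f + 4 * f),
    up1 = 3^3 * 4 * f * 2 * f + 2 * f,
    up2 = 3^3 * 2 * f * f + f,
    proj = 3^3 * f * 1 + 1)
  expect_identical(n_params(g), as.integer(sum(counts)))
})

test_that("discriminator yields a score grid at side / 2^n_down in (0, 1)", {
  set.seed(5)
  d <- build_discriminator(tiny_discriminator_spec())
  s <- predict(d, array(runif(64^3, -1, 1), c(64, 64, 64)))
  expect_identical(dim(s), c(8L, 8L, 8L))
  expect_true(all(s > 0 & s < 1))
  s32 <- predict(d, array(0, c(32, 32, 32)))
  expect_identical(dim(s32), c(4L, 4L, 4L))
  expect_error(predict(d, array(0, c(4, 4, 4))), "receptive")
})

test_that("ssim satisfies its defining identities", {
  set.seed(6)
  a <- array(runif(10^3, -1, 1), c(10, 10, 10))
  b <- array(runif(10^3, -1, 1), c(10, 10, 10))
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_lt(ssim(a, b), 1)
  expect_error(ssim(a, array(0, c(8, 8, 8))), "mismatch")
})

test_that("constant-patch ssim matches the zero-variance closed form", {
  a <- array(0, c(8, 8, 8)); b <- array(0.5, c(8, 8, 8))
  C1 <- (0.01 * 2)^2
  expect_equal(ssim(a, b), C1 / (0.25 + C1), tolerance = 1e-6)
})

test_that("ssim gradient matches finite differences", {
  set.seed(8)
  a <- array(runif(9^3, -0.5, 0.5), c(9, 9, 9))
  b <- array(runif(9^3, -0.5, 0.5), c(9, 9, 9))
  st <- decontrast:::ssim_cached(a, b)
  g <- decontrast:::ssim_grad_b(st)
  eps <- 1e-6
  for (i in sample(length(b), 5)) {
    b1 <- b; b1[i] <- b1[i] + eps
    b2 <- b; b2[i] <- b2[i] - eps
    num <- (ssim(a, b1) - ssim(a, b2)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("cycle-consistency loss follows its closed forms", {
  set.seed(9)
  x <- array(runif(8^3, -1, 1), c(8, 8, 8))
  expect_equal(cycle_consistency_loss(x, x), 0, tolerance = 1e-12)
  a <- array(0, c(8, 8, 8)); b <- array(0.5, c(8, 8, 8))
  C1 <- (0.01 * 2)^2
  expect_equal(cycle_consistency_loss(a, b),
               (0.5 + 1 - C1 / (0.25 + C1)) / 2, tolerance = 1e-6)
  # invariant to jointly negating both patches
  y <- array(runif(8^3, -1, 1), c(8, 8, 8))
  expect_equal(cycle_consistency_loss(x, y), cycle_consistency_loss(-x, -y),
               tolerance = 1e-12)
})

test_that("cycle loss gradient matches finite differences", {
  set.seed(10)
  x <- array(runif(8^3, -0.5, 0.5), c(8, 8, 8))
  r <- array(runif(8^3, -0.5, 0.5), c(8, 8, 8))
  cl <- decontrast:::cycle_loss_cached(x, r)
  g <- decontrast:::cycle_loss_grad(x, r, cl)
  eps <- 1e-6
  for (i in sample(length(r), 4)) {
    r1 <- r; r1[i] <- r1[i] + eps
    r2 <- r; r2[i] <- r2[i] - eps
    num <- (cycle_consistency_loss(x, r1) - cycle_consistency_loss(x, r2)) /
      (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("identity loss behaves as a same-domain penalty", {
  x <- array(0.2, c(8, 8, 8))
  expect_equal(identity_loss(function(p) p, x), 0)
  expect_equal(identity_loss(function(p) p * 0, x), 0.2)
})

test_that("least-squares adversarial losses hit their closed forms", {
  ones <- array(1, c(2, 2, 2)); zeros <- array(0, c(2, 2, 2))
  half <- array(0.5, c(2, 2, 2))
  expect_equal(adversarial_generator_loss(ones), 0)
  expect_equal(adversarial_discriminator_loss(ones, zeros), 0)
  expect_equal(adversarial_discriminator_loss(half, half), 0.25)
})

test_that("overall generator loss is the weighted sum", {
  expect_equal(total_generator_loss(1.0, 0.2, 0.05, loss_weights(10)), 1.7)
  expect_equal(total_generator_loss(0, 0, 0, loss_weights(3)), 0)
  expect_equal(total_generator_loss(0.4, 0.3, 9, loss_weights(0)), 0.7)
  expect_error(total_generator_loss(Inf, 0, 0), "finite")
})

test_that("checkpoints reconstruct generators exactly", {
  run_dir <- withr::local_tempdir()
  g <- fixed_tiny_generator()
  set.seed(3)
  d <- build_discriminator(tiny_discriminator_spec())
  fit <- decontrast:::assemble_fit(g$spec, d$spec, g$params, g$params,
                                   d$params, d$params, list(),
                                   loss_weights(), train_config(
                                     patch_size = 32L, n_iterations = 1L))
  path <- file.path(run_dir, "ckpt.rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  p <- array(runif(16^3, -1, 1), c(16, 16, 16))
  expect_identical(predict(fit2$g_ab, p), predict(fit$g_ab, p))
})
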