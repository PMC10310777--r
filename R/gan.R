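#' Generator architecture specification
#'
#' Describes the 3D residual generator: one convolutional encoding block
#' (reflection pad, 5^3 conv, instance norm, ReLU), two stride-2
#' down-convolution blocks, `n_residual` residual units, two stride-2
#' transposed up-convolution blocks, and a final 3^3 projection convolution
#' with Tanh activation, so outputs lie strictly inside (-1, 1).
#'
#' @param base_filters Channel count of the first block. The full-scale
#'   preset is 64; the tiny CPU test preset uses 8.
#' @param n_residual Number of residual units (full-scale preset: 9).
#' @returns An object of class `generator_spec`.
#' @seealso [build_generator()]
#' @export
generator_spec <- function(base_filters = 64L, n_residual = 9L) {
  stopifnot(base_filters >= 1, n_residual >= 1)
  structure(list(base_filters = as.integer(base_filters),
                 n_residual = as.integer(n_residual)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Patch-GAN discriminator: three stride-2 down-convolution blocks
#' (4^3 kernels, instance norm after the first, LeakyReLU 0.2), one 3^3
#' convolution to a single channel, and a sigmoid, yielding a grid of local
#' realism scores in (0, 1) with spatial side `input_side / 2^n_down`.
#'
#' @param base_filters Channel count of the first block.
#' @param n_down Number of stride-2 blocks; the reference preset is 3.
#' @returns An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(base_filters = 64L, n_down = 3L) {
  stopifnot(base_filters >= 1, n_down >= 1)
  structure(list(base_filters = as.integer(base_filters),
                 n_down = as.integer(n_down)),
            class = "discriminator_spec")
}

#' Tiny CPU presets for tests and demos
#'
#' `tiny_generator_spec()` and `tiny_discriminator_spec()` return the small
#' presets (8 base filters, 2 residual units) used throughout the test suite
#' so forward/backward passes run in milliseconds on one CPU.
#' @returns A `generator_spec` / `discriminator_spec`.
#' @export
tiny_generator_spec <- function() generator_spec(base_filters = 8L, n_residual = 2L)

#' @rdname tiny_generator_spec
#' @export
tiny_discriminator_spec <- function() discriminator_spec(base_filters = 8L)

#' Loss weights for the overall generator objective
#'
#' The overall generator loss is
#' `adversarial + cycle_consistency + lambda_identity * identity`.
#'
#' @param lambda_identity Non-negative weight on the identity term
#'   (reference value: 10).
#' @returns An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_identity = 10) {
  stopifnot(lambda_identity >= 0)
  structure(list(lambda_identity = lambda_identity), class = "loss_weights")
}

generator_layers <- function(spec) {
  f <- spec$base_filters
  res_unit <- function() nn_res(list(
    nn_refpad(1L), nn_conv(4L * f, 4L * f, 3L), nn_inorm("relu"),
    nn_refpad(1L), nn_conv(4L * f, 4L * f, 3L), nn_inorm()))
  c(list(nn_refpad(2L), nn_conv(1L, f, 5L), nn_inorm("relu"),
         nn_conv(f, 2L * f, 3L, stride = 2L, pad = 1L), nn_inorm("relu"),
         nn_conv(2L * f, 4L * f, 3L, stride = 2L, pad = 1L),
         nn_inorm("relu")),
    replicate(spec$n_residual, res_unit(), simplify = FALSE),
    list(nn_convtr(4L * f, 2L * f), nn_inorm("relu"),
         nn_convtr(2L * f, f), nn_inorm("relu"),
         nn_refpad(1L), nn_conv(f, 1L, 3L), nn_tanh()))
}

discriminator_layers <- function(spec) {
  f <- spec$base_filters
  layers <- list(nn_conv(1L, f, 4L, stride = 2L, pad = 1L), nn_lrelu(0.2))
  ch <- f
  for (i in seq_len(spec$n_down - 1L)) {
    layers <- c(layers, list(nn_conv(ch, 2L * ch, 4L, stride = 2L, pad = 1L),
                             nn_inorm("lrelu")))
    ch <- 2L * ch
  }
  c(layers, list(nn_conv(ch, 1L, 3L, stride = 1L, pad = 1L), nn_sigmoid()))
}

#' Build a generator
#'
#' Instantiates the 3D residual generator described by `spec` with randomly
#' initialised weights (N(0, 0.02) kernels, zero biases, drawn from the
#' current R RNG stream). The returned object maps a cubic patch in
#' normalized units to a same-shape patch strictly inside (-1, 1); apply it
#' with [predict()][predict.ct_generator].
#'
#' @param spec A [generator_spec()].
#' @returns An object of class `ct_generator`.
#' @examples
#' set.seed(1)
#' g <- build_generator(tiny_generator_spec())
#' patch <- array(0, c(16, 16, 16))
#' out <- predict(g, patch)
#' range(out)
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  layers <- generator_layers(spec)
  structure(list(layers = layers, params = nn_init(layers), spec = spec),
            class = "ct_generator")
}

#' Build a patch-GAN discriminator
#'
#' @param spec A [discriminator_spec()].
#' @returns An object of class `ct_discriminator`; apply it with
#'   [predict()][predict.ct_discriminator] to obtain a grid of per-patch
#'   realism scores in (0, 1).
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  layers <- discriminator_layers(spec)
  structure(list(layers = layers, params = nn_init(layers), spec = spec),
            class = "ct_discriminator")
}

as_patch4 <- function(patch) {
  d <- dim(patch)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("patch must be a 3D array")
  if (length(d) == 3L) dim(patch) <- c(d, 1L)
  patch
}

check_generator_input <- function(patch) {
  d <- dim(patch)[1:3]
  if (any(d %% 4L != 0L))
    stop("patch sides must be divisible by 4 (two stride-2 stages); got ",
         paste(d, collapse = "x"))
}

#' Apply a generator to a patch
#'
#' @param object A `ct_generator`.
#' @param patch 3D array in normalized units; every side must be divisible
#'   by 4.
#' @param float32 Run the convolutions in single precision (the training
#'   default); set `FALSE` for full double precision.
#' @param ... Unused.
#' @returns A 3D array of the same shape with values in (-1, 1).
#' @export
predict.ct_generator <- function(object, patch, float32 = TRUE, ...) {
  x <- as_patch4(patch)
  check_generator_input(x)
  y <- nn_forward(object$layers, object$params, x, float32)$y
  dim(y) <- dim(y)[1:3]
  y
}

#' Apply a discriminator to a patch
#'
#' @param object A `ct_discriminator`.
#' @param patch 3D array in normalized units; each side must be at least
#'   `2^n_down`.
#' @param float32 Single-precision convolutions (default).
#' @param ... Unused.
#' @returns A 3D grid of scores in (0, 1), spatial side `side / 2^n_down`.
#' @export
predict.ct_discriminator <- function(object, patch, float32 = TRUE, ...) {
  x <- as_patch4(patch)
  if (any(dim(x)[1:3] < 2L^object$spec$n_down))
    stop("patch smaller than the discriminator's receptive stride (",
         2L^object$spec$n_down, " voxels per axis)")
  y <- nn_forward(object$layers, object$params, x, float32)$y
  dim(y) <- dim(y)[1:3]
  y
}

#' Trainable parameter count
#'
#' @param model A `ct_generator` or `ct_discriminator`.
#' @returns Integer number of trainable weights and biases.
#' @export
n_params <- function(model) as.integer(nn_n_params(model$params))

#' @export
print.ct_generator <- function(x, ...) {
  cat("<ct_generator> base_filters=", x$spec$base_filters,
      ", n_residual=", x$spec$n_residual,
      ", parameters=", n_params(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.ct_discriminator <- function(x, ...) {
  cat("<ct_discriminator> base_filters=", x$spec$base_filters,
      ", n_down=", x$spec$n_down,
      ", parameters=", n_params(x), "\n", sep = "")
  invisible(x)
}

# ---- SSIM ----

gaussian_window <- function(size = 7L, sigma = 1.5) {
  t <- seq_len(size) - (size + 1) / 2
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

ssim_stats <- function(a, b, window, sigma, L) {
  d <- dim(a)
  if (any(d < window))
    stop("patch sides must be at least the SSIM window (", window, ")")
  w <- gaussian_window(window, sigma)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  F <- function(z) cn_sepfilt3_valid(z, dim(z), w)
  mu_x <- F(a); mu_y <- F(b)
  u2x <- F(a * a); u2y <- F(b * b); uxy <- F(a * b)
  sxx <- u2x - mu_x * mu_x
  syy <- u2y - mu_y * mu_y
  sxy <- uxy - mu_x * mu_y
  A1 <- 2 * mu_x * mu_y + C1
  A2 <- 2 * sxy + C2
  B1 <- mu_x * mu_x + mu_y * mu_y + C1
  B2 <- sxx + syy + C2
  S <- A1 * A2 / (B1 * B2)
  list(S = S, mu_x = mu_x, mu_y = mu_y, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       w = w, d = d)
}

#' Structural similarity index between two 3D patches
#'
#' Mean local SSIM with a separable Gaussian window (default 7^3 voxels,
#' sigma 1.5) over all fully interior windows. The dynamic range is `L = 2`,
#' matching patches in normalized units `[-1, 1]`, so
#' `C1 = (0.01 * 2)^2` and `C2 = (0.03 * 2)^2`.
#'
#' @param a,b 3D arrays of identical shape, each side at least `window`.
#' @param window Cubic window side (odd).
#' @param sigma Gaussian window standard deviation in voxels.
#' @param L Dynamic range of the data.
#' @returns A scalar in `[-1, 1]`; 1 iff `a` and `b` are identical.
#' @examples
#' a <- array(0, c(8, 8, 8))
#' ssim(a, a)                       # exactly 1
#' b <- array(0.5, c(8, 8, 8))
#' ssim(a, b)                       # constant-patch closed form
#' @export
ssim <- function(a, b, window = 7L, sigma = 1.5, L = 2) {
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch")
  mean(ssim_stats(a, b, window, sigma, L)$S)
}

# SSIM with cache for the gradient wrt the second argument (used inside the
# cycle loss during training).
ssim_cached <- function(a, b, window = 7L, sigma = 1.5, L = 2) {
  st <- ssim_stats(a, b, window, sigma, L)
  st$a <- a; st$b <- b
  st$value <- mean(st$S)
  st
}

# d mean-SSIM / d b. Derived by differentiating the per-window SSIM through
# the Gaussian-filtered statistics; the adjoint of the valid filter scatters
# window-level partials back to voxels.
ssim_grad_b <- function(st) {
  nwin <- length(st$S)
  V <- 1 / (st$B1 * st$B2)
  dS_dmu <- 2 * st$mu_x * (st$A2 - st$A1) * V -
    2 * st$mu_y * st$S * (1 / st$B1 - 1 / st$B2)
  dS_du2 <- -st$S / st$B2
  dS_duxy <- 2 * st$A1 * V
  adj <- function(z) cn_sepfilt3_adj(z, dim(z), st$w, st$d)
  (adj(dS_dmu) + 2 * st$b * adj(dS_du2) + st$a * adj(dS_duxy)) / nwin
}

# ---- loss terms ----

#' Cycle-consistency loss
#'
#' The average of the mean absolute error and the SSIM loss between an input
#' patch and its reconstruction:
#' `(mean(|x - x_rec|) + (1 - ssim(x, x_rec))) / 2`.
#'
#' @param x,x_rec 3D arrays of identical shape.
#' @param window,sigma SSIM window parameters (see [ssim()]).
#' @returns Non-negative scalar; 0 iff `x_rec` equals `x`.
#' @export
cycle_consistency_loss <- function(x, x_rec, window = 7L, sigma = 1.5) {
  if (!identical(dim(x), dim(x_rec)))
    stop("cycle_consistency_loss: shape mismatch")
  (mean(abs(x - x_rec)) + (1 - ssim(x, x_rec, window, sigma))) / 2
}

cycle_loss_cached <- function(x, x_rec, window = 7L, sigma = 1.5) {
  st <- ssim_cached(x, x_rec, window, sigma)
  list(value = (mean(abs(x - x_rec)) + (1 - st$value)) / 2, st = st)
}

cycle_loss_grad <- function(x, x_rec, cached) {
  (sign(x_rec - x) / length(x) - ssim_grad_b(cached$st)) / 2
}

#' Identity loss of a generator on a same-domain patch
#'
#' Mean absolute difference between `predict(g, x)` and `x`: the penalty on
#' a generator altering an image already in its target domain.
#'
#' @param g A `ct_generator` (or any function mapping a patch to a patch).
#' @param x 3D array in normalized units.
#' @returns Non-negative scalar.
#' @export
identity_loss <- function(g, x) {
  y <- if (is.function(g)) g(x) else predict(g, x)
  mean(abs(y - x))
}

#' Least-squares adversarial losses
#'
#' `adversarial_generator_loss` is `mean((d(fake) - 1)^2)`: zero when the
#' generator fully fools the discriminator.
#' `adversarial_discriminator_loss` is
#' `(mean((d(real) - 1)^2) + mean(d(fake)^2)) / 2`: zero for perfect
#' discrimination. Scores are per-patch realism grids in (0, 1).
#'
#' @param d_scores,real_scores,fake_scores Score grids from a
#'   discriminator.
#' @returns Non-negative scalar.
#' @export
adversarial_generator_loss <- function(d_scores) {
  mean((d_scores - 1)^2)
}

#' @rdname adversarial_generator_loss
#' @export
adversarial_discriminator_loss <- function(real_scores, fake_scores) {
  (mean((real_scores - 1)^2) + mean(fake_scores^2)) / 2
}

#' Overall generator loss
#'
#' `adv + cyc + lambda_identity * idn`.
#'
#' @param adv,cyc,idn Finite scalar loss components.
#' @param w A [loss_weights()].
#' @returns Scalar total loss.
#' @export
total_generator_loss <- function(adv, cyc, idn, w = loss_weights()) {
  stopifnot(is.finite(adv), is.finite(cyc), is.finite(idn))
  adv + cyc + w$lambda_identity * idn
}
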