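#' Training configuration for the cycle-GAN
#'
#' @param patch_size Cubic patch side sampled per iteration; must be
#'   divisible by 4. The full-scale preset is 64; tests use 32.
#' @param n_iterations Number of training iterations (one generator step and
#'   one step per discriminator each).
#' @param learning_rate Adam step size for generators and discriminators
#'   (reference value 2e-4).
#' @param batch_size Patches per step (reference value 1; the only
#'   supported value).
#' @param seed Seed for the single RNG stream driving weight init, patch
#'   positions and pool swaps.
#' @param image_pool_size History pool of generated patches used for
#'   discriminator updates; 0 disables the pool.
#' @param checkpoint_every Write a checkpoint every this many iterations
#'   (`Inf` disables).
#' @param checkpoint_dir Directory for checkpoints.
#' @param beta1,beta2 Adam moment decay rates.
#' @param float32 Run convolutions in single precision (default).
#' @param reject_air_patches If `TRUE`, patches whose intensities are all
#'   below `air_threshold` are redrawn (off by default: every patch is
#'   used).
#' @param air_threshold Normalized-intensity threshold for the optional
#'   rejection rule.
#' @returns An object of class `train_config`.
#' @export
train_config <- function(patch_size = 64L, n_iterations = 100L,
                         learning_rate = 2e-4, batch_size = 1L,
                         seed = 1L, image_pool_size = 50L,
                         checkpoint_every = Inf, checkpoint_dir = NULL,
                         beta1 = 0.5, beta2 = 0.999, float32 = TRUE,
                         reject_air_patches = FALSE, air_threshold = -0.9) {
  patch_size <- as.integer(patch_size)
  if (patch_size %% 4L != 0L) stop("patch_size must be divisible by 4")
  if (n_iterations < 1L) stop("n_iterations must be at least 1")
  if (batch_size != 1L) stop("only batch_size = 1 is supported")
  structure(list(patch_size = patch_size,
                 n_iterations = as.integer(n_iterations),
                 learning_rate = learning_rate, batch_size = 1L,
                 seed = as.integer(seed),
                 image_pool_size = as.integer(image_pool_size),
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir,
                 beta1 = beta1, beta2 = beta2, float32 = isTRUE(float32),
                 reject_air_patches = isTRUE(reject_air_patches),
                 air_threshold = air_threshold),
            class = "train_config")
}

#' Sample a random cubic patch from a volume
#'
#' The patch corner is drawn uniformly over all positions at which a
#' `size`^3 sub-grid fits fully inside the volume. Uses the current R RNG
#' stream.
#'
#' @param vol A [ct_volume()] or 3D array.
#' @param size Patch side in voxels.
#' @returns A 3D array of side `size` with attribute `"corner"` (1-based).
#' @export
sample_patch <- function(vol, size) {
  v <- vol_values(vol)
  d <- dim(v)
  size <- as.integer(size)
  if (any(d < size))
    stop("volume (", paste(d, collapse = "x"),
         ") is smaller than the requested patch size ", size)
  corner <- vapply(d, function(n) sample.int(n - size + 1L, 1L), 1L)
  p <- v[corner[1] + seq_len(size) - 1L,
         corner[2] + seq_len(size) - 1L,
         corner[3] + seq_len(size) - 1L]
  attr(p, "corner") <- corner
  p
}

# history pool of generated patches (vanilla cycle-GAN practice): with
# probability 1/2 the discriminator sees an older fake instead of the
# current one.
pool_query <- function(pool, img, max_size) {
  if (max_size <= 0L) return(img)
  if (length(pool$items) < max_size) {
    pool$items[[length(pool$items) + 1L]] <- img
    return(img)
  }
  if (stats::runif(1) < 0.5) {
    i <- sample.int(length(pool$items), 1L)
    old <- pool$items[[i]]
    pool$items[[i]] <- img
    return(old)
  }
  img
}

dim4 <- function(x) { dim(x) <- c(dim(x)[1:3], 1L); x }
dim3 <- function(x) { dim(x) <- dim(x)[1:3]; x }

check_finite_loss <- function(vals, iter) {
  bad <- names(vals)[!vapply(vals, is.finite, TRUE)]
  if (length(bad))
    stop("non-finite loss at iteration ", iter, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
}

#' Train the 3D patch-based cycle-GAN
#'
#' Unpaired adversarial training of the two generator/discriminator pairs.
#' Per iteration: one random patch is drawn from each domain; both
#' generators are updated jointly on the overall loss (least-squares
#' adversarial terms on `D_B(G_AB(a))` and `D_A(G_BA(b))`, cycle-consistency
#' on both reconstructions, identity on both same-domain mappings); each
#' discriminator then takes one least-squares step against the real patch
#' and a fake drawn from its history pool.
#'
#' Domain A is conventionally the contrast cohort and domain B the
#' non-contrast cohort, so `g_ab` is the contrast-removal generator.
#'
#' @param cohort_a,cohort_b Non-empty lists of normalized [ct_volume()] (or
#'   3D arrays) with every axis at least `cfg$patch_size`.
#' @param gen_spec A [generator_spec()] shared by both generators.
#' @param disc_spec A [discriminator_spec()] shared by both discriminators.
#' @param weights A [loss_weights()].
#' @param cfg A [train_config()].
#' @param verbose Print a progress line every 100 iterations.
#' @returns An object of class `cyclegan_fit`: trained `g_ab`, `g_ba`
#'   ([build_generator()] objects), `d_a`, `d_b`, a `history` tibble with
#'   one row per iteration, and the configuration.
#' @seealso [sliding_window_translate()] to apply a trained generator to a
#'   whole volume, [tidy.cyclegan_fit()] / [glance.cyclegan_fit()] /
#'   [autoplot.cyclegan_fit()] for inspection.
#' @export
train_cyclegan <- function(cohort_a, cohort_b,
                           gen_spec = tiny_generator_spec(),
                           disc_spec = tiny_discriminator_spec(),
                           weights = loss_weights(),
                           cfg = train_config(),
                           verbose = FALSE) {
  if (!length(cohort_a) || !length(cohort_b))
    stop("both cohorts must be non-empty")
  vols_a <- lapply(cohort_a, function(v) {
    v <- as_ct_volume(v, units = "normalized")
    if (v$units != "normalized")
      stop("training volumes must be in normalized units (see clip_scale_hu)")
    v$values
  })
  vols_b <- lapply(cohort_b, function(v)
    as_ct_volume(v, units = "normalized")$values)
  ps <- cfg$patch_size
  for (v in c(vols_a, vols_b))
    if (any(dim(v) < ps))
      stop("volume smaller than patch size ", ps)

  with_preserved_rng({
    set.seed(cfg$seed)
    Lg <- generator_layers(gen_spec)
    Ld <- discriminator_layers(disc_spec)
    p_ab <- nn_init(Lg); p_ba <- nn_init(Lg)
    p_da <- nn_init(Ld); p_db <- nn_init(Ld)
    opt <- list(ab = adam_new(p_ab), ba = adam_new(p_ba),
                da = adam_new(p_da), db = adam_new(p_db))
    pool_a <- new.env(parent = emptyenv()); pool_a$items <- list()
    pool_b <- new.env(parent = emptyenv()); pool_b$items <- list()
    f32 <- cfg$float32
    lam <- weights$lambda_identity
    hist <- vector("list", cfg$n_iterations)

    draw_patch <- function(vols) {
      v <- vols[[if (length(vols) > 1L) sample.int(length(vols), 1L) else 1L]]
      p <- sample_patch(v, ps)
      if (cfg$reject_air_patches) {
        tries <- 0L
        while (all(p < cfg$air_threshold) && tries < 20L) {
          p <- sample_patch(v, ps)
          tries <- tries + 1L
        }
      }
      dim4(p)
    }

    for (it in seq_len(cfg$n_iterations)) {
      a <- draw_patch(vols_a)
      b <- draw_patch(vols_b)

      # ---- generator step (both directions jointly) ----
      fab <- nn_forward(Lg, p_ab, a, f32)    # fake B from a
      fba <- nn_forward(Lg, p_ba, b, f32)    # fake A from b
      rba <- nn_forward(Lg, p_ba, fab$y, f32)  # reconstructed a
      rab <- nn_forward(Lg, p_ab, fba$y, f32)  # reconstructed b
      iba <- nn_forward(Lg, p_ba, a, f32)    # identity of G_BA on a
      iab <- nn_forward(Lg, p_ab, b, f32)    # identity of G_AB on b
      sdb <- nn_forward(Ld, p_db, fab$y, f32)
      sda <- nn_forward(Ld, p_da, fba$y, f32)

      adv_ab <- mean((sdb$y - 1)^2)
      adv_ba <- mean((sda$y - 1)^2)
      cycA <- cycle_loss_cached(dim3(a), dim3(rba$y))
      cycB <- cycle_loss_cached(dim3(b), dim3(rab$y))
      idn_a <- mean(abs(iba$y - a))
      idn_b <- mean(abs(iab$y - b))
      check_finite_loss(list(adversarial_ab = adv_ab,
                             adversarial_ba = adv_ba,
                             cycle_a = cycA$value, cycle_b = cycB$value,
                             identity_a = idn_a, identity_b = idn_b), it)

      g_sdb <- 2 * (sdb$y - 1) / length(sdb$y)
      g_sda <- 2 * (sda$y - 1) / length(sda$y)
      thru_db <- nn_backward(Ld, p_db, sdb$caches, g_sdb, f32,
                             need_gw = FALSE)
      thru_da <- nn_backward(Ld, p_da, sda$caches, g_sda, f32,
                             need_gw = FALSE)

      g_rba <- dim4(cycle_loss_grad(dim3(a), dim3(rba$y), cycA))
      back_rba <- nn_backward(Lg, p_ba, rba$caches, g_rba, f32)
      g_rab <- dim4(cycle_loss_grad(dim3(b), dim3(rab$y), cycB))
      back_rab <- nn_backward(Lg, p_ab, rab$caches, g_rab, f32)

      back_fab <- nn_backward(Lg, p_ab, fab$caches,
                              thru_db$gx + back_rba$gx, f32,
                              need_gx = FALSE)
      back_fba <- nn_backward(Lg, p_ba, fba$caches,
                              thru_da$gx + back_rab$gx, f32,
                              need_gx = FALSE)

      g_iba <- lam * sign(iba$y - a) / length(a)
      back_iba <- nn_backward(Lg, p_ba, iba$caches, g_iba, f32,
                              need_gx = FALSE)
      g_iab <- lam * sign(iab$y - b) / length(b)
      back_iab <- nn_backward(Lg, p_ab, iab$caches, g_iab, f32,
                              need_gx = FALSE)

      gr_ab <- tree_add(tree_add(back_fab$grads, back_rab$grads),
                        back_iab$grads)
      gr_ba <- tree_add(tree_add(back_fba$grads, back_rba$grads),
                        back_iba$grads)
      st <- adam_step(opt$ab, p_ab, gr_ab, cfg$learning_rate,
                      cfg$beta1, cfg$beta2)
      opt$ab <- st$state; p_ab <- st$params
      st <- adam_step(opt$ba, p_ba, gr_ba, cfg$learning_rate,
                      cfg$beta1, cfg$beta2)
      opt$ba <- st$state; p_ba <- st$params

      # ---- discriminator steps ----
      fake_b <- pool_query(pool_b, fab$y, cfg$image_pool_size)
      fake_a <- pool_query(pool_a, fba$y, cfg$image_pool_size)

      disc_update <- function(p_d, opt_d, real, fake) {
        r1 <- nn_forward(Ld, p_d, real, f32)
        r2 <- nn_forward(Ld, p_d, fake, f32)
        loss <- 0.5 * (mean((r1$y - 1)^2) + mean(r2$y^2))
        b1 <- nn_backward(Ld, p_d, r1$caches, (r1$y - 1) / length(r1$y),
                          f32, need_gx = FALSE)
        b2 <- nn_backward(Ld, p_d, r2$caches, r2$y / length(r2$y),
                          f32, need_gx = FALSE)
        st <- adam_step(opt_d, p_d, tree_add(b1$grads, b2$grads),
                        cfg$learning_rate, cfg$beta1, cfg$beta2)
        list(params = st$params, opt = st$state, loss = loss)
      }
      ub <- disc_update(p_db, opt$db, b, fake_b)
      p_db <- ub$params; opt$db <- ub$opt
      ua <- disc_update(p_da, opt$da, a, fake_a)
      p_da <- ua$params; opt$da <- ua$opt
      check_finite_loss(list(discriminator_a = ua$loss,
                             discriminator_b = ub$loss), it)

      hist[[it]] <- c(iteration = it, adv_ab = adv_ab, adv_ba = adv_ba,
                      cyc_a = cycA$value, cyc_b = cycB$value,
                      idn_a = idn_a, idn_b = idn_b,
                      disc_a = ua$loss, disc_b = ub$loss,
                      total_g = adv_ab + adv_ba + cycA$value + cycB$value +
                        lam * (idn_a + idn_b))
      if (verbose && it %% 100L == 0L)
        message(sprintf("iter %d: G=%.4f Da=%.4f Db=%.4f", it,
                        hist[[it]]["total_g"], ua$loss, ub$loss))
      if (is.finite(cfg$checkpoint_every) &&
          it %% cfg$checkpoint_every == 0L && !is.null(cfg$checkpoint_dir)) {
        fit <- assemble_fit(gen_spec, disc_spec, p_ab, p_ba, p_da, p_db,
                            hist[seq_len(it)], weights, cfg)
        save_checkpoint(fit,
                        file.path(cfg$checkpoint_dir,
                                  sprintf("checkpoint_%06d.rds", it)))
      }
    }
    assemble_fit(gen_spec, disc_spec, p_ab, p_ba, p_da, p_db, hist,
                 weights, cfg)
  })
}

assemble_fit <- function(gen_spec, disc_spec, p_ab, p_ba, p_da, p_db,
                         hist, weights, cfg) {
  as_gen <- function(p) structure(
    list(layers = generator_layers(gen_spec), params = p, spec = gen_spec),
    class = "ct_generator")
  as_disc <- function(p) structure(
    list(layers = discriminator_layers(disc_spec), params = p,
         spec = disc_spec),
    class = "ct_discriminator")
  structure(list(
    g_ab = as_gen(p_ab), g_ba = as_gen(p_ba),
    d_a = as_disc(p_da), d_b = as_disc(p_db),
    history = tibble::as_tibble(do.call(rbind, hist)),
    weights = weights, cfg = cfg),
    class = "cyclegan_fit")
}

#' @export
print.cyclegan_fit <- function(x, ...) {
  cat("<cyclegan_fit> ", nrow(x$history), " iterations, patch ",
      x$cfg$patch_size, "^3, base_filters ", x$g_ab$spec$base_filters,
      ", lambda_identity ", x$weights$lambda_identity, "\n", sep = "")
  cat("final losses: ",
      paste(sprintf("%s=%.4f", c("total_g", "disc_a", "disc_b"),
                    unlist(x$history[nrow(x$history),
                                     c("total_g", "disc_a", "disc_b")])),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Save / load a cycle-GAN checkpoint
#'
#' A checkpoint is a single file holding the architecture descriptors, all
#' four parameter trees, the loss weights and the training configuration
#' (including the seed), so a run is fully reconstructable.
#'
#' @param fit A `cyclegan_fit`.
#' @param path Destination file.
#' @returns `load_checkpoint()` returns the `cyclegan_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "cyclegan_fit"))
  saveRDS(list(gen_spec = fit$g_ab$spec, disc_spec = fit$d_a$spec,
               p_ab = fit$g_ab$params, p_ba = fit$g_ba$params,
               p_da = fit$d_a$params, p_db = fit$d_b$params,
               history = fit$history, weights = fit$weights,
               cfg = fit$cfg),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  fit <- assemble_fit(x$gen_spec, x$disc_spec, x$p_ab, x$p_ba, x$p_da,
                      x$p_db, list(), x$weights, x$cfg)
  fit$history <- x$history
  fit
}
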