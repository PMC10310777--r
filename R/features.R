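#' Convolutional feature backbone (pluggable contract)
#'
#' A feature extractor maps a 3-channel byte image to a fixed-length vector
#' by running a convolutional stack and taking, per output channel, the
#' maximum over all spatial positions (global max pooling). The default
#' desk-scale backbone is a small random-weight convolutional stack; an
#' externally supplied backbone (e.g. an RGB-pretrained network exported as
#' weights) can implement the same contract.
#'
#' @param n_channels Output channel count = feature vector length.
#' @param depth Number of 3x3 conv + ReLU blocks.
#' @param seed Seed for the random weights (fixed weights = deterministic
#'   features).
#' @returns An object of class `feature_extractor`.
#' @seealso [extract_pooled_features()]
#' @export
tiny_backbone <- function(n_channels = 8L, depth = 2L, seed = 1L) {
  stopifnot(n_channels >= 1, depth >= 1)
  with_preserved_rng({
    set.seed(seed)
    chans <- c(3L, rep(as.integer(n_channels), depth))
    weights <- lapply(seq_len(depth), function(i) {
      list(w = array(stats::rnorm(9 * chans[i] * chans[i + 1],
                                  sd = sqrt(2 / (9 * chans[i]))),
                     c(3L, 3L, 1L, chans[i], chans[i + 1])),
           b = numeric(chans[i + 1]))
    })
    structure(list(weights = weights, n_features = as.integer(n_channels),
                   depth = as.integer(depth), seed = as.integer(seed)),
              class = "feature_extractor")
  })
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat("<feature_extractor> random-weight conv stack, depth ", x$depth,
      ", ", x$n_features, " pooled features\n", sep = "")
  invisible(x)
}

#' Apply a feature extractor to one byte image
#'
#' @param object A `feature_extractor`.
#' @param image `(H, W, 3)` byte array (see [vgg_byte_normalize()]).
#' @param ... Unused.
#' @returns Numeric feature vector of length `n_features`.
#' @export
predict.feature_extractor <- function(object, image, ...) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an (H, W, 3) byte image")
  x <- array(as.numeric(image) / 255, c(d[1], d[2], 1L, 3L))
  for (lw in object$weights) {
    x <- cn_conv3d_fwd(x, dim(x), lw$w, dim(lw$w), lw$b,
                       c(1L, 1L, 1L), c(1L, 1L, 0L), FALSE)
    x <- cn_act_fwd(x, 0L, 0)
  }
  apply(x, 4L, max)
}

#' Extract pooled deep features from a set of slices
#'
#' Pipeline used by the deep-feature discrimination experiment: each
#' Hounsfield-unit slice is body-masked (background set to air so features
#' represent the body only), byte-normalized, and passed through the
#' backbone; per channel the spatial maximum is retained.
#'
#' @param slices Named list of 2D matrices in HU (all the same shape).
#' @param extractor A `feature_extractor`.
#' @param mask_fn Function producing a logical body mask from an HU slice;
#'   `NULL` disables masking.
#' @returns A feature table: tibble with `image_id` plus one `f<k>` column
#'   per backbone channel.
#' @export
extract_pooled_features <- function(slices, extractor = tiny_backbone(),
                                    mask_fn = body_mask) {
  stopifnot(length(slices) >= 1)
  dims <- unique(lapply(slices, dim))
  if (length(dims) != 1L)
    stop("all slices must share the same shape")
  ids <- names(slices)
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(slices))
  feats <- t(vapply(slices, function(sl) {
    if (!is.null(mask_fn)) {
      m <- mask_fn(sl)
      sl[!m] <- -1000
    }
    predict(extractor, vgg_byte_normalize(sl))
  }, numeric(extractor$n_features)))
  colnames(feats) <- sprintf("f%d", seq_len(ncol(feats)))
  dplyr::bind_cols(tibble::tibble(image_id = ids),
                   tibble::as_tibble(feats))
}

#' Classification head specification
#'
#' Fully connected head with sigmoid hidden activations, He-uniform
#' weight/bias initialisation and an L1 penalty on all weights and biases,
#' ending in a sigmoid output unit.
#'
#' @param hidden Strictly decreasing hidden layer sizes (reference:
#'   256, 128, 64, 32, 16).
#' @param l1 L1 penalty coefficient on weights and biases.
#' @returns An object of class `classifier_head_spec`.
#' @export
classifier_head_spec <- function(hidden = c(256L, 128L, 64L, 32L, 16L),
                                 l1 = 1e-5) {
  if (any(diff(hidden) >= 0)) stop("hidden sizes must be strictly decreasing")
  if (l1 < 0) stop("l1 penalty must be non-negative")
  structure(list(hidden = as.integer(hidden), l1 = l1),
            class = "classifier_head_spec")
}

he_uniform <- function(fan_in, n) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n, -lim, lim)
}

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(he_uniform(sizes[i], sizes[i] * sizes[i + 1]),
                    sizes[i], sizes[i + 1]),
         b = he_uniform(sizes[i], sizes[i + 1]))
  })
}

mlp_forward <- function(params, X) {
  acts <- vector("list", length(params))
  a <- X
  for (i in seq_along(params)) {
    z <- a %*% params[[i]]$W +
      matrix(params[[i]]$b, nrow(a), length(params[[i]]$b), byrow = TRUE)
    a <- 1 / (1 + exp(-z))
    acts[[i]] <- a
  }
  list(p = a[, 1L], acts = acts)
}

mlp_grads <- function(params, X, y, acts, l1) {
  n <- nrow(X)
  grads <- vector("list", length(params))
  delta <- matrix((acts[[length(acts)]][, 1L] - y) / n)  # BCE + sigmoid
  for (i in rev(seq_along(params))) {
    a_prev <- if (i == 1L) X else acts[[i - 1L]]
    gW <- crossprod(a_prev, delta) + l1 * sign(params[[i]]$W)
    gb <- colSums(delta) + l1 * sign(params[[i]]$b)
    if (i > 1L) {
      da <- delta %*% t(params[[i]]$W)
      delta <- da * acts[[i - 1L]] * (1 - acts[[i - 1L]])
    }
    grads[[i]] <- list(W = gW, b = gb)
  }
  grads
}

bce_loss <- function(p, y, params, l1) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)) +
    l1 * sum(vapply(params, function(q) sum(abs(q$W)) + sum(abs(q$b)), 0))
}

binary_metrics <- function(p, y) {
  pred <- p >= 0.5
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1)
  c(auc = roc_auc(p, y),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Train the deep-feature classification head
#'
#' Repeat-averaged training of the fully connected head on pooled features.
#' An outer stratified split holds out `1 - train_frac` of subjects as a
#' test set; within the training pool, each repeat samples a fresh
#' class-balanced validation subset of `validation_n` subjects, trains on
#' the remainder with Adam and binary cross entropy, and records per-epoch
#' loss/AUC/precision/recall for the training and validation subsets.
#' Curves are aggregated to mean and standard error over repeats.
#'
#' Reference schedule: 2500 epochs, learning rate 1e-4, batch 28,
#' validation 48 of a 160-subject pool, 30 repeats. Scale all of these down
#' together for desk-scale experiments.
#'
#' @param features Feature table from [extract_pooled_features()] (the
#'   `image_id` column is ignored for fitting).
#' @param labels Binary labels (0/1 or two-level factor), one per row.
#' @param spec A [classifier_head_spec()].
#' @param epochs,learning_rate,batch_size Optimisation schedule.
#' @param train_frac Outer stratified train fraction.
#' @param validation_n Balanced validation subset size per repeat.
#' @param repeats Independent repeats (fresh validation sample + init).
#' @param seed RNG seed.
#' @param record_every Record metrics every this many epochs (1 = every
#'   epoch).
#' @returns An object of class `curve_stats`: `curves` (tibble: epoch,
#'   split, metric, mean, sem), `final` (terminal summary), and the
#'   configuration.
#' @export
train_head <- function(features, labels, spec = classifier_head_spec(),
                       epochs = 2500L, learning_rate = 1e-4,
                       batch_size = 28L, train_frac = 0.8,
                       validation_n = 48L, repeats = 30L, seed = 1L,
                       record_every = 1L) {
  X <- as.matrix(dplyr::select(features, -dplyr::any_of(
    c("image_id", "subject_id", "label", "group"))))
  storage.mode(X) <- "double"
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("need both classes present in the labels")
  if (nrow(X) != length(y)) stop("features and labels disagree in length")

  with_preserved_rng({
    set.seed(seed)
    # outer stratified split: train pool vs held-out test
    pool <- unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, round(train_frac * length(ix)))))
    if (validation_n >= length(pool))
      stop("validation_n must be smaller than the training pool")
    if (validation_n %% 2L != 0L)
      stop("validation_n must be even (split evenly between both classes)")
    sizes <- c(ncol(X), spec$hidden, 1L)
    rec_ep <- unique(c(seq(1L, epochs, by = record_every), epochs))
    runs <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      by_cls <- split(pool, y[pool])
      val <- unlist(lapply(by_cls, function(ix)
        sample(ix, validation_n / 2)))
      tr <- setdiff(pool, val)
      params <- mlp_init(sizes)
      mstate <- lapply(params, function(q) list(W = q$W * 0, b = q$b * 0))
      vstate <- mstate
      t_ad <- 0L
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      Xva <- X[val, , drop = FALSE]; yva <- y[val]
      rows <- vector("list", length(rec_ep)); ri <- 1L
      for (ep in seq_len(epochs)) {
        ord <- sample(length(ytr))
        for (b0 in seq(1L, length(ord), by = batch_size)) {
          ix <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
          fwd <- mlp_forward(params, Xtr[ix, , drop = FALSE])
          gr <- mlp_grads(params, Xtr[ix, , drop = FALSE], ytr[ix],
                          fwd$acts, spec$l1)
          t_ad <- t_ad + 1L
          bc1 <- 1 - 0.9^t_ad; bc2 <- 1 - 0.999^t_ad
          for (i in seq_along(params)) for (nm in c("W", "b")) {
            mstate[[i]][[nm]] <- 0.9 * mstate[[i]][[nm]] + 0.1 * gr[[i]][[nm]]
            vstate[[i]][[nm]] <- 0.999 * vstate[[i]][[nm]] +
              0.001 * gr[[i]][[nm]]^2
            params[[i]][[nm]] <- params[[i]][[nm]] -
              learning_rate * (mstate[[i]][[nm]] / bc1) /
                (sqrt(vstate[[i]][[nm]] / bc2) + 1e-8)
          }
        }
        if (ep %in% rec_ep) {
          ptr <- mlp_forward(params, Xtr)$p
          pva <- mlp_forward(params, Xva)$p
          rows[[ri]] <- tibble::tibble(
            epoch = ep,
            split = rep(c("training", "validation"), each = 4L),
            metric = rep(c("loss", "auc", "precision", "recall"), 2L),
            value = c(bce_loss(ptr, ytr, params, spec$l1),
                      binary_metrics(ptr, ytr),
                      bce_loss(pva, yva, params, spec$l1),
                      binary_metrics(pva, yva)))
          ri <- ri + 1L
        }
      }
      runs[[r]] <- dplyr::bind_rows(rows)
    }
    all <- dplyr::bind_rows(runs, .id = "repeat_id")
    curves <- all |>
      dplyr::group_by(.data$epoch, .data$split, .data$metric) |>
      dplyr::summarise(
        mean = mean(.data$value, na.rm = TRUE),
        sem = stats::sd(.data$value, na.rm = TRUE) /
          sqrt(sum(!is.na(.data$value))),
        .groups = "drop")
    final <- dplyr::filter(curves, .data$epoch == max(.data$epoch))
    structure(list(curves = curves, final = final,
                   repeats = repeats, epochs = epochs,
                   validation_n = validation_n, seed = seed),
              class = "curve_stats")
  })
}

#' @export
print.curve_stats <- function(x, ...) {
  cat("<curve_stats> ", x$repeats, " repeats x ", x$epochs, " epochs\n",
      sep = "")
  fin <- dplyr::filter(x$final, .data$metric == "auc")
  for (i in seq_len(nrow(fin)))
    cat(sprintf("  terminal %s AUC: %.3f +/- %.3f (SEM)\n",
                fin$split[i], fin$mean[i], fin$sem[i]))
  invisible(x)
}

#' @export
tidy.curve_stats <- function(x, ...) x$curves

#' @export
glance.curve_stats <- function(x, ...) {
  fin <- tidyr::pivot_wider(x$final,
                            names_from = c("split", "metric"),
                            values_from = c("mean", "sem"))
  dplyr::bind_cols(tibble::tibble(repeats = x$repeats, epochs = x$epochs),
                   fin[, setdiff(names(fin), "epoch")])
}

#' Terminal validation AUC of a trained head
#'
#' @param x A `curve_stats`.
#' @returns A list with `mean` and `sem` of the last-epoch validation AUC.
#' @export
final_validation_auc <- function(x) {
  stopifnot(inherits(x, "curve_stats"))
  fin <- dplyr::filter(x$final, .data$split == "validation",
                       .data$metric == "auc")
  list(mean = fin$mean, sem = fin$sem)
}

#' Shuffled-label null control
#'
#' Uniform random permutation of the labels, preserving class counts: the
#' null model against which real feature-label association is judged.
#'
#' @param labels Label vector.
#' @param seed Optional seed (uses and restores a local RNG state).
#' @returns Permuted labels.
#' @export
shuffled_label_control <- function(labels, seed = NULL) {
  if (is.null(seed)) return(sample(labels))
  with_preserved_rng({
    set.seed(seed)
    sample(labels)
  })
}
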