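# Handcrafted-radiomics arm: feature filtering, drift, ROC machinery.
#
# A "feature table" is a tibble whose non-feature columns are limited to
# subject_id, label and group; every other column is a named numeric
# feature.

feature_cols <- function(t) {
  setdiff(names(t), c("subject_id", "image_id", "label", "group"))
}

#' Remove highly correlated features
#'
#' Greedy mean-absolute-correlation heuristic: while any absolute pairwise
#' Pearson correlation exceeds the threshold, take the worst pair and drop
#' the member with the larger mean absolute correlation to all remaining
#' features (lexicographic tie-break on feature name, so the result is
#' deterministic). Zero-variance features are removed first with a warning
#' (their correlation is undefined).
#'
#' @param t Feature table (tibble; columns `subject_id`, `label`, `group`
#'   are passed through untouched).
#' @param threshold Absolute correlation above which a pair is "high"
#'   (reference value 0.9). A threshold of 1 leaves the table unchanged.
#' @returns The table with offending features dropped; the removed names
#'   are in `attr(, "dropped")`.
#' @export
drop_correlated <- function(t, threshold = 0.9) {
  fc <- feature_cols(t)
  if (length(fc) < 2L) stop("need at least 2 features")
  X <- as.matrix(t[, fc])
  sds <- apply(X, 2L, stats::sd)
  dropped <- character()
  if (any(sds == 0 | is.na(sds))) {
    zv <- fc[sds == 0 | is.na(sds)]
    warning("removing zero-variance feature(s): ", paste(zv, collapse = ", "))
    dropped <- zv
    fc <- setdiff(fc, zv)
    X <- X[, fc, drop = FALSE]
  }
  if (length(fc) >= 2L && threshold < 1) {
    cm <- abs(stats::cor(X))
    diag(cm) <- 0
    while (length(fc) > 1L && max(cm) > threshold) {
      worst <- which(cm == max(cm), arr.ind = TRUE)
      # candidate pair of the single worst correlation; deterministic order
      pair <- sort(rownames(cm)[worst[1L, , drop = TRUE]])
      mac <- rowMeans(cm)
      drop <- if (mac[pair[1]] > mac[pair[2]]) pair[1]
        else if (mac[pair[2]] > mac[pair[1]]) pair[2]
        else pair[1]   # tie: lexicographically first
      dropped <- c(dropped, drop)
      keep <- setdiff(rownames(cm), drop)
      cm <- cm[keep, keep, drop = FALSE]
      fc <- keep
    }
  }
  out <- t[, c(setdiff(names(t), setdiff(feature_cols(t), fc)))]
  attr(out, "dropped") <- dropped
  out
}

#' Select features by Kendall rank association with the label
#'
#' Keeps features whose absolute Kendall tau-b with the binary label
#' reaches the threshold (tau-b handles the heavy ties a binary label
#' induces; the absolute value makes selection sign-invariant). Invariant
#' under strictly monotone transforms of any feature.
#'
#' @param t Feature table with a binary `label` column.
#' @param threshold Minimum `|tau-b|` (reference value 0.2).
#' @returns The table restricted to selected features; tau values in
#'   `attr(, "tau")`.
#' @export
kendall_select <- function(t, threshold = 0.2) {
  if (!"label" %in% names(t)) stop("feature table must have a label column")
  y <- if (is.factor(t$label)) as.integer(t$label) - 1L else
    as.numeric(t$label)
  if (length(unique(y)) < 2L)
    stop("labels are constant; Kendall selection undefined")
  fc <- feature_cols(t)
  tau <- vapply(fc, function(f)
    suppressWarnings(stats::cor(t[[f]], y, method = "kendall")), 0)
  keep <- fc[!is.na(tau) & abs(tau) >= threshold]
  out <- t[, c(setdiff(names(t), setdiff(fc, keep)))]
  attr(out, "tau") <- tau
  out
}

#' Standardize features (z-score)
#'
#' Optional preprocessing; centering/scaling statistics may be supplied
#' (e.g. from a training cohort) or computed from the table itself.
#'
#' @param t Feature table.
#' @param center,scale Optional named vectors of means / SDs.
#' @returns Standardized table with `center`/`scale` attributes.
#' @export
standardize_features <- function(t, center = NULL, scale = NULL) {
  fc <- feature_cols(t)
  if (is.null(center)) center <- vapply(t[fc], mean, 0)
  if (is.null(scale)) scale <- vapply(t[fc], stats::sd, 0)
  for (f in fc) t[[f]] <- (t[[f]] - center[[f]]) /
      ifelse(scale[[f]] > 0, scale[[f]], 1)
  attr(t, "center") <- center
  attr(t, "scale") <- scale
  t
}

#' Absolute percentage drift of features under style transfer
#'
#' Per subject and feature, `100 * |post - pre| / |pre|`: how much a
#' feature value moved when its source image was passed through the
#' generative model. Subjects with `pre == 0` are excluded from that
#' feature's distribution and counted in an exclusion tally (no value is
#' substituted).
#'
#' @param pre,post Feature tables with identical `subject_id` sets and
#'   feature names (pre- and post-translation).
#' @returns An object of class `drift_result`: `drift` (long tibble:
#'   subject_id, feature, drift_pct), `summary` (per-feature median/mean/
#'   max and exclusion tally), `n_excluded`.
#' @examples
#' pre <- tibble::tibble(subject_id = c("a", "b"), f1 = c(2, 4))
#' post <- tibble::tibble(subject_id = c("a", "b"), f1 = c(12, 4))
#' abs_pct_diff(pre, post)$drift
#' @export
abs_pct_diff <- function(pre, post) {
  fc <- feature_cols(pre)
  if (!setequal(fc, feature_cols(post)))
    stop("feature names differ: ",
         paste(symdiff_chr(fc, feature_cols(post)), collapse = ", "))
  if (!"subject_id" %in% names(pre)) pre$subject_id <-
      sprintf("s%03d", seq_len(nrow(pre)))
  if (!"subject_id" %in% names(post)) post$subject_id <-
      sprintf("s%03d", seq_len(nrow(post)))
  if (!setequal(pre$subject_id, post$subject_id) ||
      nrow(pre) != nrow(post))
    stop("subject sets differ between the two tables: ",
         paste(symdiff_chr(pre$subject_id, post$subject_id),
               collapse = ", "))
  post <- post[match(pre$subject_id, post$subject_id), ]
  long <- tidyr::pivot_longer(
    dplyr::select(pre, "subject_id", dplyr::all_of(fc)),
    -"subject_id", names_to = "feature", values_to = "pre")
  long$post <- tidyr::pivot_longer(
    dplyr::select(post, "subject_id", dplyr::all_of(fc)),
    -"subject_id", names_to = "feature", values_to = "post")$post
  long$excluded <- long$pre == 0
  long$drift_pct <- ifelse(long$excluded, NA_real_,
                           100 * abs(long$post - long$pre) / abs(long$pre))
  summary <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      median_drift_pct = stats::median(.data$drift_pct, na.rm = TRUE),
      mean_drift_pct = mean(.data$drift_pct, na.rm = TRUE),
      max_drift_pct = max(c(-Inf, .data$drift_pct)[is.finite(
        c(-Inf, .data$drift_pct))]),
      n_excluded = sum(.data$excluded),
      .groups = "drop")
  structure(list(
    drift = dplyr::select(long[!long$excluded, ],
                          "subject_id", "feature", "drift_pct"),
    summary = summary,
    n_excluded = sum(long$excluded)),
    class = "drift_result")
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' @export
print.drift_result <- function(x, ...) {
  cat("<drift_result> ", nrow(x$summary), " features, ",
      nrow(x$drift), " subject-feature drifts, ",
      x$n_excluded, " excluded (pre = 0)\n", sep = "")
  print(x$summary, n = 10)
  invisible(x)
}

#' @export
tidy.drift_result <- function(x, ...) x$drift

#' @export
glance.drift_result <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$summary),
                 n_drifts = nrow(x$drift),
                 n_excluded = x$n_excluded,
                 median_drift_pct = stats::median(x$drift$drift_pct),
                 max_drift_pct = max(x$drift$drift_pct))
}

#' Rank-statistic ROC AUC
#'
#' The probability that a random positive scores above a random negative,
#' with ties counted one half (Mann-Whitney statistic).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or two-level factor).
#' @returns AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))   # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Both score vectors are evaluated on the same subjects; subjects are
#' resampled with replacement stratified by class (resamples that lose a
#' class are redrawn), the AUC difference is recomputed per resample, and a
#' two-sided p-value is taken from the normal approximation to the
#' bootstrap distribution of the difference (the approach of bootstrap ROC
#' comparison tests). A degenerate bootstrap spread (identical scores)
#' yields p = 1.
#'
#' @param scores1,scores2 Paired score vectors.
#' @param labels Binary labels.
#' @param n_boot Bootstrap resamples (reference value 2000; below 100 a
#'   warning is issued).
#' @param seed RNG seed.
#' @returns A one-row tibble: `auc1`, `auc2`, `delta_auc`, `p_value`,
#'   `n_boot`.
#' @export
bootstrap_auc_compare <- function(scores1, scores2, labels,
                                  n_boot = 2000L, seed = 1L) {
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(labels))
    stop("scores1, scores2 and labels must be paired (equal length)")
  if (n_boot < 100L) warning("n_boot < 100 gives an unstable p-value")
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  auc1 <- roc_auc(scores1, y)
  auc2 <- roc_auc(scores2, y)
  delta <- auc1 - auc2
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  with_preserved_rng({
    set.seed(seed)
    deltas <- vapply(seq_len(n_boot), function(b) {
      repeat {
        ix <- c(sample(idx1, replace = TRUE), sample(idx0, replace = TRUE))
        if (length(unique(y[ix])) == 2L) break
      }
      roc_auc(scores1[ix], y[ix]) - roc_auc(scores2[ix], y[ix])
    }, 0)
    sd_b <- stats::sd(deltas)
    # degenerate bootstrap spread: identical AUCs in every resample
    p <- if (sd_b < .Machine$double.eps) {
      if (abs(delta) < .Machine$double.eps) 1 else 0
    } else 2 * stats::pnorm(-abs(delta / sd_b))
    tibble::tibble(auc1 = auc1, auc2 = auc2, delta_auc = delta,
                   p_value = p, n_boot = as.integer(n_boot))
  })
}

#' Built-in penalized-linear scorer (pluggable contract)
#'
#' A scorer is `function(train_features, train_labels)` returning
#' `function(new_features) -> scores`. This built-in fits a ridge-penalized
#' logistic regression on standardized features; external model families
#' can be plugged in through the same contract.
#'
#' @param lambda Ridge penalty.
#' @returns A scorer function.
#' @export
penalized_logistic_scorer <- function(lambda = 1e-2) {
  function(train_x, train_y) {
    X <- as.matrix(train_x[, feature_cols(train_x)])
    y <- if (is.factor(train_y)) as.integer(train_y) - 1L else
      as.integer(train_y)
    mu <- colMeans(X); sd <- apply(X, 2L, stats::sd); sd[sd == 0] <- 1
    Xs <- scale(X, mu, sd)
    p <- ncol(Xs)
    beta <- numeric(p + 1L)
    # Newton iterations with ridge on the non-intercept terms
    Z <- cbind(1, Xs)
    for (it in 1:50) {
      eta <- drop(Z %*% beta)
      mu_i <- 1 / (1 + exp(-eta))
      wts <- pmax(mu_i * (1 - mu_i), 1e-6)
      H <- crossprod(Z, Z * wts) + diag(c(0, rep(lambda, p)))
      g <- crossprod(Z, y - mu_i) - c(0, lambda * beta[-1L])
      step <- solve(H, g)
      beta <- beta + step
      if (max(abs(step)) < 1e-8) break
    }
    function(new_x) {
      Xn <- scale(as.matrix(new_x[, feature_cols(new_x)]), mu, sd)
      drop(1 / (1 + exp(-(cbind(1, Xn) %*% beta))))
    }
  }
}

#' First-order intensity features of a masked region
#'
#' Simple stand-in radiomic features (mean, SD, quantiles, energy, entropy
#' of a 25-bin histogram) of the voxels under a mask — enough structure to
#' exercise selection, drift and ROC machinery on phantoms.
#'
#' @param vol A [ct_volume()] or 3D array.
#' @param mask Logical mask (defaults to the whole grid).
#' @param bins Histogram bins for the entropy/energy features.
#' @returns A one-row tibble of named features.
#' @export
intensity_features <- function(vol, mask = NULL, bins = 25L) {
  v <- vol_values(vol)
  x <- if (is.null(mask)) as.numeric(v) else v[mask]
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  p <- h / sum(h)
  p_nz <- p[p > 0]
  tibble::tibble(
    mean = mean(x), sd = stats::sd(x),
    p10 = unname(stats::quantile(x, 0.1)),
    median = stats::median(x),
    p90 = unname(stats::quantile(x, 0.9)),
    iqr = stats::IQR(x),
    skewness = mean((x - mean(x))^3) / stats::sd(x)^3,
    energy = sum(p^2),
    entropy = -sum(p_nz * log2(p_nz)))
}
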