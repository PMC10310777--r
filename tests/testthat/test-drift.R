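test_that("duplicate features collapse to a single survivor", {
  t <- random_feature_table(n = 20L, p = 2L, seed = 1)
  t$f02 <- t$f01
  out <- suppressWarnings(drop_correlated(t, 0.9))
  fc <- setdiff(names(out), c("subject_id", "label"))
  expect_length(fc, 1L)
})

test_that("near-duplicates are dropped while independents survive", {
  set.seed(2)
  n <- 20L
  t <- tibble::tibble(f1 = rnorm(n))
  t$f2 <- t$f1 + rnorm(n, sd = 0.05)   # corr ~ 0.999
  t$f3 <- rnorm(n)
  out <- drop_correlated(t, 0.9)
  fc <- names(out)
  expect_length(fc, 2L)
  expect_true("f3" %in% fc)
  # threshold 1 leaves the table unchanged
  expect_identical(names(drop_correlated(t, 1.0)), names(t))
})

test_that("zero-variance features are removed first with a warning", {
  t <- random_feature_table(n = 15L, p = 3L, seed = 3)
  t$f03 <- 5
  expect_warning(out <- drop_correlated(t, 0.9), "zero-variance")
  expect_false("f03" %in% names(out))
})

test_that("no surviving pair exceeds the threshold (exhaustive recheck)", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 25L; p <- 8L
    X <- matrix(rnorm(n * p), n, p)
    # manufacture correlated clusters
    X[, 2] <- X[, 1] + rnorm(n, sd = 0.2)
    X[, 5] <- -X[, 4] + rnorm(n, sd = 0.1)
    t <- tibble::as_tibble(as.data.frame(X))
    names(t) <- sprintf("f%02d", 1:p)
    thr <- 0.6
    out <- drop_correlated(t, thr)
    cm <- abs(stats::cor(as.matrix(out)))
    diag(cm) <- 0
    expect_lte(max(cm), thr)
  }
})

test_that("greedy removal agrees with the reference heuristic", {
  # caret::findCorrelation(exact = TRUE) implements the same
  # mean-absolute-correlation heuristic; cross-check survivors
  set.seed(4)
  n <- 30L; p <- 6L
  X <- matrix(rnorm(n * p), n, p)
  X[, 2] <- X[, 1] + rnorm(n, sd = 0.15)
  X[, 4] <- X[, 3] + rnorm(n, sd = 0.25)
  t <- tibble::as_tibble(as.data.frame(X))
  names(t) <- sprintf("f%02d", 1:p)
  ours <- setdiff(names(drop_correlated(t, 0.7)), "subject_id")
  drop_ref <- caret::findCorrelation(stats::cor(X), cutoff = 0.7,
                                     exact = TRUE)
  ref <- setdiff(sprintf("f%02d", 1:p), sprintf("f%02d", drop_ref))
  expect_setequal(ours, ref)
})

test_that("Kendall selection keeps label-aligned features, absolute in sign", {
  n <- 30L
  t <- tibble::tibble(label = rep(0:1, n / 2))
  t$f1 <- as.numeric(t$label)
  t$f2 <- -as.numeric(t$label)
  set.seed(5)
  t$f3 <- rnorm(n)
  out <- kendall_select(t, 0.2)
  expect_setequal(setdiff(names(out), "label"), c("f1", "f2"))
  expect_error(kendall_select(dplyr::mutate(t, label = 1), 0.2), "constant")
})

test_that("tau-b matches a brute-force pair-count oracle", {
  tau_brute <- function(x, y) {
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
      if (sx == 0 && sy == 0) next
      else if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
    n0 <- n * (n - 1) / 2
    (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
  }
  set.seed(6)
  x <- rnorm(60)
  y <- rep(0:1, 30)
  expect_equal(stats::cor(x, y, method = "kendall"), tau_brute(x, y),
               tolerance = 1e-12)
  # an independent feature has small tau and is dropped at 0.2
  t <- tibble::tibble(label = y, f1 = x)
  expect_lt(abs(stats::cor(x, y, method = "kendall")), 0.15)
  out <- kendall_select(t, 0.2)
  expect_false("f1" %in% names(out))
})

test_that("Kendall selection is invariant under monotone transforms", {
  set.seed(7)
  t <- tibble::tibble(label = rep(0:1, 20), f1 = rnorm(40) + rep(0:1, 20))
  tau1 <- attr(kendall_select(t, 0.2), "tau")
  t2 <- dplyr::mutate(t, f1 = exp(f1))
  tau2 <- attr(kendall_select(t2, 0.2), "tau")
  expect_equal(tau1, tau2, tolerance = 1e-12)
})

test_that("absolute percentage drift follows the documented rules", {
  pre <- tibble::tibble(subject_id = c("a", "b", "c"),
                        f1 = c(2, 4, 0), f2 = c(1, 1, 1))
  post_same <- pre
  d0 <- abs_pct_diff(pre, post_same)
  expect_true(all(d0$drift$drift_pct == 0))
  post <- tibble::tibble(subject_id = c("a", "b", "c"),
                         f1 = c(12, 4, 5), f2 = c(1.5, 0.5, 1))
  d <- abs_pct_diff(pre, post)
  expect_equal(d$drift$drift_pct[d$drift$subject_id == "a" &
                                   d$drift$feature == "f1"], 500)
  # pre = 0 cell excluded and tallied, not substituted
  expect_identical(d$n_excluded, 1L)
  expect_false(any(d$drift$subject_id == "c" & d$drift$feature == "f1"))
  expect_error(abs_pct_diff(pre, post[1:2, ]), "subject sets differ")
  expect_error(abs_pct_diff(pre, dplyr::rename(post, g1 = f1)),
               "feature names differ")
})

test_that("rank AUC matches exhaustive pair enumeration", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5)), 0.5)
  set.seed(8)
  s <- rnorm(40); y <- rep(0:1, 20)
  brute <- {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(roc_auc(s, y), brute, tolerance = 1e-12)
  # complement property
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1, tolerance = 1e-12)
  expect_error(roc_auc(s, rep(1, 40)), "both classes")
})

test_that("rank AUC agrees with the pROC reference implementation", {
  set.seed(9)
  s <- rnorm(60); y <- rep(0:1, 30)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})

test_that("bootstrap AUC comparison behaves at its edge cases", {
  set.seed(10)
  y <- rep(0:1, 25)
  s <- rnorm(50) + y
  same <- bootstrap_auc_compare(s, s, y, n_boot = 200, seed = 1)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  # perfectly separating vs anti-separating scores
  s1 <- y + 0.001 * rnorm(50)
  cmp <- bootstrap_auc_compare(s1, -s1, y, n_boot = 500, seed = 2)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$delta_auc, 1)
  # seed determinism
  c1 <- bootstrap_auc_compare(s, s1, y, n_boot = 200, seed = 3)
  c2 <- bootstrap_auc_compare(s, s1, y, n_boot = 200, seed = 3)
  expect_equal(c1$p_value, c2$p_value)
  expect_warning(bootstrap_auc_compare(s, s1, y, n_boot = 50, seed = 1),
                 "unstable")
})

test_that("the built-in penalized-linear scorer separates informative tables", {
  t <- random_feature_table(n = 60L, p = 4L, seed = 11, informative = 2L)
  tr <- t[1:40, ]; te <- t[41:60, ]
  scorer <- penalized_logistic_scorer()
  model <- scorer(tr[, 1:4], tr$label)
  auc <- roc_auc(model(te[, 1:4]), te$label)
  expect_gt(auc, 0.9)
})

test_that("intensity features expose mask-sensitive first-order statistics", {
  p <- tiny_pair(seed = 7, noise = 0)
  fv <- intensity_features(p$contrast, p$vessel_mask)
  fn <- intensity_features(p$noncontrast, p$vessel_mask)
  expect_identical(names(fv), names(fn))
  expect_equal(fv$mean - fn$mean, 300, tolerance = 1e-9)
})
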