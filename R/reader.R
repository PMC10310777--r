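#' Reconstruct reader confusions from printed rates
#'
#' Builds per-reader confusion counts from sensitivity/specificity and the
#' number of positive (acquired/real) and negative (synthetic) images
#' presented. The positive class is fixed as "acquired": sensitivity is the
#' fraction of acquired images called acquired, specificity the fraction of
#' synthetic images called synthetic. Rates that do not correspond to
#' integral counts (to within 1e-9) raise an error, since they cannot have
#' come from the stated denominators.
#'
#' @param sensitivity,specificity Proportions in \[0, 1\] (vectorised over
#'   readers).
#' @param n_pos,n_neg Images presented per class.
#' @param reader Optional reader labels.
#' @returns A tibble with one row per reader: `reader`, `tp`, `fn`, `tn`,
#'   `fp`.
#' @examples
#' confusion_from_rates(c(0.8, 0.92), c(0.62, 0.13), 100, 100)
#' @export
confusion_from_rates <- function(sensitivity, specificity,
                                 n_pos = 100L, n_neg = 100L,
                                 reader = NULL) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 |
            specificity > 1))
    stop("rates must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stop("counts must be positive")
  tp <- sensitivity * n_pos
  tn <- specificity * n_neg
  if (any(abs(tp - round(tp)) > 1e-9) || any(abs(tn - round(tn)) > 1e-9))
    stop("inconsistent rates: sensitivity*n_pos and specificity*n_neg ",
         "must be whole counts")
  k <- max(length(sensitivity), length(specificity))
  if (is.null(reader)) reader <- paste0("reader_", seq_len(k))
  tibble::tibble(reader = reader,
                 tp = as.integer(round(tp)),
                 fn = as.integer(n_pos - round(tp)),
                 tn = as.integer(round(tn)),
                 fp = as.integer(n_neg - round(tn)))
}

#' Per-reader performance metrics
#'
#' For a single-operating-point binary rater the ROC curve is the two
#' segments through (fpr, sensitivity), so AUC reduces to
#' `(sensitivity + specificity) / 2`.
#'
#' @param confusions Tibble with columns `tp`, `fn`, `tn`, `fp` (one row
#'   per reader), e.g. from [confusion_from_rates()].
#' @returns The input with `accuracy`, `sensitivity`, `specificity`, `auc`
#'   and `fpr` columns appended.
#' @examples
#' confusion_from_rates(0.8, 0.62) |> reader_metrics()
#' @export
reader_metrics <- function(confusions) {
  need <- c("tp", "fn", "tn", "fp")
  if (!all(need %in% names(confusions)))
    stop("confusions must have columns tp, fn, tn, fp")
  if (any(rowSums(confusions[, need]) == 0))
    stop("empty confusion: no images presented")
  dplyr::mutate(confusions,
    accuracy = (.data$tp + .data$tn) /
      (.data$tp + .data$fn + .data$tn + .data$fp),
    sensitivity = .data$tp / (.data$tp + .data$fn),
    specificity = .data$tn / (.data$tn + .data$fp),
    auc = (.data$sensitivity + .data$specificity) / 2,
    fpr = .data$fp / (.data$fp + .data$tn))
}

#' Panel-level summary of a reader study
#'
#' Unweighted means across readers. `mean_fpr_on_synthetic` is the mean
#' rate at which synthetic images were called real, i.e.
#' `mean(1 - specificity)` — the headline "fooling" rate of a modified
#' Turing test.
#'
#' @param confusions Tibble as accepted by [reader_metrics()].
#' @returns A one-row tibble: `n_readers`, `mean_accuracy`,
#'   `accuracy_min`, `accuracy_max`, `mean_auc`, `mean_fpr_on_synthetic`.
#' @export
panel_summary <- function(confusions) {
  m <- reader_metrics(confusions)
  tibble::tibble(
    n_readers = nrow(m),
    mean_accuracy = mean(m$accuracy),
    accuracy_min = min(m$accuracy),
    accuracy_max = max(m$accuracy),
    mean_auc = mean(m$auc),
    mean_fpr_on_synthetic = mean(1 - m$specificity))
}

#' Fleiss' Kappa for multi-rater agreement
#'
#' Chance-corrected agreement for `n` raters assigning `N` items to `k`
#' categories: `kappa = (P_bar - P_bar_e) / (1 - P_bar_e)` where `P_bar` is
#' the mean per-item observed agreement and `P_bar_e` the expected chance
#' agreement from the category margins.
#'
#' The optional large-sample z statistic (`z`, testing kappa = 0) uses the
#' standard Fleiss variance; it is an extension beyond the kappa itself and
#' is reported alongside.
#'
#' @param counts An `N x k` matrix of rating counts (`counts[i, j]` =
#'   raters assigning item `i` to category `j`; every row sums to the
#'   common rater count `n`), or a long tibble with columns `item_id`,
#'   `reader_id`, `category` (pivoted via [ratings_to_matrix()]).
#' @returns An object of class `fleiss_kappa` with `kappa`, `p_bar`,
#'   `p_bar_e`, `N`, `n`, `k`, `z`, `p_value`. Errors if all ratings fall
#'   in one category (chance agreement 1, kappa undefined).
#' @examples
#' fleiss_kappa(rbind(c(2, 0), c(0, 2)))          # kappa = 1
#' fleiss_kappa(rbind(c(2, 0), c(1, 1)))$kappa    # -1/3
#' @export
fleiss_kappa <- function(counts) {
  if (is.data.frame(counts)) counts <- ratings_to_matrix(counts)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 items and 2 categories")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts[1L, ])
  if (any(rowSums(counts) != n))
    stop("every item must be rated by the same number of raters")
  if (n < 2L) stop("need at least 2 raters per item")
  N <- nrow(counts); k <- ncol(counts)
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (N * n)
  p_bar_e <- sum(p_j^2)
  if (1 - p_bar_e < .Machine$double.eps)
    stop("kappa undefined: all ratings fall in a single category ",
         "(chance agreement is 1)")
  kappa <- (p_bar - p_bar_e) / (1 - p_bar_e)
  var0 <- 2 * (p_bar_e - (2 * n - 3) * p_bar_e^2 +
                 2 * (n - 2) * sum(p_j^3)) /
    (N * n * (n - 1) * (1 - p_bar_e)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else NA_real_
  structure(list(kappa = kappa, p_bar = p_bar, p_bar_e = p_bar_e,
                 N = N, n = n, k = k, z = z,
                 p_value = if (is.na(z)) NA_real_ else
                   2 * stats::pnorm(-abs(z))),
            class = "fleiss_kappa")
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat(sprintf(
    "Fleiss' Kappa: %.4f  (P_bar %.4f, P_bar_e %.4f; N=%d items, n=%d raters, k=%d categories)\n",
    x$kappa, x$p_bar, x$p_bar_e, x$N, x$n, x$k))
  if (!is.na(x$z))
    cat(sprintf("large-sample z = %.3f, p = %.4f (test of kappa = 0)\n",
                x$z, x$p_value))
  invisible(x)
}

#' @export
glance.fleiss_kappa <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, p_bar = x$p_bar, p_bar_e = x$p_bar_e,
                 n_items = x$N, n_raters = x$n, n_categories = x$k,
                 z = x$z, p_value = x$p_value)
}

#' Pivot a long rating table to a count matrix
#'
#' @param ratings Tibble with columns `item_id`, `reader_id`, `category`.
#' @returns An `N x k` integer matrix of counts suitable for
#'   [fleiss_kappa()].
#' @export
ratings_to_matrix <- function(ratings) {
  need <- c("item_id", "reader_id", "category")
  if (!all(need %in% names(ratings)))
    stop("ratings must have columns item_id, reader_id, category")
  if (anyDuplicated(ratings[, c("item_id", "reader_id")]))
    stop("duplicate (item_id, reader_id) ratings")
  tab <- table(ratings$item_id, ratings$category)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Simulate a panel rating table
#'
#' Generates a long rating table for `n_items` items rated by `n_readers`
#' readers into `categories`, where each reader labels each item correctly
#' with probability `accuracy` (independent readers, half the items in each
#' true category). Used to exercise the agreement statistics on data with a
#' known generating process.
#'
#' @param n_items,n_readers Panel dimensions.
#' @param accuracy Per-reader probability of the correct label.
#' @param categories Category labels (first is used for the first half of
#'   items).
#' @param seed RNG seed.
#' @returns A long tibble (`item_id`, `reader_id`, `category`, `truth`).
#' @export
simulate_ratings <- function(n_items = 200L, n_readers = 3L,
                             accuracy = 0.6,
                             categories = c("acquired", "synthetic"),
                             seed = 1L) {
  stopifnot(length(categories) == 2L, accuracy >= 0, accuracy <= 1)
  with_preserved_rng({
    set.seed(seed)
    truth <- rep(categories, length.out = n_items)
    out <- tidyr::expand_grid(item_id = sprintf("I%04d", seq_len(n_items)),
                              reader_id = sprintf("R%d", seq_len(n_readers)))
    tr <- rep(truth, each = n_readers)
    correct <- stats::runif(nrow(out)) < accuracy
    other <- ifelse(tr == categories[1], categories[2], categories[1])
    out$category <- ifelse(correct, tr, other)
    out$truth <- tr
    out
  })
}
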