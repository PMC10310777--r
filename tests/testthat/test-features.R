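make_slice <- function(body_val = 0, air_val = -1000, n = 32L) {
  sl <- matrix(air_val, n, n)
  sl[7:26, 9:24] <- body_val
  sl
}

test_that("backbone output length equals its channel count and is deterministic", {
  bb <- tiny_backbone(n_channels = 8L, seed = 3)
  sl <- make_slice()
  f1 <- predict(bb, vgg_byte_normalize(sl))
  f2 <- predict(bb, vgg_byte_normalize(sl))
  expect_length(f1, 8L)
  expect_identical(f1, f2)
  bb5 <- tiny_backbone(n_channels = 5L, seed = 3)
  expect_length(predict(bb5, vgg_byte_normalize(sl)), 5L)
})

test_that("feature tables have one row per image and one column per channel", {
  bb <- tiny_backbone(n_channels = 6L, seed = 2)
  slices <- list(a = make_slice(0), b = make_slice(50), c = make_slice(-100))
  ft <- extract_pooled_features(slices, bb)
  expect_identical(dim(ft), c(3L, 7L))   # image_id + 6 features
  expect_identical(ft$image_id, c("a", "b", "c"))
  expect_error(extract_pooled_features(list(make_slice(), matrix(0, 8, 8)),
                                       bb), "same shape")
})

test_that("body masking makes features blind to background air", {
  bb <- tiny_backbone(n_channels = 8L, seed = 5)
  s1 <- make_slice(body_val = 30, air_val = -1000)
  s2 <- make_slice(body_val = 30, air_val = -850)   # air altered, body same
  ft <- extract_pooled_features(list(x = s1, y = s2), bb)
  expect_equal(unlist(ft[1, -1]), unlist(ft[2, -1]), tolerance = 1e-12)
  # without masking the same two images differ
  ft_raw <- extract_pooled_features(list(x = s1, y = s2), bb, mask_fn = NULL)
  expect_false(isTRUE(all.equal(unlist(ft_raw[1, -1]),
                                unlist(ft_raw[2, -1]))))
})

test_that("the head fits linearly separable features to high training AUC", {
  t <- random_feature_table(n = 40L, p = 2L, seed = 6, informative = 2L)
  cs <- train_head(t[, c("f01", "f02")], t$label,
                   classifier_head_spec(hidden = c(16L, 8L, 4L)),
                   epochs = 200L, learning_rate = 3e-3, batch_size = 8L,
                   validation_n = 8L, repeats = 2L, seed = 7,
                   record_every = 50L)
  fin <- dplyr::filter(cs$final, split == "training", metric == "auc")
  expect_gte(fin$mean, 0.99)
})

test_that("labels independent of features give chance-level validation AUC", {
  t <- random_feature_table(n = 48L, p = 4L, seed = 8, informative = 0L)
  cs <- train_head(t[, 1:4], t$label,
                   classifier_head_spec(hidden = c(16L, 8L, 4L)),
                   epochs = 80L, learning_rate = 3e-3, batch_size = 8L,
                   validation_n = 10L, repeats = 5L, seed = 9,
                   record_every = 40L)
  va <- final_validation_auc(cs)
  expect_lt(abs(va$mean - 0.5), max(3 * va$sem, 0.05) + 1e-9)
})

test_that("training the head is reproducible for a fixed seed", {
  t <- random_feature_table(n = 24L, p = 3L, seed = 10, informative = 1L)
  run <- function() train_head(t[, 1:3], t$label,
                               classifier_head_spec(hidden = c(8L, 4L, 2L)),
                               epochs = 20L, batch_size = 8L,
                               validation_n = 6L, repeats = 1L, seed = 11,
                               record_every = 10L)
  expect_equal(run()$curves, run()$curves, tolerance = 1e-12)
})

test_that("head training validates its inputs", {
  t <- random_feature_table(n = 20L, p = 3L)
  expect_error(train_head(t[, 1:3], rep(1, 20)), "both classes")
  expect_error(classifier_head_spec(hidden = c(8L, 8L)), "decreasing")
  expect_error(train_head(t[, 1:3], t$label, validation_n = 100L),
               "smaller than the training pool")
})

test_that("shuffled-label control preserves counts and is seed-stable", {
  labels <- rep(c(0, 1), c(30, 20))
  p1 <- shuffled_label_control(labels, seed = 3)
  p2 <- shuffled_label_control(labels, seed = 3)
  expect_identical(p1, p2)
  expect_identical(as.integer(table(p1)), as.integer(table(labels)))
})

test_that("label permutations are uniform over distinct orderings", {
  # 4-label multiset {a,a,b,b}: 6 distinct orderings, each probability 1/6
  labels <- c("a", "a", "b", "b")
  set.seed(31)
  draws <- replicate(6000, paste(shuffled_label_control(labels),
                                 collapse = ""))
  tab <- table(draws)
  expect_identical(length(tab), 6L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("repeat-averaged SEM shrinks with more repeats", {
  t <- random_feature_table(n = 24L, p = 3L, seed = 12, informative = 1L)
  sem_at <- function(r) {
    cs <- train_head(t[, 1:3], t$label,
                     classifier_head_spec(hidden = c(8L, 4L, 2L)),
                     epochs = 15L, learning_rate = 3e-3, batch_size = 8L,
                     validation_n = 6L, repeats = r, seed = 13,
                     record_every = 15L)
    mean(dplyr::filter(cs$final, metric == "loss")$sem)
  }
  expect_lt(sem_at(8L), sem_at(2L))
})
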