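test_that("degenerate configuration yields identical paired volumes", {
  cfg <- phantom_config(grid_shape = c(32L, 32L, 32L),
                        contrast_delta_hu = 0, noise_sd_hu = 0)
  p <- generate_phantom_pair(cfg, seed = 3)
  expect_identical(p$contrast$values, p$noncontrast$values)
})

test_that("noiseless phantoms are piecewise constant with at most 4 levels", {
  p <- tiny_pair(seed = 7, noise = 0)
  expect_lte(length(unique(as.numeric(p$contrast$values))), 4L)
  expect_lte(length(unique(as.numeric(p$noncontrast$values))), 4L)
})

test_that("generation is bit-reproducible for a fixed config and seed", {
  cfg <- phantom_config(grid_shape = c(32L, 32L, 32L))
  a <- generate_phantom_pair(cfg, seed = 7)
  b <- generate_phantom_pair(cfg, seed = 7)
  expect_identical(a$contrast$values, b$contrast$values)
  expect_identical(a$noncontrast$values, b$noncontrast$values)
  expect_identical(a$vessel_mask, b$vessel_mask)
})

test_that("masks are mutually consistent and pairing holds off-vessel", {
  p <- tiny_pair(seed = 11, noise = 0)
  expect_true(all(p$body_mask[p$vessel_mask]))   # vessel inside body
  expect_true(all(p$body_mask[p$lung_mask]))     # lung inside body
  off <- !p$vessel_mask
  expect_identical(p$contrast$values[off], p$noncontrast$values[off])
  dv <- p$contrast$values[p$vessel_mask] - p$noncontrast$values[p$vessel_mask]
  expect_true(all(dv == 300))
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(grid_shape = c(8L, 8L, 8L)), "too small")
  expect_error(phantom_config(noise_sd_hu = -1), "non-negative")
  expect_error(phantom_config(contrast_delta_hu = -5), "non-negative")
  expect_error(phantom_config(body_hu = 2000), "within")
})

test_that("cohorts have requested sizes and distinct subjects", {
  cfg <- phantom_config(grid_shape = c(32L, 32L, 32L))
  co <- generate_cohorts(cfg, 3L, 2L, seed = 5)
  expect_length(co$contrast, 3L)
  expect_length(co$noncontrast, 2L)
  expect_length(unique(co$manifest$subject_id), 5L)
  expect_length(co$registry, 5L)
  # released volumes match the hidden registry counterparts
  expect_identical(co$contrast[["S001"]]$values,
                   co$registry[["S001"]]$contrast$values)
})

test_that("zero geometry jitter makes all body masks identical", {
  cfg <- phantom_config(grid_shape = c(32L, 32L, 32L), geometry_jitter = 0)
  co <- generate_cohorts(cfg, 2L, 2L, seed = 9)
  masks <- lapply(co$registry, `[[`, "body_mask")
  for (m in masks[-1]) expect_identical(m, masks[[1]])
})

test_that("cohort vessel-region HU difference matches the contrast delta", {
  # Monte-Carlo: >= 10 subjects; the between-cohort difference in mean
  # vessel HU estimates contrast_delta_hu with SE from the noise only
  # (anatomy is piecewise constant)
  cfg <- phantom_config(grid_shape = c(32L, 32L, 32L), noise_sd_hu = 20)
  co <- generate_cohorts(cfg, 6L, 6L, seed = 13)
  man <- co$manifest
  vals <- function(dom) {
    ids <- man$subject_id[man$domain == dom]
    unlist(lapply(ids, function(id) {
      pair <- co$registry[[id]]
      vol <- if (dom == "contrast") pair$contrast else pair$noncontrast
      vol$values[pair$vessel_mask]
    }))
  }
  vc <- vals("contrast"); vn <- vals("noncontrast")
  diff <- mean(vc) - mean(vn)
  se <- 20 * sqrt(1 / length(vc) + 1 / length(vn))
  expect_lt(abs(diff - 300), 3 * se)
})

test_that("vessel-region mean separates domains when delta >> noise", {
  cfg <- phantom_config(grid_shape = c(32L, 32L, 32L), noise_sd_hu = 20,
                        contrast_delta_hu = 300)  # delta > 6 * noise
  co <- generate_cohorts(cfg, 4L, 4L, seed = 21)
  mv <- vapply(co$registry, function(pair) {
    released <- if (pair$subject_id %in%
                      co$manifest$subject_id[co$manifest$domain == "contrast"])
      pair$contrast else pair$noncontrast
    mean(released$values[pair$vessel_mask])
  }, 0)
  is_c <- co$manifest$domain == "contrast"
  expect_gt(min(mv[is_c]), max(mv[!is_c]))  # a threshold separates perfectly
})

test_that("cohorts round-trip through NIfTI with manifest", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(grid_shape = c(24L, 24L, 24L), n_vessels = 2L)
  co <- generate_cohorts(cfg, 1L, 1L, seed = 2)
  man <- write_cohorts(co, dir, with_masks = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  v <- read_volume(man$path[1])
  expect_equal(v$values, co$contrast[[1]]$values)
  expect_equal(v$spacing, co$contrast[[1]]$spacing, tolerance = 1e-6)
})
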