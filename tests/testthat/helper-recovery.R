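# Contrast-removal recovery runs are the expensive fixture: tiny-preset
# cycle-GAN, 32^3 patches, 500 iterations on 4+4 phantom volumes
# (contrast_delta 300 HU, noise 10 HU). Trained once per seed and shared
# across test files.

recovery_run <- function(seed) {
  cached(sprintf("recovery_%d", seed), {
    cfg <- phantom_config(noise_sd_hu = 10)
    cohorts <- generate_cohorts(cfg, 4L, 4L, seed = seed)
    fit <- train_cyclegan(
      lapply(cohorts$contrast, clip_scale_hu),
      lapply(cohorts$noncontrast, clip_scale_hu),
      gen_spec = tiny_generator_spec(),
      disc_spec = tiny_discriminator_spec(),
      cfg = train_config(patch_size = 32L, n_iterations = 500L,
                         seed = seed))
    list(cfg = cfg, cohorts = cohorts, fit = fit)
  })
}

# vessel-region recovery and whole-volume identity change for one run
recovery_metrics <- function(seed) {
  cached(sprintf("recovery_metrics_%d", seed), {
    run <- recovery_run(seed)
    man <- run$cohorts$manifest
    ids_c <- man$subject_id[man$domain == "contrast"]
    ids_n <- man$subject_id[man$domain == "noncontrast"]
    translate <- function(vol) sliding_window_translate(
      clip_scale_hu(vol), run$fit$g_ab, patch_size = 32L, stride = 16L)
    err <- vapply(ids_c, function(id) {
      pair <- run$cohorts$registry[[id]]
      truth <- clip_scale_hu(pair$noncontrast)$values
      x <- clip_scale_hu(pair$contrast)$values
      tr <- translate(pair$contrast)$values
      vm <- pair$vessel_mask
      c(before = mean(abs(x[vm] - truth[vm])),
        after = mean(abs(tr[vm] - truth[vm])),
        change_contrast = mean(abs(tr - x)))
    }, c(before = 0, after = 0, change_contrast = 0))
    idn <- vapply(ids_n, function(id) {
      pair <- run$cohorts$registry[[id]]
      x <- clip_scale_hu(pair$noncontrast)$values
      tr <- translate(pair$noncontrast)$values
      mean(abs(tr - x))
    }, 0)
    list(vessel_before = mean(err["before", ]),
         vessel_after = mean(err["after", ]),
         reduction = 1 - mean(err["after", ]) / mean(err["before", ]),
         change_on_contrast = mean(err["change_contrast", ]),
         change_on_noncontrast = mean(idn))
  })
}
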