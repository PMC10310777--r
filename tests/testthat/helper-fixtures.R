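# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, code) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(code), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small noiseless phantom pair on a 32^3 grid
tiny_pair <- function(seed = 7L, noise = 0, delta = 300) {
  cached(sprintf("pair_%d_%g_%g", seed, noise, delta), {
    cfg <- phantom_config(grid_shape = c(32L, 32L, 32L),
                          noise_sd_hu = noise, contrast_delta_hu = delta)
    generate_phantom_pair(cfg, seed = seed)
  })
}
# deterministic random generator/discriminator with tiny preset
fixed_tiny_generator <- function(seed = 42L) {
  cached(sprintf("gen_%d", seed), {
    set.seed(seed)
    build_generator(tiny_generator_spec())
  })
}

# random feature table: n rows, p features, optional informative signal
random_feature_table <- function(n = 20L, p = 5L, seed = 1L,
                                 informative = 0L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  label <- rep(0:1, length.out = n)
  for (j in seq_len(informative)) X[, j] <- X[, j] + 2 * label
  t <- tibble::as_tibble(as.data.frame(X))
  names(t) <- sprintf("f%02d", seq_len(p))
  t$subject_id <- sprintf("s%03d", seq_len(n))
  t$label <- label
  t
}
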