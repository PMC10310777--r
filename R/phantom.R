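#' Phantom generator configuration
#'
#' Configures the procedural chest-phantom generator: an ellipsoidal body at
#' soft-tissue attenuation surrounded by air, two lung ellipsoids, and a set
#' of tubular "vessels" threading the lungs and mediastinum. The contrast
#' domain adds `contrast_delta_hu` inside the vessel mask; both domains then
#' receive independent Gaussian acquisition noise and are clipped to
#' [-1000, 1000] HU. Defaults emulate a chest CT at typical attenuations:
#' 64^3 voxels at 1 x 1 x 2 mm, body 40 HU, lung -800 HU, vessels 60 HU,
#' contrast enhancement +300 HU, noise SD 20 HU.
#'
#' @param grid_shape Voxels per axis `(x, y, z)`.
#' @param spacing mm per voxel `(x, y, z)`.
#' @param body_hu,lung_hu,vessel_hu Mean HU of each tissue class; all must
#'   lie in `[-1000, 1000]`.
#' @param contrast_delta_hu HU added to vessel voxels in the contrast
#'   domain (non-negative).
#' @param noise_sd_hu Additive Gaussian noise scale (non-negative).
#' @param n_vessels Number of tubular structures.
#' @param vessel_radius Range (voxels) from which each tube radius is drawn.
#' @param geometry_jitter Per-subject relative scale/offset range (e.g. 0.06
#'   means axes scaled by U(0.94, 1.06) and centers shifted by up to 6% of
#'   the grid).
#' @param seed Default RNG seed used when none is supplied per call.
#' @returns An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 64L),
                           spacing = c(1, 1, 2),
                           body_hu = 40, lung_hu = -800, vessel_hu = 60,
                           contrast_delta_hu = 300, noise_sd_hu = 20,
                           n_vessels = 3L, vessel_radius = c(2L, 4L),
                           geometry_jitter = 0.06, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  hu <- c(body_hu, lung_hu, vessel_hu)
  if (any(hu < -1000 | hu > 1000))
    stop("tissue HU means must lie within [-1000, 1000]")
  if (contrast_delta_hu < 0) stop("contrast_delta_hu must be non-negative")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be non-negative")
  if (any(grid_shape < 16L))
    stop("invalid configuration: grid too small for requested geometry ",
         "(need at least 16 voxels per axis)")
  if (geometry_jitter < 0 || geometry_jitter >= 0.5)
    stop("geometry_jitter must be in [0, 0.5)")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 body_hu = body_hu, lung_hu = lung_hu, vessel_hu = vessel_hu,
                 contrast_delta_hu = contrast_delta_hu,
                 noise_sd_hu = noise_sd_hu,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius = as.integer(vessel_radius),
                 geometry_jitter = geometry_jitter,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

ellipsoid_mask <- function(n, center, semi) {
  qx <- ((seq_len(n[1]) - center[1]) / semi[1])^2
  qy <- ((seq_len(n[2]) - center[2]) / semi[2])^2
  qz <- ((seq_len(n[3]) - center[3]) / semi[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

# Rasterize a polyline tube of given radius: dense samples along the
# segments, each stamping a ball of voxels.
tube_mask <- function(n, waypoints, radius) {
  mask <- array(FALSE, n)
  off <- as.matrix(expand.grid(x = -radius:radius, y = -radius:radius,
                               z = -radius:radius))
  off <- off[rowSums(off^2) <= radius^2, , drop = FALSE]
  for (s in seq_len(nrow(waypoints) - 1L)) {
    p0 <- waypoints[s, ]; p1 <- waypoints[s + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.5)))
    for (t in ts) {
      c0 <- round(p0 + t * (p1 - p0))
      vox <- sweep(off, 2L, c0, `+`)
      keep <- vox[, 1] >= 1 & vox[, 1] <= n[1] &
        vox[, 2] >= 1 & vox[, 2] <= n[2] &
        vox[, 3] >= 1 & vox[, 3] <= n[3]
      if (any(keep)) mask[vox[keep, , drop = FALSE]] <- TRUE
    }
  }
  mask
}

with_preserved_rng <- function(code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Generate one paired contrast / non-contrast phantom
#'
#' Builds a single subject's phantom: the piecewise-constant anatomy is
#' shared, the contrast volume adds `contrast_delta_hu` on vessel voxels,
#' and each domain receives independent Gaussian noise before clipping to
#' [-1000, 1000] HU. With zero noise the two volumes are voxelwise identical
#' outside the vessel mask — the hidden pairing that makes translation error
#' measurable.
#'
#' @param cfg A [phantom_config()].
#' @param seed Integer seed; output is bit-reproducible for fixed
#'   `(cfg, seed)`.
#' @param subject_id Identifier stored with the pair.
#' @returns An object of class `phantom_pair` with elements `contrast`,
#'   `noncontrast` (both [ct_volume()] in HU), `body_mask`, `lung_mask`,
#'   `vessel_mask` (logical arrays) and `subject_id`.
#' @examples
#' cfg <- phantom_config(grid_shape = c(32, 32, 32), noise_sd_hu = 0)
#' p <- generate_phantom_pair(cfg, seed = 7)
#' all(p$contrast$values[!p$vessel_mask] ==
#'     p$noncontrast$values[!p$vessel_mask])
#' @export
generate_phantom_pair <- function(cfg, seed = cfg$seed,
                                  subject_id = sprintf("S%04d", seed %% 10000L)) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_preserved_rng({
    set.seed(seed)
    n <- cfg$grid_shape
    j <- cfg$geometry_jitter
    jit <- function(k) if (j > 0) stats::runif(k, 1 - j, 1 + j) else rep(1, k)
    sh <- function(k) if (j > 0) stats::runif(k, -j, j) else rep(0, k)

    center <- n / 2 + sh(3) * n / 2
    body_semi <- c(0.42, 0.40, 0.46) * n * jit(3)
    body <- ellipsoid_mask(n, center, body_semi)

    lung_semi <- c(0.15, 0.26, 0.34) * n * jit(3)
    lung_off <- 0.21 * n[1] * jit(1)
    lungs <- ellipsoid_mask(n, center + c(lung_off, 0, 0), lung_semi) |
      ellipsoid_mask(n, center - c(lung_off, 0, 0), lung_semi)
    lungs <- lungs & body

    vessel <- array(FALSE, n)
    lo <- 0.25 * n; hi <- 0.75 * n
    for (v in seq_len(cfg$n_vessels)) {
      k <- 3L
      wp <- cbind(stats::runif(k, lo[1], hi[1]),
                  stats::runif(k, lo[2], hi[2]),
                  stats::runif(k, 0.15 * n[3], 0.85 * n[3]))
      r <- if (cfg$vessel_radius[1] == cfg$vessel_radius[2])
        cfg$vessel_radius[1]
      else sample(cfg$vessel_radius[1]:cfg$vessel_radius[2], 1L)
      vessel <- vessel | tube_mask(n, wp, r)
    }
    vessel <- vessel & body
    if (!any(vessel))
      stop("invalid configuration: grid too small for requested geometry ",
           "(no vessel voxels landed inside the body)")

    base <- array(-1000, n)
    base[body] <- cfg$body_hu
    base[lungs] <- cfg$lung_hu
    base[vessel] <- cfg$vessel_hu

    contrast <- base
    contrast[vessel] <- contrast[vessel] + cfg$contrast_delta_hu
    noncontrast <- base
    if (cfg$noise_sd_hu > 0) {
      noncontrast <- noncontrast +
        array(stats::rnorm(prod(n), sd = cfg$noise_sd_hu), n)
      contrast <- contrast +
        array(stats::rnorm(prod(n), sd = cfg$noise_sd_hu), n)
    }
    clip <- function(x) pmin(pmax(x, -1000), 1000)
    structure(list(
      contrast = ct_volume(clip(contrast), cfg$spacing, "HU"),
      noncontrast = ct_volume(clip(noncontrast), cfg$spacing, "HU"),
      body_mask = body, lung_mask = lungs, vessel_mask = vessel,
      subject_id = subject_id), class = "phantom_pair")
  })
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("<phantom_pair> subject ", x$subject_id, ", ",
      paste(dim(x$contrast$values), collapse = "x"),
      " voxels, vessel voxels: ", sum(x$vessel_mask), "\n", sep = "")
  invisible(x)
}

#' Generate unpaired phantom cohorts with a hidden pair registry
#'
#' Draws `n_contrast + n_noncontrast` subjects, each with independent
#' geometry jitter, and releases only one domain per subject — the unpaired
#' training regime. The full pairs (hidden counterparts plus masks) are kept
#' in a registry for evaluation only.
#'
#' @param cfg A [phantom_config()].
#' @param n_contrast,n_noncontrast Cohort sizes (at least 1 each).
#' @param seed Cohort-level seed; per-subject seeds are derived from it.
#' @returns A list with `contrast` and `noncontrast` (named lists of
#'   [ct_volume()]), `registry` (named list of `phantom_pair`), and
#'   `manifest` (tibble: subject_id, domain).
#' @export
generate_cohorts <- function(cfg, n_contrast, n_noncontrast,
                             seed = cfg$seed) {
  stopifnot(n_contrast >= 1, n_noncontrast >= 1)
  n_total <- n_contrast + n_noncontrast
  subject_seeds <- with_preserved_rng({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n_total)
  })
  ids <- sprintf("S%03d", seq_len(n_total))
  registry <- stats::setNames(vector("list", n_total), ids)
  for (i in seq_len(n_total))
    registry[[i]] <- generate_phantom_pair(cfg, subject_seeds[i], ids[i])
  idx_c <- seq_len(n_contrast)
  idx_n <- n_contrast + seq_len(n_noncontrast)
  list(
    contrast = lapply(registry[idx_c], `[[`, "contrast"),
    noncontrast = lapply(registry[idx_n], `[[`, "noncontrast"),
    registry = registry,
    manifest = tibble::tibble(
      subject_id = ids,
      domain = rep(c("contrast", "noncontrast"),
                   c(n_contrast, n_noncontrast))))
}

#' Write phantom cohorts to disk
#'
#' One NIfTI per subject per released domain plus a tab-delimited manifest
#' (`subject_id`, `domain`, `path`). Masks are written as 0/1 NIfTI when
#' `with_masks = TRUE`.
#'
#' @param cohorts Result of [generate_cohorts()].
#' @param dir Output directory (created if missing).
#' @param with_masks Also write body/lung/vessel masks from the registry.
#' @returns The manifest tibble, invisibly; also written to
#'   `file.path(dir, "manifest.tsv")`.
#' @export
write_cohorts <- function(cohorts, dir, with_masks = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohorts$manifest
  paths <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    id <- man$subject_id[i]; dom <- man$domain[i]
    vol <- if (dom == "contrast") cohorts$contrast[[id]]
           else cohorts$noncontrast[[id]]
    paths[i] <- file.path(dir, paste0(id, "_", dom, ".nii.gz"))
    write_volume(vol, paths[i])
    if (with_masks) {
      pair <- cohorts$registry[[id]]
      for (m in c("body_mask", "lung_mask", "vessel_mask"))
        write_mask(pair[[m]], file.path(dir, paste0(id, "_", m, ".nii.gz")),
                   spacing = vol$spacing)
    }
  }
  man$path <- paths
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}
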