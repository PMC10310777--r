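#' Resample a CT volume to a target voxel spacing
#'
#' Trilinear (per-axis linear) interpolation at voxel centers. The output
#' grid shape is `round(extent / target_spacing)` where
#' `extent = shape * spacing`; sampling coordinates are clamped at the
#' boundary.
#'
#' @param vol A [ct_volume()] (at least 2 voxels per axis).
#' @param target_spacing Strictly positive `(x, y, z)` spacing in mm.
#' @returns A resampled [ct_volume()] with the requested spacing.
#' @examples
#' v <- ct_volume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1, 1, 1))
#' r <- resample_volume(v, c(1, 1, 2))
#' dim(r)
#' @export
resample_volume <- function(vol, target_spacing) {
  vol <- as_ct_volume(vol)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target spacing must be three strictly positive numbers (mm)")
  d <- dim(vol$values)
  if (any(d < 2L)) stop("volume must have at least 2 voxels per axis")
  extent <- d * vol$spacing
  nd <- pmax(1L, as.integer(round(extent / target_spacing)))

  # voxel-center coordinates of the output grid expressed as (0-based)
  # fractional input indices
  coord <- function(ax) {
    x_mm <- (seq_len(nd[ax]) - 0.5) * target_spacing[ax]
    idx <- x_mm / vol$spacing[ax] - 0.5
    pmin(pmax(idx, 0), d[ax] - 1)
  }
  cx <- coord(1); cy <- coord(2); cz <- coord(3)
  i0 <- pmin(floor(cx), d[1] - 2); fx <- cx - i0
  j0 <- pmin(floor(cy), d[2] - 2); fy <- cy - j0
  k0 <- pmin(floor(cz), d[3] - 2); fz <- cz - k0

  ii <- rep(i0, times = nd[2] * nd[3])
  jj <- rep(rep(j0, each = nd[1]), times = nd[3])
  kk <- rep(k0, each = nd[1] * nd[2])
  wx <- rep(fx, times = nd[2] * nd[3])
  wy <- rep(rep(fy, each = nd[1]), times = nd[3])
  wz <- rep(fz, each = nd[1] * nd[2])

  v <- vol$values
  lin <- function(di, dj, dk)
    v[1L + (ii + di) + d[1] * ((jj + dj) + d[2] * (kk + dk))]
  out <-
    lin(0, 0, 0) * (1 - wx) * (1 - wy) * (1 - wz) +
    lin(1, 0, 0) * wx * (1 - wy) * (1 - wz) +
    lin(0, 1, 0) * (1 - wx) * wy * (1 - wz) +
    lin(1, 1, 0) * wx * wy * (1 - wz) +
    lin(0, 0, 1) * (1 - wx) * (1 - wy) * wz +
    lin(1, 0, 1) * wx * (1 - wy) * wz +
    lin(0, 1, 1) * (1 - wx) * wy * wz +
    lin(1, 1, 1) * wx * wy * wz
  ct_volume(array(out, nd), spacing = target_spacing, units = vol$units)
}

#' Clip Hounsfield units and scale to normalized range
#'
#' Clamps intensities to [-1000, 1000] HU and divides by 1000, mapping the
#' CT dynamic range onto (-1, 1) for GAN training. [inverse_scale()] undoes
#' the scaling (multiply by 1000); the round trip is the identity for
#' in-range values.
#'
#' @param vol A [ct_volume()] in HU.
#' @returns A [ct_volume()] with `units = "normalized"`.
#' @export
clip_scale_hu <- function(vol) {
  vol <- as_ct_volume(vol)
  if (vol$units != "HU") stop("clip_scale_hu expects a volume in HU")
  ct_volume(pmin(pmax(vol$values, -1000), 1000) / 1000,
            spacing = vol$spacing, units = "normalized")
}

#' @rdname clip_scale_hu
#' @export
inverse_scale <- function(vol) {
  vol <- as_ct_volume(vol, units = "normalized")
  if (vol$units != "normalized")
    stop("inverse_scale expects a normalized volume")
  ct_volume(vol$values * 1000, spacing = vol$spacing, units = "HU")
}

#' Body-contour mask
#'
#' Thresholds at HU > -500, applies a morphological opening with a 5x5
#' square kernel per axial slice, then fills interior holes per slice.
#' This isolates the patient body from air and detached specks before
#' feature extraction.
#'
#' @param x A [ct_volume()] in HU, a 3D array, or a single 2D slice.
#' @param threshold_hu Threshold (default -500 HU).
#' @returns Logical mask of the same shape.
#' @export
body_mask <- function(x, threshold_hu = -500) {
  is_slice <- is.matrix(x)
  if (!is_slice) {
    vol <- as_ct_volume(x)
    if (vol$units != "HU") stop("body_mask expects intensities in HU")
    v <- vol$values
  } else v <- x
  kern <- EBImage::makeBrush(5L, shape = "box")
  clean <- function(sl) {
    m <- EBImage::opening(sl > threshold_hu, kern)
    m <- EBImage::fillHull(m)
    m > 0
  }
  if (is_slice) return(clean(v))
  out <- array(FALSE, dim(v))
  for (k in seq_len(dim(v)[3])) out[, , k] <- clean(v[, , k])
  out
}

#' Byte normalization for convolutional feature backbones
#'
#' Maps CT numbers to 8-bit intensities, `y = floor(255 * (x + 1000) / 2000)`
#' clipped to `[0, 255]`, and replicates the result across three channels —
#' the input format expected by RGB-pretrained convolutional backbones.
#'
#' @param x A [ct_volume()] in HU, a 3D array, or a 2D slice.
#' @returns An integer array with a trailing channel dimension of 3:
#'   `(nx, ny, 3)` for a slice, `(nx, ny, nz, 3)` for a volume.
#' @examples
#' vgg_byte_normalize(matrix(c(-1000, 0, 1500), 1))[1, , 1]
#' @export
vgg_byte_normalize <- function(x) {
  if (inherits(x, "ct_volume")) {
    if (x$units != "HU") stop("vgg_byte_normalize expects intensities in HU")
    x <- x$values
  }
  y <- floor(255 * (x + 1000) / 2000)
  y <- pmin(pmax(y, 0), 255)
  d <- if (is.matrix(x)) dim(x) else dim(x)
  out <- array(as.integer(y), c(d, 3L))
  out
}
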