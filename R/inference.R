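#' Center-weighted blending kernel for sliding-window inference
#'
#' Separable tent kernel `w(i, j, k) = t(i) t(j) t(k)` where `t` rises
#' linearly from `eps` at the patch border to 1 at the center (for even
#' sizes the two central planes tie at 1). Voxels predicted near a patch
#' center therefore dominate the blend over voxels near patch borders; the
#' floor `eps` keeps every covered voxel at strictly positive weight.
#'
#' @param size Patch side (at least 2).
#' @param eps Border weight floor in (0, 1].
#' @returns A `size`^3 array of strictly positive weights, maximal at the
#'   center and symmetric under reflection of any axis.
#' @export
make_weight_kernel <- function(size, eps = 0.05) {
  size <- as.integer(size)
  if (size < 2L) stop("kernel size must be at least 2")
  if (eps <= 0 || eps > 1) stop("eps must be in (0, 1]")
  r <- pmin(seq_len(size), size + 1L - seq_len(size))
  rmax <- max(r)
  t <- if (rmax == 1L) rep(1, size) else eps + (1 - eps) * (r - 1) / (rmax - 1)
  outer(outer(t, t), t)
}

#' Translate a whole volume with sliding-window patch inference
#'
#' Covers the volume with `patch_size`^3 windows on a stride grid (the last
#' window per axis is clamped to the boundary so coverage is complete),
#' translates each window with the generator, and blends overlapping
#' predictions by center-weighted averaging:
#' `output = sum(w * g(patch)) / sum(w)` over all covering windows.
#' Accumulation uses double-precision buffers.
#'
#' @param vol A normalized [ct_volume()] or 3D array, every axis at least
#'   `patch_size`.
#' @param g A `ct_generator` or any function mapping a patch to a same-shape
#'   patch.
#' @param patch_size Window side (reference inference uses 64).
#' @param stride Window stride in voxels, `1 <= stride <= patch_size`
#'   (reference value 16).
#' @param eps Border weight floor for [make_weight_kernel()].
#' @param float32 Precision of generator convolutions.
#' @returns Translated volume, same shape and type as the input.
#' @export
sliding_window_translate <- function(vol, g, patch_size = 64L, stride = 16L,
                                     eps = 0.05, float32 = TRUE) {
  is_vol <- inherits(vol, "ct_volume")
  v <- vol_values(vol)
  d <- dim(v)
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  if (any(d < patch_size))
    stop("volume (", paste(d, collapse = "x"), ") smaller than patch size ",
         patch_size, "; pad the volume before inference")
  if (stride < 1L || stride > patch_size)
    stop("stride must satisfy 1 <= stride <= patch_size")
  apply_g <- if (is.function(g)) g else {
    function(p) predict(g, p, float32 = float32)
  }
  w <- make_weight_kernel(patch_size, eps)
  starts <- function(n) {
    s <- seq.int(1L, n - patch_size + 1L, by = stride)
    if (s[length(s)] != n - patch_size + 1L) s <- c(s, n - patch_size + 1L)
    s
  }
  num <- array(0, d)
  den <- array(0, d)
  idx <- seq_len(patch_size) - 1L
  for (k in starts(d[3])) for (j in starts(d[2])) for (i in starts(d[1])) {
    p <- v[i + idx, j + idx, k + idx]
    pred <- apply_g(p)
    if (!identical(dim(pred), dim(p)))
      stop("generator returned a patch of different shape")
    num[i + idx, j + idx, k + idx] <- num[i + idx, j + idx, k + idx] + w * pred
    den[i + idx, j + idx, k + idx] <- den[i + idx, j + idx, k + idx] + w
  }
  out <- num / den
  if (is_vol) ct_volume(pmin(pmax(out, -1), 1), vol$spacing, "normalized")
  else out
}

#' Clipped intensity difference map
#'
#' `(a - b)` clipped to `[-clip, clip]` (default 0.4 in normalized units),
#' the rendering used to visualize contrast removal.
#'
#' @param a,b Normalized [ct_volume()]s or arrays of identical shape.
#' @param clip Clip half-range.
#' @returns An object of class `difference_map`: the clipped difference
#'   grid plus rendering metadata (`range`, `spacing`).
#' @export
difference_map <- function(a, b, clip = 0.4) {
  av <- vol_values(a); bv <- vol_values(b)
  if (!identical(dim(av), dim(bv)))
    stop("difference_map: shape mismatch (", paste(dim(av), collapse = "x"),
         " vs ", paste(dim(bv), collapse = "x"), ")")
  spacing <- if (inherits(a, "ct_volume")) a$spacing else c(1, 1, 1)
  structure(list(values = pmin(pmax(av - bv, -clip), clip),
                 range = c(-clip, clip), spacing = spacing),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat("<difference_map> ", paste(dim(x$values), collapse = "x"),
      ", clipped to [", x$range[1], ", ", x$range[2], "]\n", sep = "")
  invisible(x)
}
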