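#' CT volume container
#'
#' A 3D scalar intensity grid plus voxel spacing and a units tag. Grids are
#' plain R arrays indexed `(x, y, z)`, 1-based; spacing is `(x, y, z)` in mm,
#' following the NIfTI convention. Intensities are either Hounsfield units
#' (`"HU"`) or `"normalized"` units in `[-1, 1]`.
#'
#' @param values 3D numeric array.
#' @param spacing Positive numeric length-3 vector, mm per voxel `(x, y, z)`.
#' @param units `"HU"` or `"normalized"`.
#' @returns An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(-1000, c(8, 8, 8)), spacing = c(1, 1, 2))
#' v
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1),
                      units = c("HU", "normalized")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (mm)")
  if (units == "normalized" && any(abs(values) > 1 + 1e-9, na.rm = TRUE))
    stop("normalized volumes must have all values in [-1, 1]")
  structure(list(values = values, spacing = spacing, units = units),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$values), collapse = "x"),
      " voxels, spacing ", paste(x$spacing, collapse = "x"), " mm, ",
      x$units, ", range [", round(min(x$values), 2), ", ",
      round(max(x$values), 2), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

as_ct_volume <- function(x, units = "HU", spacing = c(1, 1, 1)) {
  if (inherits(x, "ct_volume")) return(x)
  if (is.array(x) && length(dim(x)) == 3L)
    return(ct_volume(x, spacing = spacing, units = units))
  stop("expected a ct_volume or a 3D array")
}

vol_values <- function(x) if (inherits(x, "ct_volume")) x$values else x

#' Read / write CT volumes as NIfTI
#'
#' `read_volume()` ingests a NIfTI file, taking voxel spacing from the
#' header; intensities are assumed to be Hounsfield units unless
#' `units` says otherwise. `write_volume()` round-trips values bit-exactly
#' for double encodings and spacing to within 1e-6 mm.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param units Units tag to attach on read.
#' @returns `read_volume()` a [ct_volume()]; `write_volume()` the path,
#'   invisibly.
#' @export
read_volume <- function(path, units = c("HU", "normalized")) {
  units <- match.arg(units)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("failed to parse '", path,
                                           "' as NIfTI: ", conditionMessage(e),
                                           call. = FALSE))
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(vals)), " dimensions")
  spacing <- RNifti::pixdim(img)[1:3]
  attributes(vals) <- list(dim = dim(vals))   # strip niftiImage attributes
  ct_volume(vals, spacing = spacing, units = units)
}

#' @param vol A [ct_volume()] (or 3D array, written with unit spacing).
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  vol <- as_ct_volume(vol)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a binary mask as 0/1 NIfTI
#'
#' @param mask Logical or 0/1 3D array.
#' @param path Destination file.
#' @param spacing Voxel spacing (mm).
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
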