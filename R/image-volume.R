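#' Voxel volume container
#'
#' An `image_volume` is a 3D voxel grid with explicit physical geometry: a
#' numeric array in `(slice, row, column)` order, a per-axis voxel spacing in
#' mm, the physical coordinate of voxel `(0,0,0)`, and a modality tag. CT
#' volumes carry Hounsfield units (HU); PET volumes carry SUV or SUL values in
#' g/mL. Axial slices are always the first array axis, so slice-range
#' operations are axis-order independent for the user.
#'
#' @param voxels numeric 3D array, `(slice, row, column)` order.
#' @param spacing numeric length-3, physical size of one voxel per axis (mm);
#'   all components must be positive.
#' @param origin numeric length-3, physical coordinate (mm) of voxel
#'   `(0,0,0)`.
#' @param modality `"CT"` or `"PET"`.
#'
#' @details CT voxel values outside the plausible HU range \[-1024, 3071\]
#'   trigger a warning, not an error: odd calibrations exist in the wild and
#'   segmentation windows make out-of-range values harmless.
#'
#' @return An object of class `image_volume`.
#' @export
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' voxel_volume_ml(vol)
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive finite numbers (mm)")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3 || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite numbers (mm)")
  }
  if (modality == "CT") {
    rng <- range(voxels, na.rm = TRUE)
    if (rng[1] < -1024 || rng[2] > 3071) {
      warn("CT voxel values outside the plausible HU range [-1024, 3071]")
    }
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         modality = modality),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_volume> %s, %d x %d x %d voxels (slice, row, col)\n",
    x$modality, d[1], d[2], d[3]
  ))
  cat(sprintf("  spacing: %s mm; origin: %s mm\n",
              paste(signif(x$spacing, 6), collapse = " x "),
              paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

is_image_volume <- function(x) inherits(x, "image_volume")

stopifnot_volume <- function(vol, modality = NULL) {
  if (!is_image_volume(vol)) abort("expected an `image_volume`")
  if (!is.null(modality) && vol$modality != modality) {
    abort(sprintf("expected a %s volume, got %s", modality, vol$modality))
  }
  invisible(vol)
}

#' Physical volume of one voxel
#'
#' @param vol an [image_volume()].
#' @return Volume of a single voxel in mL (product of the spacing components
#'   in mm^3 divided by 1000).
#' @export
voxel_volume_ml <- function(vol) {
  stopifnot_volume(vol)
  prod(vol$spacing) / 1000
}

#' Crop a volume to an axial slice range
#'
#' Keeps axial slices in the half-open, 0-based interval `[lo, hi)`. This
#' mimics truncating a whole-body acquisition to a limited-coverage range.
#' Spacing is unchanged; the origin shifts by `lo` times the axial spacing.
#'
#' @param vol an [image_volume()].
#' @param lo,hi integer slice bounds, `0 <= lo < hi <=` number of slices.
#' @return The cropped `image_volume` with exactly `hi - lo` slices.
#' @export
#' @examples
#' vol <- image_volume(array(rnorm(4 * 3 * 3), c(4, 3, 3)), c(1, 1, 1))
#' dim(crop_axial(vol, 1, 3))  # 2 slices
crop_axial <- function(vol, lo, hi) {
  stopifnot_volume(vol)
  n <- dim(vol$voxels)[1]
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 ||
      length(hi) != 1 || lo != floor(lo) || hi != floor(hi)) {
    abort("`lo` and `hi` must be single integers")
  }
  if (lo < 0 || hi > n || lo >= hi) {
    abort(sprintf(
      "invalid axial range [%d, %d) for a volume with %d slices", lo, hi, n
    ))
  }
  origin <- vol$origin
  origin[1] <- origin[1] + lo * vol$spacing[1]
  image_volume(
    vol$voxels[(lo + 1):hi, , , drop = FALSE],
    spacing = vol$spacing, origin = origin, modality = vol$modality
  )
}
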