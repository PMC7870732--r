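#' Hounsfield-unit window
#'
#' The adipose-tissue window used for fat segmentation. Both bounds are
#' inclusive; the default \[-190, -30\] HU is the conventional adipose window.
#'
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return A list of class `hu_window`.
#' @export
hu_window <- function(lo = -190, hi = -30) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 ||
      length(hi) != 1 || !is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort("`lo` and `hi` must be finite numbers with lo < hi")
  }
  structure(list(lo = lo, hi = hi), class = "hu_window")
}

#' Segment fat tissue by HU window
#'
#' Fat voxels are those whose CT number lies inside the window (both bounds
#' inclusive), optionally restricted to a body mask. Partial-volume voxels
#' are counted whole: the mask is binary, with no sub-voxel weighting.
#'
#' @param ct a CT [image_volume()].
#' @param window an [hu_window()]; default \[-190, -30\] HU.
#' @param mask optional logical array of the same shape (e.g. from
#'   [body_mask()]); segmentation is restricted to it when given.
#' @return A logical array the shape of `ct`.
#' @export
segment_fat <- function(ct, window = hu_window(), mask = NULL) {
  stopifnot_volume(ct, "CT")
  if (!inherits(window, "hu_window")) abort("`window` must be an `hu_window`")
  fat <- ct$voxels >= window$lo & ct$voxels <= window$hi
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(ct$voxels))) {
      abort("`mask` shape does not match the volume")
    }
    fat <- fat & mask
  }
  fat
}

#' Body mask by largest connected component
#'
#' Builds a patient-body mask so fat-range voxels outside the patient (couch
#' padding, positioning bags) do not count toward fat volume: voxels above
#' the air threshold are labelled by 26-connectivity, the largest component
#' is kept, and the result is morphologically closed so internal air (bowel
#' gas, airways) is included in the body.
#'
#' @param ct a CT [image_volume()].
#' @param air_threshold HU value separating air from tissue (default -500).
#' @param closing_radius box closing radius in voxels per axis (default 2;
#'   single values are recycled).
#' @return A logical array: the body mask.
#' @export
body_mask <- function(ct, air_threshold = -500, closing_radius = 2) {
  stopifnot_volume(ct, "CT")
  d <- dim(ct$voxels)
  m <- ct$voxels > air_threshold
  if (!any(m)) {
    abort("no voxels above the air threshold: empty body mask",
          class = "lbmct_content_error")
  }
  labels <- label_components_3d(as.logical(m), as.integer(d), 26L)
  tab <- tabulate(labels)
  keep <- which.max(tab)
  m <- array(labels == keep, d)
  r <- as.integer(rep_len(closing_radius, 3))
  if (any(r > 0)) {
    dil <- box_dilate_3d(as.logical(m), as.integer(d), r)
    # erosion as complement-dilation; complement padded implicitly by the
    # array border, so re-restrict to the dilated support
    ero <- !box_dilate_3d(!dil, as.integer(d), r)
    m <- array(ero | m, d)
  }
  m
}

#' Measure fat volume from a segmentation mask
#'
#' Multiplies the fat-voxel count by the physical volume of one voxel.
#' Optionally restricts the count to a half-open, 0-based axial slice range
#' (the limited-coverage convention).
#'
#' @param mask logical array from [segment_fat()].
#' @param vol the [image_volume()] the mask was derived from (for spacing).
#' @param region_label `"whole_body"`, `"limited_coverage"` or `"custom"`;
#'   defaults to a label recorded on `vol` by [limited_coverage_region()],
#'   else `"custom"`.
#' @param slice_range optional `c(lo, hi)`, half-open 0-based axial range to
#'   restrict the count to.
#' @return A one-row tibble: `region`, `voxel_count`, `fat_volume_ml`,
#'   `fat_volume_l`, `slice_lo`, `slice_hi`.
#' @export
fat_volume <- function(mask, vol, region_label = NULL, slice_range = NULL) {
  stopifnot_volume(vol)
  if (!identical(dim(mask), dim(vol$voxels))) {
    abort("`mask` shape does not match the volume")
  }
  region_label <- region_label %||% attr(vol, "region_label") %||% "custom"
  region_label <- match.arg(region_label,
                            c("whole_body", "limited_coverage", "custom"))
  if (!is.null(slice_range)) {
    n <- dim(mask)[1]
    lo <- slice_range[1]; hi <- slice_range[2]
    if (lo < 0 || hi > n || lo >= hi) {
      abort(sprintf("invalid slice range [%d, %d)", lo, hi))
    }
    counted <- sum(mask[(lo + 1):hi, , , drop = FALSE])
  } else {
    counted <- sum(mask)
    src <- attr(vol, "source_slice_range")
    lo <- if (is.null(src)) NA_integer_ else src[1]
    hi <- if (is.null(src)) NA_integer_ else src[2]
  }
  ml <- counted * voxel_volume_ml(vol)
  tibble(
    region = region_label,
    voxel_count = as.integer(counted),
    fat_volume_ml = ml,
    fat_volume_l = ml / 1000,
    slice_lo = as.integer(lo),
    slice_hi = as.integer(hi)
  )
}

#' Convert fat volume to fat mass
#'
#' @param fv_l fat volume in litres (non-negative).
#' @param density adipose-tissue average density in kg/L; default 0.923.
#' @return Fat mass in kg.
#' @export
#' @examples
#' fat_mass_from_volume(1)       # 0.923 kg
fat_mass_from_volume <- function(fv_l, density = 0.923) {
  if (any(!is.finite(fv_l)) || any(fv_l < 0)) {
    abort("`fv_l` must be non-negative", class = "lbmct_domain_error")
  }
  if (!is.numeric(density) || density <= 0) {
    abort("`density` must be positive", class = "lbmct_domain_error")
  }
  density * fv_l
}

#' Extract the limited-coverage sub-volume
#'
#' Truncates a whole-body CT to the limited-coverage axial range (in the
#' clinical setting, from the top level of the thorax to the distal point of
#' the ischium; the landmarks are supplied as slice indices since no
#' automatic anatomical detection is attempted). The returned volume records
#' the region label and slice range for provenance, and [fat_volume()] picks
#' them up automatically.
#'
#' @inheritParams crop_axial
#' @param ct a CT [image_volume()].
#' @return The cropped volume, tagged `limited_coverage`.
#' @export
limited_coverage_region <- function(ct, lo, hi) {
  stopifnot_volume(ct, "CT")
  out <- crop_axial(ct, lo, hi)
  attr(out, "region_label") <- "limited_coverage"
  attr(out, "source_slice_range") <- c(lo, hi)
  out
}
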