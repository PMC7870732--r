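#' Read a voxel volume
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`) or a directory containing a
#' single uncompressed DICOM series into an [image_volume()]. DICOM slices
#' are ordered by their physical slice position (not filename), and the
#' rescale slope/intercept is applied at read time so downstream code always
#' sees Hounsfield units. NIfTI volumes written by [write_volume()] carry a
#' JSON sidecar (`<path>.json`) with the modality tag and exact geometry; it
#' is honoured when present.
#'
#' @param path path to a NIfTI file or to a DICOM series directory.
#' @param format_hint optional `"nifti"` or `"dicom"`; by default inferred
#'   from the path (directory implies DICOM).
#' @return An [image_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format_hint = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "lbmct_not_found")
  }
  fmt <- format_hint %||%
    (if (dir.exists(path)) "dicom" else "nifti")
  fmt <- match.arg(fmt, c("nifti", "dicom"))
  if (fmt == "dicom") {
    return(read_dicom_series(path))
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) abort("expected a 3D NIfTI volume")
  spacing <- RNifti::pixdim(img)[1:3]
  # stored NIfTI axis order is (column, row, slice); normalise
  vox <- aperm(arr, c(3, 2, 1))
  spacing <- rev(spacing)
  modality <- "CT"
  origin <- c(0, 0, 0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    modality <- meta$modality %||% modality
    if (!is.null(meta$spacing)) spacing <- as.numeric(meta$spacing)
    if (!is.null(meta$origin)) origin <- as.numeric(meta$origin)
  }
  suppressWarnings(
    image_volume(vox, spacing = spacing, origin = origin, modality = modality)
  )
}

#' Write a voxel volume as NIfTI
#'
#' Writes the volume as an uncompressed-precision (float64) NIfTI-1 file plus
#' a JSON sidecar holding the modality tag and the exact spacing and origin,
#' so that a write/read round trip preserves voxel values, shape and geometry
#' bit-exactly (NIfTI stores pixdim as float32; the sidecar keeps the full
#' double precision).
#'
#' @param vol an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  if (!dir.exists(dirname(path))) {
    abort(sprintf("parent directory does not exist: %s", dirname(path)),
          class = "lbmct_io_error")
  }
  arr <- aperm(vol$voxels, c(3, 2, 1))
  attr(arr, "pixdim") <- rev(vol$spacing)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(modality = vol$modality, spacing = vol$spacing, origin = vol$origin),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
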