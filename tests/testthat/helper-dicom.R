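# Writes minimal explicit-VR little-endian DICOM part-10 slices so the DICOM
# reader can be tested without shipping binary fixtures.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_elem_str <- function(group, elem, vr, value) {
  v <- charToRaw(value)
  if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
  c(u16le(group), u16le(elem), charToRaw(vr), u16le(length(v)), v)
}

dcm_elem_us <- function(group, elem, value) {
  c(u16le(group), u16le(elem), charToRaw("US"), u16le(2), u16le(value))
}

dcm_elem_pixels <- function(stored) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.integer(stored), con, size = 2, endian = "little")
  v <- rawConnectionValue(con)
  close(con)
  c(u16le(0x7fe0), u16le(0x0010), charToRaw("OW"), raw(2),
    u32le(length(v)), v)
}

# slice: integer matrix [row, col] of stored values (signed 16-bit)
write_test_dicom_slice <- function(path, slice, z, pixel_spacing = c(1, 1),
                                   ipp_xy = c(0, 0), slope = 1,
                                   intercept = 0, series_uid = "1.2.3.4",
                                   modality = "CT") {
  stored <- as.vector(t(slice))  # row-major, as PixelData requires
  body <- c(
    dcm_elem_str(0x0008, 0x0060, "CS", modality),
    dcm_elem_str(0x0020, 0x000e, "UI", series_uid),
    dcm_elem_str(0x0020, 0x0032, "DS",
                 sprintf("%g\\%g\\%g", ipp_xy[1], ipp_xy[2], z)),
    dcm_elem_us(0x0028, 0x0010, nrow(slice)),
    dcm_elem_us(0x0028, 0x0011, ncol(slice)),
    dcm_elem_str(0x0028, 0x0030, "DS",
                 sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2])),
    dcm_elem_us(0x0028, 0x0100, 16),
    dcm_elem_us(0x0028, 0x0103, 1),
    dcm_elem_str(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    dcm_elem_str(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    dcm_elem_pixels(stored)
  )
  meta <- dcm_elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  invisible(path)
}

# Writes a series of constant-value 4x4 slices at the given z positions.
write_test_dicom_series <- function(dir, z_positions, value = 0, slope = 1,
                                    intercept = 0, series_uid = "1.2.3.4",
                                    pixel_spacing = c(1, 1),
                                    filenames = NULL) {
  dir.create(dir, showWarnings = FALSE)
  filenames <- filenames %||%
    sprintf("slice%02d.dcm", seq_along(z_positions))
  for (i in seq_along(z_positions)) {
    write_test_dicom_slice(
      file.path(dir, filenames[i]),
      matrix(value, 4, 4), z = z_positions[i],
      pixel_spacing = pixel_spacing, slope = slope, intercept = intercept,
      series_uid = series_uid
    )
  }
  dir
}

`%||%` <- function(a, b) if (is.null(a)) b else a
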