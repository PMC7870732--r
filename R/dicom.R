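# Minimal DICOM series reader: uncompressed little-endian transfer syntaxes
# (implicit VR 1.2.840.10008.1.2 and explicit VR 1.2.840.10008.1.2.1), 16-bit
# single-frame grayscale slices. Covers CT/PET series as exported by scanners;
# encapsulated/compressed pixel data is rejected.

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1])
}

dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1]) +
    65536 * as.numeric(raw[pos + 2]) + 16777216 * as.numeric(raw[pos + 3])
}

dcm_string <- function(value) {
  s <- rawToChar(value[value != as.raw(0)])
  trimws(s)
}

dcm_ds <- function(value) {
  as.numeric(strsplit(dcm_string(value), "\\\\")[[1]])
}

# VRs that use the 12-byte (reserved + 32-bit length) explicit header
dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one element; returns list(tag, value, next_pos) or NULL at end.
dcm_parse_element <- function(raw, pos, explicit) {
  n <- length(raw)
  if (pos + 7 > n) return(NULL)
  group <- dcm_u16(raw, pos)
  elem <- dcm_u16(raw, pos + 2)
  pos <- pos + 4
  if (explicit) {
    vr <- rawToChar(raw[pos:(pos + 1)])
    pos <- pos + 2
    if (vr %in% dcm_long_vrs) {
      len <- dcm_u32(raw, pos + 2)
      pos <- pos + 6
    } else {
      len <- dcm_u16(raw, pos)
      pos <- pos + 2
    }
  } else {
    len <- dcm_u32(raw, pos)
    pos <- pos + 4
  }
  if (len == 4294967295) {
    abort("undefined-length DICOM elements (sequences) are not supported")
  }
  value <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
  list(tag = sprintf("%04x,%04x", group, elem), group = group,
       value = value, next_pos = pos + len)
}

# Read a single DICOM file, returning the tags this reader needs.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    abort(sprintf("not a DICOM part-10 file: %s", basename(path)),
          class = "lbmct_format_error")
  }
  pos <- 133
  # file meta group (0002,xxxx) is always explicit VR little endian
  ts <- NULL
  repeat {
    el <- dcm_parse_element(raw, pos, explicit = TRUE)
    if (is.null(el) || el$group != 2L) break
    if (el$tag == "0002,0010") ts <- dcm_string(el$value)
    pos <- el$next_pos
  }
  explicit <- if (is.null(ts) || ts == "1.2.840.10008.1.2.1") TRUE
  else if (ts == "1.2.840.10008.1.2") FALSE
  else abort(sprintf("unsupported transfer syntax %s in %s", ts,
                     basename(path)), class = "lbmct_format_error")
  wanted <- c("0008,0060", "0020,000e", "0020,0032", "0028,0010",
              "0028,0011", "0028,0030", "0028,0100", "0028,0103",
              "0028,1052", "0028,1053", "7fe0,0010")
  tags <- list()
  repeat {
    el <- dcm_parse_element(raw, pos, explicit = explicit)
    if (is.null(el)) break
    if (el$tag %in% wanted) tags[[el$tag]] <- el$value
    pos <- el$next_pos
  }
  for (req in c("0028,0010", "0028,0011", "0020,0032", "7fe0,0010")) {
    if (is.null(tags[[req]])) {
      abort(sprintf("DICOM file %s lacks required element (%s)",
                    basename(path), req), class = "lbmct_format_error")
    }
  }
  rows <- dcm_u16(tags[["0028,0010"]], 1)
  cols <- dcm_u16(tags[["0028,0011"]], 1)
  bits <- if (!is.null(tags[["0028,0100"]])) dcm_u16(tags[["0028,0100"]], 1) else 16L
  if (bits != 16) {
    abort(sprintf("only 16-bit DICOM pixel data supported (%s)",
                  basename(path)), class = "lbmct_format_error")
  }
  signed <- !is.null(tags[["0028,0103"]]) && dcm_u16(tags[["0028,0103"]], 1) == 1L
  stored <- readBin(tags[["7fe0,0010"]], "integer", n = rows * cols,
                    size = 2, signed = signed, endian = "little")
  slope <- if (!is.null(tags[["0028,1053"]])) dcm_ds(tags[["0028,1053"]]) else 1
  intercept <- if (!is.null(tags[["0028,1052"]])) dcm_ds(tags[["0028,1052"]]) else 0
  # PixelData is row-major: first Columns pixels form the first row
  slice <- t(matrix(slope * stored + intercept, nrow = cols, ncol = rows))
  ipp <- dcm_ds(tags[["0020,0032"]])
  ps <- if (!is.null(tags[["0028,0030"]])) dcm_ds(tags[["0028,0030"]]) else c(1, 1)
  list(
    slice = slice,
    ipp = ipp,
    pixel_spacing = ps,  # (row, column) mm
    series_uid = if (!is.null(tags[["0020,000e"]])) dcm_string(tags[["0020,000e"]]) else "",
    modality = if (!is.null(tags[["0008,0060"]])) dcm_string(tags[["0008,0060"]]) else "CT",
    file = basename(path)
  )
}

# Read a directory holding exactly one DICOM series; slices ordered by
# physical z position. Inconsistent slice spacing (> 1% spread) or mixed
# series UIDs raise a format error naming the offending slices.
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) {
    abort(sprintf("no files in DICOM directory %s", dir),
          class = "lbmct_format_error")
  }
  slices <- lapply(files, read_dicom_file)
  uids <- unique(vapply(slices, `[[`, "", "series_uid"))
  if (length(uids) > 1) {
    abort(sprintf("directory mixes %d DICOM series (files: %s)", length(uids),
                  paste(vapply(slices, `[[`, "", "file"), collapse = ", ")),
          class = "lbmct_format_error")
  }
  z <- vapply(slices, function(s) s$ipp[3], 0)
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  if (length(slices) > 1) {
    dz <- diff(z)
    if (any(dz <= 0)) {
      abort("duplicate or non-increasing DICOM slice positions",
            class = "lbmct_format_error")
    }
    ref <- median(dz)
    bad <- which(abs(dz - ref) / ref > 0.01)
    if (length(bad) > 0) {
      offending <- unique(c(vapply(slices[bad], `[[`, "", "file"),
                            vapply(slices[bad + 1], `[[`, "", "file")))
      abort(sprintf(
        "non-uniform DICOM slice spacing (spread > 1%%); offending slices: %s",
        paste(offending, collapse = ", ")
      ), class = "lbmct_format_error")
    }
    axial <- ref
  } else {
    axial <- 1
  }
  d <- dim(slices[[1]]$slice)
  vox <- array(0, c(length(slices), d[1], d[2]))
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]$slice), d)) {
      abort("DICOM slices have inconsistent matrix sizes",
            class = "lbmct_format_error")
    }
    vox[i, , ] <- slices[[i]]$slice
  }
  ps <- slices[[1]]$pixel_spacing
  modality <- if (slices[[1]]$modality %in% c("PT", "PET")) "PET" else "CT"
  suppressWarnings(image_volume(
    vox,
    spacing = c(axial, ps[1], ps[2]),
    origin = c(z[1], slices[[1]]$ipp[2], slices[[1]]$ipp[1]),
    modality = modality
  ))
}
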