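# Minimal DICOM writer used to build series fixtures at test time
# (explicit VR little endian, single-frame 16-bit grayscale).

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(r, pad = as.raw(0)) if (length(r) %% 2) c(r, pad) else r

dcm_el <- function(group, elem, vr, value) {
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(value)), value)
  } else {
    c(head, dcm_u16(length(value)), value)
  }
}

dcm_str_val <- function(s, pad = as.raw(32)) dcm_pad(charToRaw(s), pad)

write_test_dicom <- function(path, pixels, instance, spacing = c(1, 1),
                             thickness = 1, slope = NULL, intercept = NULL,
                             omit_instance = FALSE, omit_geometry = FALSE) {
  ts <- dcm_str_val("1.2.840.10008.1.2.1", as.raw(0))
  meta <- dcm_el(2L, 16L, "UI", ts)
  body <- raw(0)
  if (!omit_geometry)
    body <- c(body, dcm_el(24L, 80L, "DS", dcm_str_val(format(thickness))))
  if (!omit_instance)
    body <- c(body, dcm_el(32L, 19L, "IS", dcm_str_val(as.character(instance))))
  body <- c(body,
            dcm_el(40L, 2L, "US", dcm_u16(1)),            # SamplesPerPixel
            dcm_el(40L, 16L, "US", dcm_u16(nrow(pixels))), # Rows
            dcm_el(40L, 17L, "US", dcm_u16(ncol(pixels)))) # Columns
  if (!omit_geometry)
    body <- c(body, dcm_el(40L, 48L, "DS",
                           dcm_str_val(paste(spacing, collapse = "\\"))))
  body <- c(body,
            dcm_el(40L, 256L, "US", dcm_u16(16)),  # BitsAllocated
            dcm_el(40L, 259L, "US", dcm_u16(0)))   # PixelRepresentation
  if (!is.null(intercept))
    body <- c(body, dcm_el(40L, 4178L, "DS", dcm_str_val(format(intercept))))
  if (!is.null(slope))
    body <- c(body, dcm_el(40L, 4179L, "DS", dcm_str_val(format(slope))))
  px <- dcm_u16(as.vector(t(pixels)))  # row-major
  body <- c(body, dcm_el(32736L, 16L, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

write_test_series <- function(dir, stack, instances = seq_len(dim(stack)[1]),
                              ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(dim(stack)[1]))
    write_test_dicom(file.path(dir, sprintf("img%02d.dcm", i)),
                     stack[i, , ], instance = instances[i], ...)
  invisible(dir)
}
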