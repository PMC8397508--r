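## Minimal read-only DICOM support.
##
## MPI scanners export plain single-frame grayscale series; none of the
## pre-existing R imaging stack reads DICOM, so a deliberately small parser
## is provided here.  Scope: little-endian transfer syntaxes (implicit and
## explicit VR), uncompressed 8/16-bit single-sample pixel data, defined
## lengths only.  Anything else errors rather than guessing.

dcm_uint <- function(raw, signed = FALSE) {
  sum(as.integer(raw) * 256^(seq_along(raw) - 1))
}

## Parse one data element starting at offset `pos` (1-based) in raw vector.
## Returns list(group, element, value_raw, vr, next_pos).
dcm_element <- function(bytes, pos, explicit) {
  group <- dcm_uint(bytes[pos:(pos + 1)])
  elem  <- dcm_uint(bytes[(pos + 2):(pos + 3)])
  pos <- pos + 4
  vr <- NA_character_
  if (explicit) {
    vr <- rawToChar(bytes[pos:(pos + 1)])
    pos <- pos + 2
    if (vr %in% c("OB", "OW", "OF", "OL", "SQ", "UC", "UR", "UT", "UN")) {
      len <- dcm_uint(bytes[(pos + 2):(pos + 5)])
      pos <- pos + 6
    } else {
      len <- dcm_uint(bytes[pos:(pos + 1)])
      pos <- pos + 2
    }
  } else {
    len <- dcm_uint(bytes[pos:(pos + 3)])
    pos <- pos + 4
  }
  if (len == 4294967295)
    stop("DICOM element with undefined length is not supported ",
         sprintf("(%04x,%04x)", group, elem))
  val <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
  list(group = group, element = elem, vr = vr, value = val,
       next_pos = pos + len)
}

dcm_str <- function(val) trimws(rawToChar(val[val != as.raw(0)]))

dcm_us <- function(val) dcm_uint(val[1:2])

## Read the tags this pipeline needs from one single-frame DICOM file.
read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 160 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  pos <- 133
  ts <- "1.2.840.10008.1.2.1"
  # file meta group (0002,....) is always explicit VR little endian
  while (pos < length(bytes)) {
    el <- dcm_element(bytes, pos, explicit = TRUE)
    if (el$group != 2L) break
    if (el$element == 16L) ts <- dcm_str(el$value)  # (0002,0010)
    pos <- el$next_pos
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2"   = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported DICOM transfer syntax ", ts, " in ", path))
  tags <- list()
  while (pos <= length(bytes) - 7) {
    el <- dcm_element(bytes, pos, explicit = explicit)
    key <- sprintf("%04x%04x", el$group, el$element)
    tags[[key]] <- el
    pos <- el$next_pos
  }
  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("DICOM file lacks ", what, ": ", path)
    tags[[key]]
  }
  rows <- dcm_us(need("00280010", "Rows")$value)
  cols <- dcm_us(need("00280011", "Columns")$value)
  bits <- dcm_us(need("00280100", "BitsAllocated")$value)
  signed <- !is.null(tags[["00280103"]]) && dcm_us(tags[["00280103"]]$value) == 1
  if (!bits %in% c(8L, 16L))
    stop("unsupported BitsAllocated = ", bits, " in ", path)
  if (!is.null(tags[["00280002"]]) && dcm_us(tags[["00280002"]]$value) != 1)
    stop("multi-sample DICOM pixel data is not supported: ", path)
  px <- need("7fe00010", "PixelData")$value
  vals <- readBin(px, what = "integer", n = rows * cols,
                  size = bits / 8, signed = signed, endian = "little")
  slope <- if (!is.null(tags[["00281053"]])) as.numeric(dcm_str(tags[["00281053"]]$value)) else 1
  inter <- if (!is.null(tags[["00281052"]])) as.numeric(dcm_str(tags[["00281052"]]$value)) else 0
  inst <- if (!is.null(tags[["00200013"]])) as.integer(dcm_str(tags[["00200013"]]$value)) else NA_integer_
  spacing <- if (!is.null(tags[["00280030"]]))
    as.numeric(strsplit(dcm_str(tags[["00280030"]]$value), "\\\\")[[1]]) else NULL
  thick <- if (!is.null(tags[["00180050"]]))
    as.numeric(dcm_str(tags[["00180050"]]$value)) else NULL
  list(pixels = matrix(vals * slope + inter, nrow = rows, byrow = TRUE),
       instance = inst, spacing = spacing, thickness = thick)
}

## Assemble a directory of single-frame DICOM files into a volume, slices
## ordered by instance number.
read_dicom_series <- function(path, meta = list()) {
  if (!dir.exists(path)) stop("no such DICOM directory: ", path)
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L)
    stop("a DICOM series needs at least 2 slices; found ", length(files),
         " file(s) in ", path)
  frames <- lapply(files, read_dicom_file)
  inst <- vapply(frames, `[[`, integer(1), "instance")
  if (any(is.na(inst)))
    stop("DICOM series has files without InstanceNumber; cannot order slices")
  if (anyDuplicated(inst))
    stop("DICOM series has duplicate InstanceNumbers")
  frames <- frames[order(inst)]
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("DICOM series slices disagree in shape")
  v <- aperm(simplify2array(lapply(frames, `[[`, "pixels")), c(3, 1, 2))
  sp <- frames[[1]]$spacing
  th <- frames[[1]]$thickness
  if (is.null(sp) || is.null(th)) {
    warning("DICOM series carries incomplete voxel geometry; ",
            "assuming 1 mm where missing")
    if (is.null(sp)) sp <- c(1, 1)
    if (is.null(th)) th <- 1
  }
  scan_volume(v, voxel_size = c(th, sp[1], sp[2]), meta = meta)
}
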