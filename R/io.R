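## Scan volume container and format readers/writers.
##
## Internal convention: a volume is a 3D array ordered (slice z, row y,
## col x) with the slice axis first, all indices 1-based.  Intensities are
## arbitrary MPI units and are never rescaled on load — MPI signal is linear
## in iron, so rescaling would silently change any downstream calibration.

#' Construct a scan volume
#'
#' @param voxels 3D numeric array of intensities ordered `(z, y, x)`;
#'   slice = axis 1.  All values must be finite.
#' @param voxel_size Numeric length-3 voxel edge lengths in mm per axis.
#' @param meta Named list of free-form metadata (subject id, timepoint,
#'   modality tag, ...).
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(voxels, voxel_size = c(1, 1, 1), meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array ordered (z, y, x)")
  if (any(!is.finite(voxels))) stop("`voxels` must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths (mm)")
  structure(list(voxels = voxels, voxel_size = voxel_size, meta = meta),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("MPI scan volume: %d slices x %d x %d voxels (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("intensity range [%.4g, %.4g] (arbitrary units)\n",
              min(x$voxels), max(x$voxels)))
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

guess_format <- function(path) {
  if (dir.exists(path)) return("dicom")
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.tiff?$", lp)) return("tiff")
  if (grepl("\\.dcm$", lp)) return("dicom")
  stop("cannot guess format of ", path, "; pass `format` explicitly")
}

#' Read a scan volume from disk
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`; the reference, lossless
#' format), multi-page TIFF stacks, and minimal single-frame DICOM series
#' (a directory of `.dcm` files, read-only; slices are ordered by instance
#' number).  Axis order is normalized to `(z, y, x)` and intensities are
#' left untouched.  Voxel size is taken from the header (or the TIFF JSON
#' sidecar written by [write_scan()]) when present; otherwise 1 mm isotropic
#' is assumed with a warning.
#'
#' @param path File (NIfTI/TIFF) or directory (DICOM series).
#' @param format One of `"auto"`, `"nifti"`, `"tiff"`, `"dicom"`.
#' @param meta Metadata list attached to the returned volume.
#' @return A [scan_volume()].
#' @export
read_scan <- function(path, format = c("auto", "nifti", "tiff", "dicom"),
                      meta = list()) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format != "dicom" && !file.exists(path)) stop("no such file: ", path)
  switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      v <- as.array(img)
      if (length(dim(v)) == 4L && dim(v)[4] == 1L) v <- v[, , , 1]
      if (length(dim(v)) != 3L)
        stop("NIfTI input is not a 3D volume (2D-only input without stack?): ",
             path)
      pd <- RNifti::pixdim(img)
      # stored order (x, y, z) -> internal (z, y, x)
      scan_volume(aperm(v, c(3, 2, 1)), voxel_size = rev(pd[1:3]), meta = meta)
    },
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      if (length(pages) < 2L)
        stop("TIFF input has a single page; a 2D-only image is not a volume: ",
             path)
      if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
        stop("multi-channel TIFF pages are not supported: ", path)
      v <- aperm(simplify2array(pages), c(3, 1, 2))  # (page=z, row=y, col=x)
      side <- paste0(path, ".json")
      vs <- c(1, 1, 1); scale <- 1
      if (file.exists(side)) {
        sc <- jsonlite::read_json(side, simplifyVector = TRUE)
        if (!is.null(sc$voxel_size_mm)) vs <- as.numeric(sc$voxel_size_mm)
        if (!is.null(sc$intensity_scale)) scale <- as.numeric(sc$intensity_scale)
        if (is.null(names(meta)) && !is.null(sc$meta)) meta <- as.list(sc$meta)
      } else {
        warning("TIFF carries no voxel geometry; assuming 1 mm isotropic voxels")
      }
      scan_volume(v * scale, voxel_size = vs, meta = meta)
    },
    dicom = read_dicom_series(path, meta = meta))
}

#' Write a scan volume to disk
#'
#' NIfTI output is a lossless float64 round-trip.  TIFF output is 32-bit
#' float and, because the TIFF writer stores values in `[0, 1]`, intensities
#' are divided by a power-of-two scale (exact in floating point) recorded,
#' together with voxel size and metadata, in a `<path>.json` sidecar that
#' [read_scan()] uses to restore them.
#'
#' @param scan A [scan_volume()].
#' @param path Output file; extension selects the format unless `format`
#'   is given.
#' @param format `"auto"`, `"nifti"` or `"tiff"` (DICOM is read-only).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, format = c("auto", "nifti", "tiff")) {
  stopifnot(inherits(scan, "scan_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") {
    img <- RNifti::asNifti(aperm(scan$voxels, c(3, 2, 1)))
    RNifti::pixdim(img) <- rev(scan$voxel_size)
    RNifti::writeNifti(img, path)
  } else if (format == "tiff") {
    mx <- max(scan$voxels)
    scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
    pages <- lapply(seq_len(dim(scan$voxels)[1]),
                    function(z) scan$voxels[z, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(intensity_scale = scale,
                              voxel_size_mm = scan$voxel_size,
                              meta = scan$meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else stop("DICOM output is not supported")
  invisible(path)
}

#' Describe a fiducial marker
#'
#' A fiducial marker is a small tube of tracer at known concentration placed
#' at a fixed position in the scanner bed; its known iron mass anchors the
#' signal-to-iron standard curve.
#'
#' @param id Unique label.
#' @param expected_center Expected voxel coordinates `(z, y, x)`, 1-based.
#' @param concentration_fraction Fraction of the stock concentration in
#'   `(0, 1]` (e.g. 0.40 for a 40% dilution).
#' @param stock_iron_mg_per_ml Stock iron concentration (mg/ml, > 0);
#'   default 5.5 mg/ml, the standard VivoTrax stock.
#' @param volume_ul Marker volume in µl (> 0).
#' @param search_radius Matching radius in voxels used by
#'   [assign_fiducials()].
#' @return An object of class `fiducial_spec`.
#' @export
fiducial_spec <- function(id, expected_center, concentration_fraction,
                          stock_iron_mg_per_ml = 5.5, volume_ul = 1,
                          search_radius = 5) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("`id` must be a non-empty string")
  expected_center <- as.numeric(expected_center)
  if (length(expected_center) != 3L || any(!is.finite(expected_center)))
    stop(sprintf("fiducial '%s': `expected_center` must be (z, y, x)", id))
  if (!is.numeric(concentration_fraction) ||
      concentration_fraction <= 0 || concentration_fraction > 1)
    stop(sprintf("fiducial '%s': concentration_fraction must be in (0, 1]", id))
  if (stock_iron_mg_per_ml <= 0 || volume_ul <= 0)
    stop(sprintf("fiducial '%s': stock concentration and volume must be > 0", id))
  if (search_radius <= 0)
    stop(sprintf("fiducial '%s': search_radius must be > 0", id))
  structure(list(id = id, expected_center = expected_center,
                 concentration_fraction = concentration_fraction,
                 stock_iron_mg_per_ml = stock_iron_mg_per_ml,
                 volume_ul = volume_ul, search_radius = search_radius),
            class = "fiducial_spec")
}

#' Read fiducial specifications from JSON or CSV
#'
#' The file must provide columns/fields `id`, `z`, `y`, `x` (or an
#' `expected_center` array in JSON), `concentration_fraction`,
#' `stock_iron_mg_per_ml` and `volume_ul`; `search_radius` is optional
#' (default 5 voxels).
#'
#' @param path `.json` or `.csv` file.
#' @return List of [fiducial_spec()] objects.
#' @export
read_fiducials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", tolower(path))) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (grepl("\\.csv$", tolower(path))) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  } else stop("fiducial file must be .json or .csv: ", path)
  if (length(recs) == 0L)
    stop("fiducial file is empty; calibration is impossible: ", path)
  specs <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    center <- if (!is.null(r$expected_center)) unlist(r$expected_center)
              else c(r$z, r$y, r$x)
    for (fld in c("id", "concentration_fraction", "stock_iron_mg_per_ml",
                  "volume_ul"))
      if (is.null(r[[fld]]))
        stop(sprintf("fiducial record %d is missing field '%s'", i, fld))
    if (length(center) != 3L || any(is.na(as.numeric(center))))
      stop(sprintf("fiducial record %d ('%s') has no valid center (z, y, x)",
                   i, r$id))
    fiducial_spec(id = as.character(r$id), expected_center = as.numeric(center),
                  concentration_fraction = as.numeric(r$concentration_fraction),
                  stock_iron_mg_per_ml = as.numeric(r$stock_iron_mg_per_ml),
                  volume_ul = as.numeric(r$volume_ul),
                  search_radius = if (is.null(r$search_radius)) 5
                                  else as.numeric(r$search_radius))
  })
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate fiducial ids: ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "))
  specs
}

#' Write fiducial specifications to JSON
#'
#' @param specs List of [fiducial_spec()] objects.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(specs, path) {
  recs <- lapply(specs, function(sp) {
    sp <- unclass(sp)
    sp$expected_center <- as.numeric(sp$expected_center)
    sp
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
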