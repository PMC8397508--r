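## Pipeline report output: JSON + CSV tables plus mask volumes aligned with
## the input scan.

#' Write a quantification report
#'
#' Writes `<prefix>.json` (curve coefficients and R², per-slice pixel sums
#' and TIVs, total TIV, fiducial table, cluster/segmentation diagnostics),
#' `<prefix>.csv` (the per-slice table) and, when `masks = TRUE`, the ROI
#' and graft masks as volumes aligned with the input scan
#' (`<prefix>_roi_mask.<ext>`, `<prefix>_graft_mask.<ext>`).
#'
#' @param result An [quantify_scan()] result.
#' @param prefix Output path prefix (directories are created as needed).
#' @param masks Write mask volumes? Default `TRUE`.
#' @param mask_format `"nifti"` or `"tiff"`.
#' @param voxel_size Voxel size stamped on mask volumes; defaults to the
#'   scan's if recorded in the result metadata, else 1 mm.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(result, prefix, masks = TRUE,
                         mask_format = c("nifti", "tiff"),
                         voxel_size = NULL) {
  stopifnot(inherits(result, "mpi_quantification"))
  mask_format <- match.arg(mask_format)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  seg <- result$segmentation
  nslices <- seg$dims[1]
  slice_tab <- data.frame(
    slice = seq_len(nslices),
    roi_pixel_sum = vapply(seg$slices, `[[`, numeric(1), "roi_pixel_sum"),
    graft_pixel_sum = seg$graft_slice_sums,
    graft_tiv_ug = if (!is.null(result$tiv$per_slice_tiv_ug))
      result$tiv$per_slice_tiv_ug else rep(NA_real_, nslices),
    k_used = vapply(seg$slices, `[[`, integer(1), "k_used"),
    flagged = vapply(seg$slices, `[[`, logical(1), "flagged"))
  report <- list(
    meta = result$meta,
    params = result$params,
    total_tiv_ug = result$tiv$total_tiv_ug,
    method = result$tiv$method,
    curve = list(slope = result$curve$slope,
                 intercept = result$curve$intercept,
                 r_squared = result$curve$r_squared,
                 mode = result$curve$mode,
                 n_points = result$curve$n_points),
    fiducials = result$fiducial_table,
    per_slice = slice_tab,
    segmentation = list(
      n_slices = nslices,
      roi_voxels = sum(seg$mask),
      noise_floor = seg$noise_floor,
      n_components = length(seg$components$components),
      n_graft_components = length(seg$graft_components),
      flagged_slices = which(slice_tab$flagged)))
  files <- character(0)
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  files <- c(files, json_path)
  csv_path <- paste0(prefix, ".csv")
  write.csv(slice_tab, csv_path, row.names = FALSE)
  files <- c(files, csv_path)
  if (masks) {
    vs <- if (!is.null(voxel_size)) voxel_size else c(1, 1, 1)
    ext <- if (mask_format == "nifti") ".nii.gz" else ".tif"
    for (nm in c("roi_mask", "graft_mask")) {
      m <- if (nm == "roi_mask") seg$mask else seg$graft_mask
      p <- paste0(prefix, "_", nm, ext)
      write_scan(scan_volume(array(as.numeric(m), dim(m)), voxel_size = vs),
                 p, format = mask_format)
      files <- c(files, p)
    }
  }
  invisible(files)
}
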