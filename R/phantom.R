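## Synthetic MPI phantom generator.
##
## The generator emulates the linear MPI signal model: each iron source
## deposits a Gaussian-blurred blob whose intensity integral equals
## signal_per_ug * iron_ug, before noise.  It makes no attempt to model the
## physical MPI forward problem (drive field, harmonics, x-space
## reconstruction); linearity of signal in iron mass is assumed.

#' Describe a point source of iron in a phantom
#'
#' @param center Numeric length-3 voxel coordinates `(z, y, x)`, 1-based.
#'   May be fractional (sub-voxel positions are supported by the blur model).
#' @param iron_ug Iron mass of the source in µg (>= 0).
#' @param kind Either `"fiducial"` (reference marker) or `"graft"`
#'   (the labeled cell graft being quantified).
#' @return An object of class `iron_source`.
#' @seealso [phantom_config()], [render_scan()]
#' @export
iron_source <- function(center, iron_ug, kind = c("graft", "fiducial")) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be three finite voxel coordinates (z, y, x)")
  if (!is.numeric(iron_ug) || length(iron_ug) != 1L || !is.finite(iron_ug) ||
      iron_ug < 0)
    stop("`iron_ug` must be a single non-negative number")
  structure(list(center = center, iron_ug = iron_ug, kind = kind),
            class = "iron_source")
}

#' Configuration of a synthetic MPI phantom scan
#'
#' Defines the voxel grid, the linear signal gain, the Gaussian point-spread
#' width and the noise model used by [render_scan()].
#'
#' @param grid_shape Integer length-3 voxels per axis `(z slices, y, x)`.
#'   The default 36 x 64 x 64 gives a slice count inside the 32-36 layer
#'   range typical of a whole-mouse 3D MPI acquisition.
#' @param voxel_size Numeric length-3 voxel edge lengths in mm.
#' @param signal_per_ug Intensity-sum units produced per µg of iron
#'   (scanner gain, arbitrary units; > 0).
#' @param psf_sigma Gaussian point-spread sigma in voxels, either a scalar
#'   (isotropic) or length-3 per axis.  `0` collapses a source onto its
#'   nearest voxel.
#' @param noise_additive_sd Standard deviation of additive Gaussian noise in
#'   intensity units.  `NULL` (default) resolves at render time to 0.5% of
#'   the peak noise-free fiducial intensity (or of the overall peak if the
#'   configuration has no fiducials).
#' @param noise_multiplicative_cv Coefficient of variation of multiplicative
#'   Gaussian noise (unitless fraction).
#' @param rng_seed Integer seed; identical seeds give byte-identical volumes.
#' @param sources List of [iron_source()] objects.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(36L, 64L, 64L),
                           voxel_size = c(1, 1, 1),
                           signal_per_ug = 1000,
                           psf_sigma = 1,
                           noise_additive_sd = NULL,
                           noise_multiplicative_cv = 0.01,
                           rng_seed = 42L,
                           sources = list()) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)) || any(grid_shape < 1L))
    stop("`grid_shape` must be three integers >= 1")
  if (!is.numeric(signal_per_ug) || signal_per_ug <= 0)
    stop("`signal_per_ug` must be > 0")
  psf_sigma <- as.numeric(psf_sigma)
  if (length(psf_sigma) == 1L) psf_sigma <- rep(psf_sigma, 3L)
  if (length(psf_sigma) != 3L || any(psf_sigma < 0))
    stop("`psf_sigma` must be a non-negative scalar or length-3 vector")
  if (!is.null(noise_additive_sd) &&
      (!is.numeric(noise_additive_sd) || noise_additive_sd < 0))
    stop("`noise_additive_sd` must be >= 0 (or NULL for automatic)")
  if (!is.numeric(noise_multiplicative_cv) || noise_multiplicative_cv < 0)
    stop("`noise_multiplicative_cv` must be >= 0")
  if (inherits(sources, "iron_source")) sources <- list(sources)
  for (s in sources)
    if (!inherits(s, "iron_source")) stop("`sources` must be iron_source objects")
  structure(list(grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 signal_per_ug = signal_per_ug,
                 psf_sigma = psf_sigma,
                 noise_additive_sd = noise_additive_sd,
                 noise_multiplicative_cv = noise_multiplicative_cv,
                 rng_seed = as.integer(rng_seed),
                 sources = sources),
            class = "phantom_config")
}

## Unit-mass Gaussian blob on the voxel grid.  Per-axis weights are the
## integrals of a N(center, sigma) density over each voxel bin, so a blob
## whose support lies inside the grid sums to 1 up to the (negligible)
## truncated tails; at grid edges mass is simply lost, as a real
## reconstruction crops the field of view.
gaussian_blob <- function(dims, center, sigma) {
  w <- lapply(1:3, function(a) {
    i <- seq_len(dims[a])
    if (sigma[a] == 0) {
      as.numeric(i == max(1L, min(dims[a], round(center[a]))))
    } else {
      pnorm(i + 0.5, center[a], sigma[a]) - pnorm(i - 0.5, center[a], sigma[a])
    }
  })
  outer(outer(w[[1]], w[[2]]), w[[3]])
}

#' Render a synthetic MPI scan from a phantom configuration
#'
#' Deposits each source as a Gaussian blob with intensity integral
#' `signal_per_ug * iron_ug`, then applies multiplicative and additive
#' Gaussian noise and clips the result at zero.
#'
#' @param config A [phantom_config()].
#' @param meta Optional named list of metadata stored on the scan
#'   (e.g. subject id, timepoint label).
#' @return A list with components `scan` (a [scan_volume()]) and `truth`, a
#'   `ground_truth` object holding the noise-free volume, the per-source
#'   iron table and the total graft iron in µg.
#' @examples
#' cfg <- phantom_config(grid_shape = c(8, 16, 16), psf_sigma = 1,
#'                       noise_additive_sd = 0, noise_multiplicative_cv = 0,
#'                       sources = list(iron_source(c(4, 8, 8), 2)))
#' out <- render_scan(cfg)
#' sum(out$scan$voxels)  # ~ 2000 intensity units
#' @export
render_scan <- function(config, meta = list()) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  clean <- array(0, dims)
  fid_clean <- array(0, dims)
  for (i in seq_along(config$sources)) {
    src <- config$sources[[i]]
    if (any(src$center < 0.5) || any(src$center > dims + 0.5))
      stop(sprintf("source %d (%s, %.3g ug) lies outside the grid", i,
                   src$kind, src$iron_ug))
    blob <- gaussian_blob(dims, src$center, config$psf_sigma) *
      (config$signal_per_ug * src$iron_ug)
    clean <- clean + blob
    if (src$kind == "fiducial") fid_clean <- fid_clean + blob
  }
  sd_add <- config$noise_additive_sd
  if (is.null(sd_add)) {
    peak <- if (any(fid_clean > 0)) max(fid_clean) else max(clean, 0)
    sd_add <- 0.005 * peak
  }
  set.seed(config$rng_seed)
  n <- length(clean)
  noisy <- clean
  if (config$noise_multiplicative_cv > 0)
    noisy <- noisy * (1 + rnorm(n, 0, config$noise_multiplicative_cv))
  if (sd_add > 0)
    noisy <- noisy + rnorm(n, 0, sd_add)
  noisy[noisy < 0] <- 0
  noisy <- array(noisy, dims)

  iron <- vapply(config$sources, `[[`, numeric(1), "iron_ug")
  kind <- vapply(config$sources, `[[`, character(1), "kind")
  truth <- structure(list(
    sources = config$sources,
    per_source_iron_ug = iron,
    noise_free = clean,
    total_graft_iron_ug = sum(iron[kind == "graft"]),
    noise_additive_sd = sd_add), class = "ground_truth")
  list(scan = scan_volume(noisy, voxel_size = config$voxel_size, meta = meta),
       truth = truth)
}

#' Default fiducial marker layout for synthetic phantoms
#'
#' Three 1 µl fiducial markers at 10, 20 and 40% of a 5.5 mg/ml iron stock
#' (0.55, 1.1 and 2.2 µg iron), placed in a fixed column along one edge of
#' the volume at the mid slice — the placement is kept constant across scans
#' so the same fiducial specification applies to a whole series.
#'
#' @param grid_shape Voxel grid the positions are laid out for.
#' @param search_radius Matching radius (voxels) stored on each spec.
#' @return A list of three [fiducial_spec()] objects.
#' @export
standard_fiducials <- function(grid_shape = c(36L, 64L, 64L),
                               search_radius = 5) {
  z <- ceiling(grid_shape[1] / 2)
  ys <- round(grid_shape[2] * c(0.25, 0.5, 0.75))
  x <- max(8, round(grid_shape[3] * 0.15))
  fracs <- c(0.10, 0.20, 0.40)
  lapply(1:3, function(i)
    fiducial_spec(id = sprintf("fid%d0", c(1, 2, 4)[i]),
                  expected_center = c(z, ys[i], x),
                  concentration_fraction = fracs[i],
                  stock_iron_mg_per_ml = 5.5, volume_ul = 1,
                  search_radius = search_radius))
}

## Iron sources corresponding to a list of fiducial specs.
fiducial_sources <- function(specs) {
  lapply(specs, function(sp)
    iron_source(sp$expected_center, fiducial_iron_mass(sp), kind = "fiducial"))
}

## Default graft position: mid slice, centered in y, on the opposite side of
## the volume from the fiducial column.
default_graft_center <- function(grid_shape) {
  c(ceiling(grid_shape[1] / 2), round(grid_shape[2] / 2),
    round(grid_shape[3] * 0.7))
}

#' Generate the organoid-count dilution phantom series
#'
#' One scan per organoid count: a single graft source with iron
#' `count * iron_per_organoid_ug` plus the three standard fiducial markers.
#' Scan `i` uses seed `config$rng_seed + i - 1` so the series is
#' reproducible but scans are independent.
#'
#' @param counts Non-negative organoid counts, default the dilution series
#'   `c(0, 25, 50, 100, 200, 400)`.
#' @param iron_per_organoid_ug Iron load per organoid in µg.  This is a free
#'   parameter of the simulation (per-organoid loading is assay-dependent);
#'   default 0.01 µg.
#' @param config Base [phantom_config()]; its `sources` are replaced.
#' @param fiducials Fiducial specs giving positions and iron; default
#'   [standard_fiducials()] for the configured grid.
#' @param graft_center Voxel center of the graft blob.
#' @return A list with one `list(scan, truth, count)` element per count.
#' @export
make_phantom_series <- function(counts = c(0, 25, 50, 100, 200, 400),
                                iron_per_organoid_ug = 0.01,
                                config = phantom_config(),
                                fiducials = standard_fiducials(config$grid_shape),
                                graft_center = default_graft_center(config$grid_shape)) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("organoid `counts` must be non-negative")
  if (iron_per_organoid_ug < 0) stop("`iron_per_organoid_ug` must be >= 0")
  fid_src <- fiducial_sources(fiducials)
  lapply(seq_along(counts), function(i) {
    cfg <- config
    cfg$sources <- c(fid_src, list(
      iron_source(graft_center, counts[i] * iron_per_organoid_ug, "graft")))
    cfg$rng_seed <- config$rng_seed + i - 1L
    out <- render_scan(cfg, meta = list(subject = "phantom",
                                        organoid_count = counts[i]))
    out$count <- counts[i]
    out
  })
}

#' Generate a longitudinal series of graft scans
#'
#' One scan per imaging day with the graft iron set to the specified total
#' iron value.  The default trajectory rises from day 1 to day 7 and falls
#' by day 28, the qualitative pattern seen in longitudinal MPI of
#' transplanted grafts.
#'
#' @param day_tivs Named numeric vector mapping day to graft iron (µg),
#'   default `c("1" = 4, "7" = 5, "28" = 2)`.
#' @inheritParams make_phantom_series
#' @return A list with one `list(scan, truth, day)` element per day, ordered
#'   by day.
#' @export
make_longitudinal_series <- function(day_tivs = c("1" = 4, "7" = 5, "28" = 2),
                                     config = phantom_config(),
                                     fiducials = standard_fiducials(config$grid_shape),
                                     graft_center = default_graft_center(config$grid_shape)) {
  days <- as.numeric(names(day_tivs))
  if (any(is.na(days))) stop("`day_tivs` must be named by day")
  if (anyDuplicated(days)) stop("days must be distinct")
  if (any(!is.finite(day_tivs)) || any(day_tivs < 0))
    stop("ground-truth TIVs must be non-negative")
  ord <- order(days)
  fid_src <- fiducial_sources(fiducials)
  lapply(seq_along(ord), function(j) {
    i <- ord[j]
    cfg <- config
    cfg$sources <- c(fid_src, list(
      iron_source(graft_center, unname(day_tivs[i]), "graft")))
    cfg$rng_seed <- config$rng_seed + i - 1L
    out <- render_scan(cfg, meta = list(subject = "longitudinal",
                                        day = days[i]))
    out$day <- days[i]
    out
  })
}
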