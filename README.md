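# mpiquant

Quantification of superparamagnetic iron oxide tracer in 3D magnetic
particle imaging (MPI) scans of labeled cell grafts.

MPI detects SPION tracers directly — no tissue background, signal linear
in iron mass — which makes it well suited to tracking transplanted,
tracer-labeled cells (such as stem-cell-derived islet organoids) over
weeks. The quantitative readout is the **total iron value (TIV, µg)** of
the graft region. `mpiquant` computes it with an automated pipeline:

1. **Layer-by-layer segmentation** — each slice of the volume (typically
   32–36 layers per scan) is clustered on pixel intensity with a
   from-scratch **k-means++** implementation (default *k* = 4:
   background plus three signal tiers); the region of interest is built
   from the signal clusters, with a robust background noise floor and
   hysteresis-style mask growth so every source is captured down to the
   same intensity floor.
2. **Fiducial separation** — connected components of the 3D mask are
   matched spatially against **fiducial markers**, reference tubes of
   known iron content (1 µl at 10/20/40% of a 5.5 mg/ml iron stock =
   0.55/1.1/2.2 µg) kept at fixed scanner-bed positions.
3. **Calibration and TIV estimation** — the fiducial pixel sums and known
   masses define a linear **standard curve** (through the origin by
   default), per-slice graft pixel sums are mapped through it, and the
   per-slice TIVs are summed over the 3D structure:

   `TIV = Σ_z slope · S_z`, with `slope` from OLS of iron (µg) on
   fiducial pixel sum. A single-fiducial **ratio method**
   (`TIV = S_graft / S_fid × m_fid`) mirrors the manual-rater workflow.
4. **Validation statistics** — two-way absolute-agreement intraclass
   correlation, ICC(A,1)/ICC(A,k) with 95% CIs and the F test, for
   algorithm-versus-rater comparison, plus linear regression with R² for
   phantom linearity.

A synthetic phantom generator provides MPI-like volumes with known
ground-truth iron (Gaussian-blurred point sources on a 36×64×64 grid,
linear gain, additive + multiplicative noise), so the whole pipeline is
testable end to end without scanner data: the organoid dilution series
(0, 25, 50, 100, 200, 400 labeled organoids) and a longitudinal
rise-then-fall TIV trajectory are built in.

Supported formats: NIfTI-1 (reference, lossless), multi-page TIFF (+ JSON
sidecar), minimal read-only DICOM series; fiducial specs as JSON/CSV;
reports as JSON + CSV + mask volumes.

## Worked example

Simulate one phantom with 200 labeled organoids (0.01 µg iron each, so
2 µg ground truth) plus the three standard fiducials, and quantify it:

```r
library(mpiquant)

cfg    <- phantom_config(rng_seed = 42L)
fids   <- standard_fiducials(cfg$grid_shape)
scan   <- make_phantom_series(counts = 200, config = cfg,
                              fiducials = fids)[[1]]
quantify_scan(scan$scan, fids, seed = 42)
```

```
MPI quantification
standard curve (origin mode, 3 points):
  iron_ug = 0.00108129 * pixel_sum +0   (R^2 = 0.997899)
TIV estimate (standard_curve): total 1.99771 ug iron
  5 of 36 slices carry graft signal
  graft components: 1; fiducials matched: 3
```

The curve slope says one intensity-sum unit corresponds to ~0.00108 µg
iron in this scan; the graft's per-slice sums map through it to a total
of 1.998 µg — within 0.2% of the 2 µg ground truth despite the noise.

Comparing two raters' TIVs (here a 6×2 matrix) gives the agreement
statistics:

```r
m <- matrix(c(4.1, 4.3, 5.0, 4.6, 2.2, 2.9,
              7.7, 7.1, 6.5, 6.9, 3.3, 3.0), ncol = 2, byrow = TRUE)
icc_absolute_agreement(m)
```

```
Intraclass correlation (two-way, absolute agreement), n = 6, k = 2
  single measures  ICC(A,1) = 0.971  95% CI [0.807, 0.996]
  average measures ICC(A,2) = 0.985  95% CI [0.893, 0.998]
  F(5, 5) = 56.97, p = 0.0002084
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/mpiquant.R simulate phantom-series --seed 42 --out-dir sim/
Rscript inst/cli/mpiquant.R quantify --input sim/count200.nii.gz \
    --fiducials sim/fiducials.json --seed 42 --out report
Rscript inst/cli/mpiquant.R validate-icc --ratings ratings.csv --out icc.json
```

See `vignettes/mpi-quantification.Rmd` for the model, the parameter
choices and their rationale, and known limitations.

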