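# tpstereo

Two-photon laser scanning **stereomicroscopy**, as software: simulate
extended-depth-of-field (EDF) two-photon imaging with tilted Bessel–Gauss
beams, and recover per-object depth from the resulting stereo image pairs.

## The problem

A Bessel–Gauss beam (generated by an axicon, appearing as an annulus at the
objective's back focal plane, BFP) has a focal line hundreds of micrometres
long.  Scanning it through a specimen gives a single 2D image in which the
whole depth range is simultaneously in focus — fast volumetric imaging, but
the depth coordinate is integrated away.  Laterally shifting the annulus at
the BFP tilts the focal line by `theta = asin(shift / n)`; scanning every
line twice with two opposite tilts (`±alpha/2`) yields an interlaced raw
frame whose odd/even lines form a left/right stereo pair.  Depth is then
encoded as **disparity**:

```
disparity_px = 2 z tan(alpha/2) / pixel_size        (triangulation)
dz           = dx / sin(alpha)                      (axial resolution)
```

With a measured lateral resolution dx ≈ 0.77 µm and a parallax
alpha ≈ 2.5°, the axial resolution is ≈ 17.6 µm — coarse, but objects that
are *recognisable features* can be localised axially far better than dz by
a correspondence algorithm.

For sparse circular objects (fluorescent beads), each view is preprocessed
(frequency-domain low-pass, Richardson–Lucy deconvolution), circles are
found with a circular Hough transform, and left/right features are matched
by minimising the cost

```
Delta = dE + dy − S
```

where `dE` is the normalised energy difference, `dy` the normalised
vertical (epipolar) offset, and `S` the detector's circle metric of the
candidate.  Matched disparities are triangulated to depth.

The package contains seven modules: `optics` (scalar angular-spectrum
simulation of annular pupils and tilted focal volumes), `scangeom` (scanner
waveforms, volume-rate timing, triangulation geometry), `simcore`
(synthetic bead phantoms and the EDF forward model, with ground truth),
`stereoio` (deinterlacing, side-by-side and red/cyan anaglyph export),
`depthrecon` (the reconstruction pipeline above plus accuracy statistics),
`tracking` (nearest-neighbour 3D track linking) and a CLI
(`inst/cli/tpstereo.R`).  Images travel as multi-page TIFF, tables as CSV,
configuration and stats as JSON — all written by in-package codecs (the
target environment has no R imaging package).

## Worked example

```r
library(tpstereo)

cfg <- default_run_config()
cfg$frame$n_fast <- 256L; cfg$frame$m_slow <- 256L    # 65 x 65 um field
cfg$phantom$n_beads <- 25L
cfg$phantom$extent  <- c(58, 58, 80)                  # z in [-40, 40] um

sim <- run_simulate(cfg, "demo", seed = 1)            # raw.tif + truth.csv
res <- run_reconstruct(file.path("demo", "raw.tif"), cfg, "demo_rec")
frame <- do.call(frame_geometry, cfg$frame)
dep <- assign_truth_ids(res$depths, sim$truth, frame)
st  <- run_evaluate(dep, sim$truth, thresholds = c(2, 5))
```

Output (log lines to stderr):

```
[tpstereo] simulate: 25 beads placed (0.01 s)
[tpstereo] simulate: wrote demo/raw.tif (0.12 s)
[tpstereo] reconstruct: 25 left / 25 right features, 25 matches (2.07 s)
[tpstereo] evaluate: 25/25 matched, RMSE 0.16 um
```

All 25 beads are detected in both views, matched, and triangulated; every
recovered depth is within 2 µm of ground truth (`st$fraction_within` is
1.0 at both the 2 µm and 5 µm thresholds) and the depth RMSE is 0.16 µm —
two orders of magnitude below the dz ≈ 17.6 µm resolution bound, because
bead centres are localised to sub-pixel precision.  `demo_rec/` also holds
the red/cyan anaglyph (`anaglyph.png`) and per-stage CSV tables.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/tpstereo.R simulate    --seed 1 --out demo
Rscript inst/cli/tpstereo.R reconstruct --in demo/raw.tif --out demo_rec
Rscript inst/cli/tpstereo.R evaluate    --pred demo_rec/depths.csv \
                                        --truth demo/truth.csv --out demo_rec
```

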