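---
title: "Models and methods in tpstereo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tpstereo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tpstereo)
```

This vignette documents the models behind `tpstereo`, the calibration and
numerical choices that are genuinely open, and what the synthetic tests do
and do not establish.  All lengths are micrometres, angles degrees.

## 1. The optical model

### Scalar angular-spectrum propagation

The excitation path is simulated with scalar diffraction.  A pupil field
is defined on a grid of NA coordinates `nu = n sin(theta)` and propagated
plane by plane:

```
E(x, y, z) = IFFT2[ P(nu_x, nu_y) · exp(i k_z z) ],
k_z = (2*pi/lambda) * sqrt(n^2 - nu_x^2 - nu_y^2),
```

with evanescent components (`nu >= n`) removed (a band-limited angular
spectrum).  The two-photon excitation PSF is the squared, peak-normalised
intensity, `PSF2p = (I/I_max)^2`.  No aplanatic apodization is applied by
default (`apodization = "none"`); the propagator is then exactly the
scalar diffraction of the aperture field.  An optional `"sine"` weighting
(`sqrt(cos theta)`) is provided, but the two conventions differ by under
2% in the focal FWHM at NA 1.0, which is inside every tolerance used here.
Polarisation (vector Debye–Wolf) effects are out of scope.

Sampling is set by the pupil grid: the focal-plane pixel is
`dx = lambda / (2 * na_halfspan)` regardless of `grid_n`, and `grid_n`
sets the field of view.  Gaussian-focus FWHM runs use `dx = 50 nm`
(`na_halfspan = 7.8`); Bessel-volume runs use coarser lateral sampling,
which is adequate because the Bessel core is ~0.65 µm wide.  Per-plane
energy is conserved exactly (Parseval), which the tests assert.

### The annulus and its calibration

The axicon-generated ring at the BFP is modelled as a Gaussian-profile
annulus, amplitude `exp(-((nu - nu0)/w)^2)`.  Neither the ring diameter
nor its width is a measured quantity available to the package, so both
are **calibrated to the two printed anchors** instead:

* `annulus_na` (`nu0` ≈ 0.311): chosen so the ideal Bessel two-photon
  profile `J0(k_r r)^4` has a lateral FWHM of 0.65 µm.  The half-maximum
  argument solves `J0(x*) = 2^(-1/4)` (`x*` ≈ 0.8145, by root-finding),
  giving `FWHM = 2 x* lambda / (2 pi nu0)`.
* `annulus_width_na` (`w` ≈ 0.0054): chosen so the on-axis two-photon
  axial FWHM is 160 µm.  Linearising `k_z` across the narrow ring gives a
  Gaussian axial envelope with `FWHM_z = 2 sqrt(ln 2) / (D w)`,
  `D = (2 pi/lambda) nu0 / sqrt(n^2 - nu0^2)`; the closed form is
  inverted for `w` and the full numerical profile is then checked against
  the 160 µm target (within 10%) in the acceptance suite.  This is a
  *consistency check of the calibration*, not an independent prediction.

This is one self-consistent choice, not a measurement; any (`nu0`, `w`)
pair reproducing both anchors would serve.

### Tilt: rotation, not translation

A beam tilt by `theta = asin(shift/n)` is implemented as a **rotation of
the angular spectrum on the k-sphere**, whose ring-centre displacement at
the BFP equals `n sin(theta) = shift`.  A rigid in-plane translation of
the ring — the obvious alternative — is *not* a tilted Bessel beam: its
energy-weighted walk-off is faster than `tan(theta)` by roughly
`1 + nu0^2 / (2 k_z0^2)` (≈ 3% here), because the ring must deform as it
tilts.  With the rotation model the per-plane intensity centroid of the
simulated volume tracks `tan(theta)` to better than 1% inside the Bessel
zone, which is what the galvo-driven tilt of the physical instrument does.
The centroid fit is restricted to the Bessel zone: beyond it the beam
opens into a conical shell and a cropped centroid is meaningless.

### Rounded axicon tip

Real axicons have a rounded apex; light crossing it is essentially
undeviated and interferes with the conical wave, producing the
characteristic on-axis intensity oscillation.  The optional `rounded_tip`
pupil mode adds an on-axis Gaussian leakage term (relative amplitude 0.15,
width `nu0/4` by default) to the annulus; the ideal annulus gives a smooth
axial envelope (≤ 1 local maximum), the rounded-tip model ≥ 3 maxima.
This is a deliberately minimal surrogate, not a surface-metrology model.

## 2. Scanner geometry and timing

Each slow-axis position is scanned twice — once per view — so a frame of
`M` lines contains `2M` scanned lines interlaced `L,R,L,R...`.  The
volume rate is

```
VPS = pair_rate / M,   pair_rate = 1 / (2 t_line + dt1 + dt2).
```

`pair_rate` cannot be derived from the published hardware description
(flyback fractions are unstated), so it is a **calibrated configuration
value**: 716.8 pairs/s reproduces the 1.4 volumes/s full-frame (512-line)
operating point, and then 512×128 frames give exactly 5.6 VPS since
`VPS · M` is constant.  Waveform amplitudes are normalised scan angles;
the volts-per-degree mapping is hardware-specific and out of scope.

The parallax `alpha` is defined as the **full** inter-beam angle, beams at
`±alpha/2`.  This makes the axial-resolution formula `dz = dx/sin(alpha)`
and the triangulation `z = d·p / (2 tan(alpha/2))` mutually consistent
(at 2.5° the two denominators differ by < 0.1%).  Whether a printed tilt
of "≈ 2.5°" means the per-beam or full angle is ambiguous in the source
material; the full-angle convention is adopted because it reproduces the
≈ 17 µm axial-resolution figure with dx = 0.77 µm.

## 3. The synthetic-data engine

Phantoms emulate slides of mixed 1 µm and 6 µm fluorescent beads: radii
{0.5, 3.0} µm with equal probability, uniform positions over a
130 × 130 × 90 µm volume (the full-frame field of view at 0.254 µm/px),
uniform dye density (brightness proportional to path length through the
sphere).  The minimum pairwise separation (default 5 µm) is enforced on
the **lateral (xy)** distance, not the 3D distance: the EDF projection
collapses z entirely, so only lateral overlap degrades the images, and a
3D criterion would still allow exact lateral coincidence.

The forward model is a **shear projection**: a bead at depth `z` appears
in the left/right view displaced by `± z tan(alpha/2)`, drawn as a
projected solid sphere (analytic chord length per pixel) and convolved
with the lateral two-photon kernel (`J0^4`, truncated at the third zero
of `J0`).  The Bessel axial envelope is treated as flat because its
160 µm FWHM exceeds the 90 µm depth range; axial intensity falloff,
scattering, bleaching and scan-motion distortion of moving samples are
not modelled.  Noise is Poisson only, parameterised by the expected
photon count at the image peak.  A conventional ground-truth z-stack is
rendered by slab-integrating each bead's chord per plane, which makes the
stack's z-sum equal the untilted EDF projection exactly — a property the
tests exploit.

Consequently, a green synthetic test establishes that the *algorithms*
are correct and self-consistent under this stated world; it does not
reproduce the published physical-sample statistics (87 objects, 70%/93%
error fractions, sigma = 2.82 µm), which depend on a particular slide and
are treated as non-reproducible at desk scale.

## 4. Depth reconstruction

Preprocessing follows low-pass → Richardson–Lucy.  The low-pass is a
circular raised-cosine in the frequency domain (cutoff 0.25 cycles/px,
roll-off 0.05; a cutoff ≥ 0.5 disables it).  RL runs 10 multiplicative
iterations with the rendering kernel; both counts are exposed in the
configuration because the source pipeline does not state them.

**Detection.** Gradient-voting circular Hough over radii 1.5–15 px (step
0.5), covering both bead classes at 0.254 µm/px.  The accumulator only
nominates candidates; the circle metric `S` is the **perimeter
coverage** — the fraction of perimeter directions with an inward-pointing
edge pixel (checked at `r` and `r ± 0.5`).  A raw vote count normalised
by `2 pi r` was tried first and discarded: along the extended edges of
large deconvolved objects it saturates at small radii and floods the
detector with false candidates, whereas arc-shaped support covers only a
small angular fraction and scores low.  Non-maximum suppression ranks by
total perimeter evidence `r·S`, so the object-scale circle beats the
small concentric ring artifacts RL deconvolution creates inside large
beads.  Centres are refined by a background-subtracted intensity centroid
restricted to pixels nearest this detection (Voronoi restriction limits
bias from overlapping neighbours); radii are refined to the
gradient-magnitude ridge.  The right view uses 0.8× the left sensitivity,
implementing the deliberately looser right-image threshold.

**Matching.** Cost `Delta = dE + dy − S` with the package's
normalisations (the source states only "normalised"):
`dE = |E_L − E_R| / max(E_L, E_R)` and `dy = |y_L − y_R| / w_epi`, both
in [0, 1] and hence commensurate with `S`; `S` is the right candidate's
metric.  Candidates are gated by `|dy_raw| ≤ 3 px` and
`|dx| ≤ 10 px`.  The disparity gate is set from the instrument, not
tuned: the 90 µm depth range bounds |disparity| by 7.7 px, plus margin.
A wider gate admits geometrically impossible partners, and because beads
of one size class have near-identical energies, `dE` cannot veto them —
the `−S` term can then override geometry.  One-to-one matching is greedy
in ascending cost (the source specifies per-feature minimisation only); a
`method = "global"` exact assignment (branch-and-bound, maximum
cardinality then minimum total cost) is provided and is tested against a
plain exhaustive oracle.  Unmatched features are reported as unmatched,
never imputed.

**Evaluation.** Absolute-error fractions at configurable thresholds, and
a Gaussian sigma obtained by least-squares fit of a normal density to the
signed-error histogram (1 µm bins).  With fewer than 3 matched objects
sigma is undefined; on a degenerate (zero-residual) fit the estimate is
kept and its standard error reported as `NA`.  Ties in the z-stack
depth search resolve to the lower z; parabolic sub-plane refinement is
optional.

## 5. Tracking

Frame-to-frame linking is greedy nearest-neighbour in 3D with a hard
displacement gate; unlinked detections start new tracks.  This replaces a
full tracking suite deliberately: for sparse beads with sub-gate motion
the greedy solution equals the optimal assignment, and gap closing,
merging and motion models are out of scope.

## 6. Numerical conventions and degenerate inputs

* FFT convolutions are circular; images are assumed dark at their
  borders (true for the rendered scenes).
* `measure_fwhm` interpolates the half-maximum crossings linearly and
  refuses profiles whose maximum sits at an endpoint or that never cross
  half-maximum.
* The FFT grid axis `(-N/2 ... N/2-1)·d` has no mirror partner for its
  first sample; symmetry checks must exclude it.
* Empty phantoms, blank frames, empty feature lists and empty candidate
  sets all propagate as empty results with headers, not errors.
* Raw frames are quantised to 16-bit on write (relative error ≤ 2/65535).
* TIFF/PNG are written by in-package codecs (uncompressed baseline TIFF;
  PNG via R's zlib).  This is an environment-driven necessity; outputs
  were validated against independent readers during development.

## 7. Known limitations

* Scalar optics only; no aberrations, no vectorial effects, no
  fluorescence collection path.
* The annulus geometry is calibrated, not measured (Section 1); all
  derived quantities inherit that choice.
* The forward model's flat axial envelope slightly overstates contrast
  for objects near the depth-range edges.
* Energy-based correspondence cannot separate same-class beads that are
  simultaneously within the epipolar window and the disparity gate of
  each other; such configurations are rare under the default separation
  but produce outlier depths when they occur.
* The greedy matcher is order-dependent under exact cost ties.
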