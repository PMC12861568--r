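---
title: "Quantitative virtual histology by simulated phase-contrast tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative virtual histology by simulated phase-contrast tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement this package simulates

Propagation-based x-ray phase-contrast tomography (XPCT) images unstained,
paraffin-embedded tissue through the phase shift the specimen imprints on a
coherent hard x-ray beam. The refractive index at these energies is
$n = 1 - \delta + i\beta$ with

$$\delta = \frac{r_e \lambda^2}{2\pi}\,\rho_e,$$

so the reconstructed $\delta$ volume is, up to a known constant, a map of
electron density $\rho_e$ (e/nm^3^) — and for soft tissue electron density
is in good approximation proportional to mass density. After free-space
propagation over an effective distance $z$, the detector records Fresnel
diffraction patterns ("holograms"); in the holographic regime the Fresnel
number $F = \mathrm{px}^2/(\lambda z)$ is far below 1. Phase retrieval
inverts the contrast transfer function (CTF), tomographic reconstruction
turns the retrieved projections into a 3D $\delta$ volume, and the uniform
paraffin matrix around the tissue provides an absolute anchor: its
electron density, 328 e/nm^3^ for CH~2~ paraffin at 0.9554 g/cm^3^
(`electron_density_formula()`), calibrates the otherwise offset-ambiguous
density scale.

`xpct` implements the full chain as a simulation-plus-analysis pipeline:

1. **Phantom synthesis** (`make_phantom()`) — 3D electron-density volumes
   of neuropathological inclusions with exact per-compartment ground truth.
2. **Forward optics** (`acquire()`) — projection, Fresnel propagation at up
   to four distances, detector gain, Poisson noise, flat/dark frames.
3. **Phase retrieval** (`retrieve_phase()`, `ctf_retrieve()`,
   `paganin_retrieve()`, `nlt_refine()`).
4. **Reconstruction** (`reconstruct_tomogram()`, `fbp()`) with rotation-axis
   correction, ring suppression, and 360°→180° folding.
5. **Densitometry** (`delta_to_rho()`, `calibrate()`, `roi_stats()`).
6. **Statistics** (`mann_whitney_u()`, `bonferroni_adjust()`,
   `density_report()`), plus watershed/threshold segmentation.

```{r}
library(xpct)
cfg <- default_run_config(seed = 1, outdir = "run1")
manifest <- run_pipeline(cfg)
```

## The phantom and its default densities

The default scene (`default_run_config()`) is a 160^3^ volume at 100 nm
voxels — a desk-scale stand-in for a 1 mm tissue punch imaged at the
90–140 nm effective pixel sizes of zoom holotomography. It contains one
large neuron soma (cytoplasm, nucleus, nucleolus) hosting a Lewy body
(dense core, fainter halo, six hypodense rim inclusions), 18
granulovacuolar-degeneration (GvD) vacuoles with central dense grains, a
neuromelanin granule cluster, and a rod-shaped Hirano body that pierces the
soma boundary; outside the soma sit a cored amyloid plaque and a vessel
segment. Structure sizes are scaled down relative to human pathology so
that all of them fit a single desk-scale volume; their *relative* geometry
(concentric Lewy-body shells, grains inside vacuoles, the Hirano body
protruding beyond the cell border) follows the histological descriptions.

Only two densities are anchored to published values: the paraffin
background (328 e/nm^3^) and the neuronal cytoplasm (paraffin + 4 e/nm^3^,
the reported mean somatic elevation). All other defaults are placeholders
chosen to reproduce the qualitative ordering reported for these
inclusions — Hirano body highest, then neuromelanin, Lewy-body core,
Lewy-body halo, cytoplasm, plaque shell, and GvD lumen at the paraffin
level (the vacuolar space is nearly protein-free). They are user-settable
per structure and are *not* measured values.

GvD vacuoles default to flat paraffin-density lumens. The observed
radially increasing density toward the central grain is available as
`gvd(gradient = TRUE)`, which interpolates linearly from the lumen wall to
the grain surface.

## Forward model choices

**Background referencing.** Contrast in paraffin-embedded tissue is
generated by the difference with respect to the embedding matrix, so the
forward model subtracts the paraffin density before projecting; retrieved
phase and reconstructed $\delta$ are therefore *relative* to paraffin, and
`calibrate()` restores the absolute scale by a single offset. The
multiplicative scale needs no fitting — it is fixed by $r_e$, $\lambda$
and the voxel size.

**Geometry.** All stages work in the equivalent parallel-beam geometry;
cone-beam (zoom) configurations are mapped onto it with the Fresnel scaling
theorem (`cone_to_parallel()`), the standard reduction for small cone
angles over a 1 mm specimen. Projection rotates the volume about the
vertical axis with bilinear interpolation.

**Conventions.** The transmission function is $T = e^{-B + i\varphi}$ with
$\varphi = (2\pi/\lambda)\int\delta\,dz \ge 0$ for matter denser than the
reference and $B = \varphi/\kappa$ under the homogeneous-object assumption
($\kappa = \delta/\beta$, default 500 at 17.1 keV — the ratio is not pinned
by measurement here and is configurable). With the propagator convention
used by `fresnel_propagate()` the weak-contrast hologram spectrum is
$\widehat{I-1} = -2(\sin\chi + \cos\chi/\kappa)\hat\varphi$ with
$\chi = \pi\lambda z|\nu|^2$; the CTF estimator and the Paganin filter
carry the matching signs so that dense-over-paraffin objects retrieve
positive phase. Propagation replicate-pads to twice the frame to suppress
wrap-around (`pad = "none"` is available and makes pure-phase propagation
exactly unitary).

**Detector margin.** The simulated detector is wider than the specimen
(`fov_margin`, default 64 px on each side). This mirrors the real
experiment — the field of view exceeds the punch — and matters numerically:
Fresnel fringes that leave the specimen frame stay on the detector, and the
margin provides known-empty paraffin pixels that anchor the retrieval
background (below). With a tight frame, fringe truncation corrupts the
border and biases every interior density.

**Noise.** Default 5000 photons/pixel Poisson noise per projection and
distance, a random second-order polynomial detector gain within ±5%
(separate per distance), dark counts, and 16 flat/dark frames per distance.
`flatfield_correct()` applies the usual (raw − dark)/(flat − dark)
normalization.

**Distances.** Four effective distances, 8–56 mm by default
($F \approx 0.017$–0.0025 at 17.1 keV and 100 nm pixels), chosen so the
zero crossings of the four CTFs interleave (the combined response
$\sum_j s_j^2$ stays well above zero across the band) and deliberately
split into two short and two long ones: contrast at a spatial frequency
$\nu$ scales as $\sin(\pi\lambda z\nu^2)$, so the long distances carry the
low and intermediate frequencies — which dominate per-region mean densities
and would otherwise be the noisiest part of the retrieval at a finite
photon budget — while the short distances carry the band up to Nyquist.
Longer distances spread fringes further across the detector; the default
margin keeps the resulting loss negligible at the frequencies each
distance is responsible for.

## Phase retrieval

`ctf_retrieve()` implements the linearized multi-distance estimator

$$\hat\varphi(\nu) = \frac{\sum_j s_j(\nu)\,\widehat{1 - I_j}(\nu)}
 {2\sum_j s_j(\nu)^2 + \alpha(\nu)},\qquad
 s_j = \sin\chi_j + \tfrac{1}{\kappa}\cos\chi_j,$$

with a two-band Tikhonov weight $\alpha(\nu)$ (defaults
$\alpha_\text{low} = 10^{-5}$ below the first CTF maximum of the shortest
distance, $\alpha_\text{high} = 10^{-1}$ above, logistic blend). The low
band is nearly in-band for four-distance data, so $\alpha_\text{low}$ is
kept small; the high band damps noise at CTF minima. The DC component of
the phase is unconstrained by the CTF; standalone `ctf_retrieve()` pins it
by zeroing the mean over the outermost 5 % border frame, and the pipeline
(`retrieve_phase()`) additionally fits and subtracts a first-order 2D
polynomial over the outer half of the known-paraffin detector margin
(`flatten_phase()`). This removes the per-projection offset and tilt in
which low-frequency retrieval noise accumulates, without the extrapolation
instability a higher-order fit on an outer band would have; whatever smooth
background survives is absorbed by the paraffin calibration downstream.

`paganin_retrieve()` is the single-distance homogeneous-object filter
$\varphi = -(\kappa/2)\ln(\mathcal{F}^{-1}[\widehat I/(1 + \pi\lambda z
\kappa|\nu|^2)])$, exact for a pure absorber at $z = 0$ and consistent with
the CTF estimator at small $\chi$. `nlt_refine()` polishes any initial
phase against the full nonlinear propagation model by gradient descent with
backtracking on
$\sum_j \||P_{z_j} e^{(i - 1/\kappa)\varphi}|^2 - I_j\|^2 +
\alpha\|\varphi\|^2$; its propagation is periodic (no padding) so the
analytic gradient is the exact adjoint, and the loss trace is
non-increasing by construction.

## Reconstruction

Rotation-axis correction cross-correlates the 0° projection with the
mirrored 180° one (the specific algorithm used at beamlines varies; this is
a documented stand-in). Three robustness choices: the correlation runs on
smoothed detector-column profile *gradients*, which localize far more
sharply than the smooth projections; the pipeline feeds it the
half-turn-averaged, ring-corrected projections, suppressing per-projection
noise by averaging ~90 frames; and the estimate is applied only when the
correlation peak is clearly localized (prominence gate) — at the default
photon budget a flat-topped correlation cannot pin the axis below ~1 px,
and applying such an estimate would do more harm than assuming the
geometry, so the finder warns and returns 0 instead. Ring suppression
(`remove_rings()`) removes the angle-invariant sinogram component: outlier
detector columns are flagged by a moving-median comparison and replaced
before a local quartic (Savitzky-Golay, width 11 px) background fit, so
genuine object structure — including its extrema — stays untouched (the
operation is a near-identity on ring-free data) while the narrow
fixed-pattern residual is subtracted from every projection. This is the
post-hoc counterpart of the random-displacement acquisition trick used at
the beamline. 360° scans are folded onto 180° (`fold_360()`); with the default
181 angles no exact opposite partners exist, so each projection is averaged
with the linear interpolation of its two bracketing partners.

`fbp()` is standard parallel-beam filtered back projection with Ram-Lak,
Shepp-Logan or Hann filters. The Ram-Lak response is generated from the
band-limited ramp's impulse response (1/4 at lag 0, $-1/(\pi n)^2$ at odd
lags) rather than by sampling $|\nu|$, which would otherwise bias the DC
level; with this choice a noiseless analytic ball reconstructs with
interior error below 2%. Output is scaled so that forward projection of
the tomogram reproduces the input phase, giving per-voxel $\delta$.

## Calibration and quantification

`calibrate()` adds the constant that makes the median reconstructed density
over a known paraffin mask equal the reference (offset-only; the median is
robust to residual rings). The pipeline's paraffin mask is the label-0
background eroded by 2 voxels and restricted to the tomographically
well-sampled inscribed cylinder. `roi_stats()` erodes each compartment
label by 1 voxel (partial-volume guard), then reports n, mean, median, sd,
quartiles and Tukey 1.5·IQR whiskers ("whisker range" is not defined in the
source literature; Tukey's rule is the documented assumption), absolute and
relative to paraffin. `density_report()` runs all pairwise Mann-Whitney U
tests with Bonferroni correction over the performed pairs and draws the
box-plot panel.

The Mann-Whitney implementation computes U from midranks; for
$n_1 + n_2 \le 16$ the two-sided p-value is exact by full enumeration of
all $\binom{n_1+n_2}{n_1}$ assignments (doubling the smaller tail, capped
at 1), beyond that a tie- and continuity-corrected normal approximation is
used. The cut-off keeps the largest enumeration at 12,870 splits.

## Segmentation

`threshold_segment()` offers global Otsu or fixed thresholds with
26-connected component labelling and a minimum-size filter.
`seeded_watershed_3d()` smooths with a Gaussian ($\sigma = 1$ voxel, to
stabilize seeds on noisy reconstructions), finds seeds as h-maxima via
grayscale reconstruction by dilation, and floods the inverted intensity
with a priority queue; raising the prominence h can only merge seeds, so
the label count is monotone non-increasing in h.

## What the simulation does and does not capture

The generator emulates the *contrast mechanism* (electron-density
differences against paraffin), the acquisition geometry (multi-distance
holography, 360° parallel-beam scan), detector gain and shot noise, and
morphologically faithful — but geometrically simplified and size-scaled —
inclusions with exact ground truth. It does not model partial coherence,
detector point-spread, wavefront aberrations, beam drift, anatomically
realistic neuropil texture, myelin, or vascular trees. Passing tests
therefore demonstrate that the *processing chain* recovers calibrated
densities under realistic counting statistics, not that any particular
biological density value is correct; on real data the unstated
instrumental effects add further blur and structured background.

Desk-scale problem sizes are used throughout (160^3^ phantom, 181 angles,
4 distances, ~3 min end to end on one CPU; oracle tests use 64^3^
volumes and up to 400 angles), standing in for the 2000–3000 projections
and larger grids of the beamline experiments.

## Numerical and design notes

- Frequencies are cycles/nm on the centred FFT grid of the effective pixel;
  all lengths are nm, all angles degrees in user-facing interfaces.
- Rotation centre is voxel-centre $(n-1)/2$ (0-based) about the vertical
  axis in projection, folding and back projection alike; the 180°
  projection is the exact mirror of the 0° one.
- The axis-offset sign convention is fixed by the round trip: correcting a
  sinogram with `shift_columns(., -offset)` re-centres it; a test enforces
  this end to end.
- Overlap policy in phantoms: later structures overwrite earlier ones,
  except nuclear compartments, which are protected; structure order is the
  configuration order, and each structure draws from its own seed
  substream, so phantoms are bit-reproducible.
- GvD vacuole placement uses rejection sampling with greedy restarts; a
  configuration whose vacuoles cannot be placed without overlap is an
  error, not a silent degradation.
- Volumes persist as 32-bit multi-page TIFF scaled to [0, 1] with the
  affine transform in a JSON sidecar (round-trip exact to range/2^32^);
  label volumes, truth tables and ROI statistics travel as CSV; manifests
  record md5 checksums per artifact, so re-running a stage on tampered
  inputs fails loudly.

## Known limitations

- The CTF estimator is linearized; objects with phase excursions well
  beyond ~1 rad need the NLT refinement, and no phase unwrapping is
  provided (contrast is kept weak by design).
- Single-distance pure-phase CTF is ill-conditioned at its zero crossings;
  the implementation warns and relies on regularization.
- FDK cone-beam reconstruction is intentionally absent — cone data are
  handled through the Fresnel scaling equivalence, valid for small cone
  angles.
- Extended-FOV stitching of multi-distance scans, iterative reconstruction
  and learned segmentation are out of scope.
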