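---
title: "Methods: multimodal scanning X-ray imaging and tomography with scanxray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal scanning X-ray imaging and tomography with scanxray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanxray)
```

## The measurement

In a scanning X-ray microprobe a focused beam is raster-scanned across the
sample while a fast 2D detector records the transmitted beam for every scan
pixel and energy-dispersive detectors record a fluorescence spectrum. One
acquisition therefore yields, simultaneously:

* **absorption contrast** — the integrated transmitted intensity,
* **differential phase contrast (DPC)** — the refraction angle of the beam,
  measured as the displacement of the beam centroid on the detector,
* **dark field** — the intensity scattered outside the direct-beam footprint,
  sensitive to density fluctuations below the beam size,
* **elemental maps** — areas of characteristic fluorescence peaks.

The raw container is a hierarchical (HDF5, NeXus-style) file holding a 4D
transmission-frame matrix (two scan dimensions plus two detector
dimensions), one 3D spectrum matrix per fluorescence detector, and 2D
encoder-position and monitor matrices. `scanxray` implements the full chain
from streamed readout of that container to phase maps and tomograms, and
ships a synthetic forward model so that every stage can be validated against
known ground truth.

## Streamed readout

Raw scans are far larger than the maps derived from them, so the reader
never materialises a full dataset: a *plan* of hyperslab read requests is
built first (`plan_requests()`, default block = one scan line, the size of
the first scan dimension), then `iterate_blocks()` serves the blocks in
acquisition order while prefetching at most one request ahead. The
observable contract — order, exactly-once partition of the selection, and
peak residency bounded by two blocks — is what the tests pin down; the
prefetch mechanism behind it is an implementation detail. A `low_res` plan
takes every second pixel in both scan dimensions for quick overviews, and
rectangular exclusion masks drop uninteresting regions from the plan
entirely. Failures are per-request: the error carries the failing request,
and blocks already delivered stay valid.

Dataset discovery is by array rank and shape consistency, not by group
names, so containers from other facilities load as long as they follow the
4D/3D/2D pattern; an explicit `scan_layout()` overrides discovery. Files
written from R keep R's column-major dimension order; containers written by
C-order tools appear axis-reversed and need the explicit layout.

## Pre-treatment

* **Beam ROI** (`auto_roi()`): a uniform 10% subsample of the scan is
  summed and thresholded (default 1% of the maximum); the bounding box of
  the support, padded by 2 pixels, is the detector ROI. All reductions work
  inside it.
* **Illumination mask** (`build_illumination_mask()`): each ROI frame is
  thresholded at `min_value` (default 5 counts, i.e. just above a zero
  pedestal), binarised and summed over the scan. Pixels whose count lies in
  the 95–100% band of the maximum form the transmitted-beam support; ROI
  pixels outside it collect the dark-field signal.
* **Hot pixels** (`detect_hot_pixels()`): a pixel is suspicious in a frame
  when it deviates from its 3×3 neighbourhood median by more than
  `variance_threshold` (default 8) times the neighbourhood MAD plus a
  1-count floor. MAD rather than variance makes the statistic robust to the
  beam peak itself. Because shot noise is transient while detector defects
  persist, a pixel enters the look-up table only when flagged in at least
  80% of the sampled frames. Repair either replaces the pixel by the mean
  of its non-hot 8-neighbours or excludes it (`NA`) from every downstream
  sum and centroid. All thresholds are user-modifiable.
* **XRF calibration** (`calibrate_energy()`): least-squares line through at
  least two identified lines, exact for two. Energy windows map to channel
  ranges by treating channels as bins of one gain-width centred on their
  nominal energy.

## Reduction

Per scan pixel: transmission is the sum of repaired frame values over the
ROI; dark field is the same sum restricted to outside the beam mask (so
transmission = beam + dark field is an exact partition); elemental maps are
channel-range sums of the spectra (peak fitting and background subtraction
are delegated to dedicated fitting software, whose fitted maps can be
re-imported from TIFF).

DPC: the beam centroid inside the ROI, minus a reference centroid, gives
the shift in detector pixels. The reference defaults to the per-scan median
centroid — no unique convention fixes the DPC zero, and the median is
robust to the sample occupying most of the field; a background region can
be passed instead. With pixel pitch $p$ and
camera length $L$, the refraction angle is $\alpha = \mathrm{shift}\cdot
p/L$, and the phase gradient follows from
$\alpha_{x,y} = \frac{\lambda}{2\pi}\,\partial\phi/\partial(x,y)$.
Gradients are stored in rad/µm with the geometry in metadata, so the
conversion is reversible; a unit flag also exposes raw shifts or angles.
Scanning DPC measures the gradient directly, so no phase wrapping occurs at
any φ magnitude.

## Correction

* **Monitor**: count modalities are divided by the monitor scaled to its
  mean; DPC is left alone because a centroid is invariant under intensity
  scaling.
* **Virtual grid** (`regrid_virtual()`): continuous-motion scans have
  unequal measured pixel extents. Every map is reassigned to a uniform grid
  whose cell size is the mean measured extent; multi-hit cells are
  averaged, empty cells filled from their neighbourhood median. Smoothing
  is applied *only* where aberrant values can appear — cells with zero or
  multiple hits — never to clean one-hit cells, which keeps the operation
  idempotent on already-uniform grids.
* **Background reference** (`background_reference()`): for well isolated
  objects each row's ends are object-free; the row baseline is their
  median, the object support is where the smoothed row deviates from the
  baseline by more than 5 row-end MADs (plus a relative floor), widened by
  the median-filter half-width. Count modalities are divided by the row
  reference, phase gradients have it subtracted. Rows whose object reaches
  the baseline window are flagged and fall back to the global reference; a
  manual region is recommended for non-isolated specimens.
* **Rotation axis and wobble** (`estimate_rotation_axis()`): the per-angle
  centre of mass of an in-field object is exactly $c + A\sin(\theta+\psi)$;
  a linear least-squares fit in $(c, A\cos\psi, A\sin\psi)$ with one
  Tukey-reweighted pass (the "special care" against noisy projections)
  gives the rotation centre $c$; the residuals are the per-angle wobble
  shifts. `apply_shift_correction()` removes the residuals and recentres
  the axis on the sinogram midline by sub-pixel linear interpolation, and
  the same fit — normally estimated on the highest-contrast modality,
  transmission — is applied to all modalities, which share the geometry.
  A 360° sinogram is strongly preferred; below ~270° coverage the sine term
  is poorly constrained and the fit is flagged wide-confidence rather than
  refused.

A modelling note on wobble: a lateral axis deviation at the rotation
frequency is mathematically indistinguishable from a constant object
offset (both are $c + A\sin(\theta+\psi)$), so no centre-of-mass method
could separate them. The synthetic acquisition therefore models wobble on
the second harmonic, $\sin(2\theta+\psi)$ — the precession-like component
the residuals genuinely capture.

## Phase integration

Two integrators turn the gradient pair $(g_x, g_y)$ into a quantitative
phase map.

**Fourier derivative method** (`fourier_integrate()`): the complex image
$g_x + i g_y$ is Fourier transformed and divided by the complex frequency
sum; the real part of the inverse transform is φ and the imaginary part is
the reconstruction residual, conventionally required to stay below 10% of
the real part in intensity. Two numerical choices matter:

* The complex divisor is built from the *same* centred-difference
  convention used to form the gradients (eigenvalues $i\sin(2\pi u/N)$
  rather than $2\pi i u/N$), which makes differentiate-then-integrate an
  exact inverse on periodic band-limited fields — machine-precision
  round-trips rather than a convention-mismatch bias.
* The zero-frequency coefficient is set to zero to avoid the divergence, so
  the offset is lost; it is re-calibrated as the mean over an object-free
  region (`calib_region`), typically corner squares or pixels flagged as
  background by the correction stage.

The DFT assumes periodicity, so a sample crossing the field edge wraps and
contaminates the result. Mirroring both gradient images in both directions
before integrating imposes Neumann-like boundaries: `MDI` mirrors the
derivative images as they are, `ASDI` flips the sign of the mirrored
normal derivative, which is the extension consistent with an even (mirror)
continuation of φ itself; the result is cropped back to the original
window. The boundary-artefact test (edge-touching bump) verifies both beat
the plain periodic transform, with ASDI the accurate default.

**Southwell least squares** (`southwell_integrate()`): iterative
finite-difference integration in the staggered Southwell geometry — each
pixel is repeatedly replaced by the relaxed average of its neighbours'
phase corrected by the mid-point measured gradients. Missing neighbours
and invalid gradients drop out of the average with renormalised counts
(Neumann-like edges). With the `jacobi` scheme the whole map updates per
sweep and the relaxation must lie in (0, 1]; with `gauss_seidel` each pixel
updates in place and over-relaxation has an optimal value depending only on
the number of measured gradient values N, used as the default:
$w = 2/\bigl(1 + \sin(\pi/(\sqrt{N}+1))\bigr)$ (the classical SOR optimum
for the equivalent Poisson system, with $\sqrt{N}$ the effective grid
side). Iteration stops when the largest update falls below `tol`
(10⁻⁶ rad by default, 10⁴ iterations cap); non-convergence is a flag on
the returned map, not an error. The method's practical advantage is
locality: where a saturating sample holder leaves garbage, mutually
inconsistent gradients, the artefacts stay circumscribed near the
discontinuity instead of contaminating the full field as the global
Fourier solution does — at the price of runtime that grows with the map.

Thickness conversion is $t = \phi\lambda/(2\pi\delta)$ with
$\lambda = 12.398/E$ Å. For the nylon validation wires
($\delta = 1.63\times10^{-6}$ at 14 keV, nominal diameters 100 µm and
50 µm) the full synthetic pipeline recovers the maximum thickness to well
within 2% of nominal.

## Tomography

Projections are modelled as $p_i = \sum_j w_{ij} f_j$. `fractional_area`
weights are exact ray–pixel intersection lengths normalised by the pixel
size — a length-weighting stand-in for area weighting that is exact in the
limit of thin rays and, as the sub-pixel point test shows, localises
features with less bias than the fast `binary` (0/1) weights. Geometry
conventions (nowhere prescribed by the method literature in a unique way):
parallel rays, angle 0 along +y, counterclockwise angles, grid centred on
the corrected axis, tomogram pixel = detector step.

* **FBP**: rows are zero-padded, filtered with the ramp $2|k|$ times a
  Hamming window, back-projected with linear interpolation and scaled by
  $\pi/(2M)$ — a scale that serves 180° and 360° coverage alike because
  opposite projections duplicate. The **Hilbert** filter
  $-\tfrac{i}{\pi}\mathrm{sign}(k)$ (times the same window) reconstructs
  directly from derivative (DPC) sinograms; its normalisation is pinned by
  the uniform-disc plateau test rather than by convention, since none is
  standard. The interpolating backprojector has a discretisation floor:
  with ~128-pixel grids the reconstruction error stops improving beyond
  roughly half the grid size in projections, which is also exactly the
  sampling advisory (`sampling_check()` warns when $M < P/2$).
* **ART**: Kaczmarz row action, rays visited in fixed angle-major order
  (no shuffling, for reproducibility), relaxation default 0.25. Setting the
  relaxation to 1 recovers the textbook form.
* **SIRT**: simultaneous row/column-sum normalised update, relaxation
  default 1.0, optional non-negativity for count modalities. It converges
  more slowly than ART but suppresses noise and streaks, which is why it is
  the default for low-count XRF sinograms: on the 30-projection noisy
  capillary twin the FBP background variance is an order of magnitude above
  SIRT's, while the SIRT tomogram's Rose SNR (object-minus-background mean
  over background standard deviation, detectability threshold 5) stays
  comfortably above 5.

Per-modality defaults follow the dedicated-default policy: transmission
and dark field → FBP ramp×Hamming; DPC → FBP Hilbert; XRF → SIRT.

## The synthetic acquisition model

The generator emulates the acquisition end to end with known ground truth:

* **Phantoms**: cylinders and capillary shells with analytic chord
  thickness; the validation presets are the 100 µm (vertical) and 50 µm
  (horizontal) nylon wires on a 0.5 µm, 256² grid, and the tomography test
  object — a 500 µm glass capillary holding two 100 µm and one 50 µm nylon
  fibres and a 40 µm copper wire, scanned as 500 positions of 4 µm at 500
  angles over 360° (sparse subset: 30 angles, 12° apart). Ground-truth
  gradients are centred finite differences of φ, not the analytic
  derivative, so integration tests are discretisation-consistent (the
  analytic chord derivative diverges at the wire edge).
* **Frames**: Gaussian focused beam (detector-frame footprint), Beer–Lambert
  attenuation $\exp(-4\pi\beta t/\lambda)$, centroid displaced by
  $\alpha L/p$ with the fixture geometry $L = 1$ m, $p = 130$ µm (the
  plausible defaults of a nanoprobe endstation; no result depends on their
  values beyond this shift relation). The scattered halo deposits
  `halo_coef` × (scatter strength × path) counts uniformly in an annulus
  outside the beam; hot pixels are burned in last; Poisson noise, encoder
  jitter and a sinusoidal monitor drift are optional and seeded.
* **Spectra**: Gaussian peaks at the element line energies, areas equal to
  emissivity × path length, binned exactly per channel, over an optional
  flat continuum.

What the model does *not* contain — wave-optical propagation, detector
point spread, spectral backgrounds and pile-up, XRF self-absorption,
scattering anisotropy — bounds what green tests mean: they validate the
algorithmic chain against its own stated forward model, not detector
physics. Absorption indices in the presets are kept small so transmission
stays in a high-SNR regime.

## Validation problem sizes

The shipped tests and the acceptance script use: 256² wire grids for the
thickness twins; a 500² capillary slice with 30 projections and ~100-count
Poisson statistics for the SIRT/FBP comparison (SNR averaged over five
noise seeds); 96–160 px grids for the property suites (axis recovery,
integration cross-checks, monotonicity). These sizes were chosen so each
property is measured well inside its asymptotic regime while the whole
suite stays desk-scale.

## Known limitations

* The streaming contract is exercised at megabyte scale; no terabyte-scale
  benchmarking is attempted.
* TIFF exports carry a JSON sidecar with the affine scale restoring the
  float values; plain consumers see a [0, 1]-normalised image.
* The length-weighted projector leaves a ~0.5% per-ray mass ripple, which
  bounds centre-of-mass residuals for compact objects at a fraction of a
  percent of the orbit radius.
* For 180° sinograms the axis sine fit is under-constrained and only
  flagged, not refused.
* Excluded scan regions are rectangular masks; arbitrary polygons are an
  extension point.
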