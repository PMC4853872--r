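# scanxray

Processing chain for **multimodal scanning X-ray imaging and tomography**.

In a scanning X-ray microprobe, a focused beam is raster-scanned across the
sample while a 2D detector records the transmitted beam per scan pixel and
energy-dispersive detectors record fluorescence spectra. One acquisition
simultaneously encodes absorption contrast, differential phase contrast
(DPC), dark-field contrast and elemental distributions. `scanxray` is for
the people who have to turn those raw multi-gigabyte containers into
quantitative maps and tomograms: beamline scientists and their users doing
post-experiment analysis on ordinary machines.

The package covers the whole chain:

* **scan I/O** — streamed, memory-bounded, block-wise readout of
  NeXus-style HDF5 scan containers (4D frames, 3D spectra, 2D
  positions/monitor), with shape-based dataset discovery, low-resolution
  decimated plans and rectangular exclusions;
* **pre-treatment** — automatic beam ROI from a 10% scan subsample,
  illumination mask with the 95–100% beam-support band, MAD-based
  hot-pixel detection/repair, XRF energy calibration (≥ 2 lines) and
  spectral ROI selection, mca spectrum export / fitted-map import;
* **reduction** — per-pixel transmission sums, centroid-based DPC
  (shift → refraction angle α = shift·p/L → phase gradient
  ∂φ/∂x = 2πα/λ), dark field outside the beam mask, elemental ROI maps;
* **correction** — monitor normalisation, virtual-grid regridding of
  jittered encoder positions, per-row background referencing, and
  rotation-axis + wobble correction from a robust sine fit to the
  sinogram centre of mass;
* **phase integration** — Fourier-derivative method
  φ = Re 𝓕⁻¹[𝓕(g**x** + i g**y**)/(i k**x** − k**y**)] with the zero
  frequency nulled and mirrored (MDI/ASDI) boundaries, and Southwell
  least-squares iteration (Jacobi or Gauss–Seidel with the N-dependent
  optimal relaxation); thickness via t = φλ/(2πδ);
* **tomography** — parallel-beam projector with fractional or binary
  weights, FBP (ramp×Hamming, and a Hilbert filter that reconstructs
  directly from DPC sinograms), ART (Kaczmarz) and SIRT, plus the Rose
  SNR metric and an angular-sampling advisory;
* **synthetic acquisition** — a seeded forward model (wire and capillary
  phantoms, Gaussian beam, Beer–Lambert attenuation, centroid shifts,
  scatter halo, hot pixels, jitter, monitor drift, Poisson noise) that
  gives every stage a ground truth.

## Worked example

The quantitative validation twin: recover the thickness of a 100 µm nylon
wire (δ = 1.63×10⁻⁶ at 14 keV) from its DPC gradients, then reconstruct a
noisy 30-projection capillary sinogram with SIRT.

```r
library(scanxray)

## 100 um nylon-wire phantom and its DPC gradients
ph <- wire_phantom("large")            # 256 x 256 px of 0.5 um, 14 keV
pg <- phase_and_gradients(ph)
g  <- phase_gradient_pair(pg$gx, pg$gy, ph$pixel_size_um, unit = "per_um")

## Fourier integration, antisymmetric mirror boundary, corner calibration
corner <- matrix(FALSE, 256, 256); corner[1:10, 1:10] <- TRUE
pm <- fourier_integrate(g, boundary = "ASDI", calib_region = corner)
pm
#> phase_map (fourier_ASDI): 256 x 256 px, range [-5.329e-15, 11.56] rad

th <- phase_to_thickness(pm, delta = 1.63e-6, energy_kev = 14)
cat(sprintf("max thickness: %.3f um (nominal 100)\n", max(th)))
#> max thickness: 99.999 um (nominal 100)
cat(sprintf("residual ratio: %.2g%%\n", 100 * pm$residual_ratio))
#> residual ratio: 1.5e-13%

## tomographic twin: noisy 30-projection capillary, SIRT vs FBP
cap <- capillary_phantom()             # 500 um capillary, 500 px of 4 um
sino <- forward_project(phantom_slice(cap, "scatter"),
                        attr(cap, "angles_sub"), step_um = 4,
                        modality = "scatter")
set.seed(42)
sc <- 100 / max(sino$values)           # ~100 counts at the densest ray
sino$values[] <- rpois(length(sino$values), sino$values * sc) / sc
rec <- sirt(sino, n_iter = 100)
fibre <- disc_mask(500, c(-120, 60), 40, 4)          # inside a 100 um fibre
bg    <- rect_mask(500, c(400, 800), c(400, 800), 4) # outside the capillary
cat(sprintf("SIRT Rose SNR: %.2f | FBP/SIRT background variance: %.1f\n",
            rose_snr(rec, fibre, bg),
            var(fbp(sino)$values[bg]) / var(rec$values[bg])))
#> SIRT Rose SNR: 12.14 | FBP/SIRT background variance: 45.9
```

The phase map spans 11.56 rad — exactly 2πδ·t/λ for t = 100 µm at 14 keV —
and converts back to the nominal wire diameter to 0.001%. The imaginary
part of the Fourier reconstruction (its error channel) is negligible for
this interior object. On the 30-projection capillary, SIRT keeps the
100 µm fibre detectable (Rose SNR ≈ 12, criterion ≥ 5) while FBP's
star-artefact background carries ~46× more variance.

A pipeline front end (`run_simulate()` → `run_reduce()` → `run_correct()`
→ `run_phase()`/`run_tomo()`, or the `inst/cli/scanxray` Rscript with a
YAML config) orchestrates the same stages over files with provenance
sidecars; stages must be completed sequentially.

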