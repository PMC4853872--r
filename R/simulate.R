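#' Acquisition specification for the synthetic forward model
#'
#' Describes the instrument side of a simulated scan: focused-beam frame
#' model (2D Gaussian on the detector), geometry linking refraction angle to
#' centroid shift, counting noise, encoder jitter, hot pixels, monitor
#' drift, and (for tomography) rotation-axis offset and wobble.
#'
#' @param scan_shape integer(2) scan lines x columns.
#' @param frame_shape detector frame rows x columns.
#' @param beam_amplitude total beam counts per frame.
#' @param beam_sigma_px Gaussian beam sigma in detector pixels.
#' @param beam_center nominal beam centre `c(row, col)`; default frame centre.
#' @param pixel_pitch_um detector pixel pitch p (um).
#' @param distance_mm sample-to-detector distance L (mm).
#' @param noise logical; apply Poisson counting noise.
#' @param seed RNG seed used when `noise` or `jitter_sigma_um > 0`.
#' @param jitter_sigma_um encoder position jitter sigma (um).
#' @param hot_pixels data.frame with columns `row`, `col`, `value`.
#' @param monitor_drift relative amplitude of a slow sinusoidal drift.
#' @param halo_coef dark-field halo counts per (scatter x um) of path.
#' @param n_channels XRF channels per spectrum (0 disables XRF).
#' @param xrf_gain,xrf_offset energy calibration of the simulated detector
#'   (keV/channel, keV), energies at `offset + gain * channel`, 0-based.
#' @param xrf_sigma_kev fluorescence peak width (keV).
#' @param xrf_continuum flat continuum level (counts/channel/pixel).
#' @param angles projection angles (degrees) for tomographic fixtures.
#' @param axis_offset_px rotation-axis offset (detector steps).
#' @param wobble_amplitude_px,wobble_phase sinusoidal wobble of the axis.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(scan_shape, frame_shape = c(32, 32),
                             beam_amplitude = 1e4, beam_sigma_px = 3,
                             beam_center = NULL, pixel_pitch_um = 130,
                             distance_mm = 1000, noise = FALSE, seed = NULL,
                             jitter_sigma_um = 0, hot_pixels = NULL,
                             monitor_drift = 0, halo_coef = 0,
                             n_channels = 0L, xrf_gain = 0.02,
                             xrf_offset = 0, xrf_sigma_kev = 0.1,
                             xrf_continuum = 0, angles = NULL,
                             axis_offset_px = 0, wobble_amplitude_px = 0,
                             wobble_phase = 0) {
  stopifnot(beam_sigma_px >= 0, distance_mm > 0)
  if (!is.null(angles) && any(diff(angles) <= 0))
    stop_scan("angles must be strictly increasing")
  if (is.null(beam_center)) beam_center <- (frame_shape + 1) / 2
  structure(as.list(environment()), class = "acquisition_spec")
}

# discrete Gaussian beam frame, normalised to unit total
beam_kernel <- function(frame_shape, center, sigma) {
  r <- seq_len(frame_shape[1]); c <- seq_len(frame_shape[2])
  if (sigma <= 0) {
    k <- matrix(0, frame_shape[1], frame_shape[2])
    k[round(center[1]), round(center[2])] <- 1
    return(k)
  }
  kr <- exp(-0.5 * ((r - center[1]) / sigma)^2)
  kc <- exp(-0.5 * ((c - center[2]) / sigma)^2)
  k <- outer(kr, kc)
  k / sum(k)
}

#' Simulate raw transmission frames for a scan
#'
#' Per scan pixel the Gaussian beam is attenuated by Beer-Lambert
#' `exp(-4 pi beta t / lambda)` and its centroid displaced by
#' `alpha * L / p` detector pixels, with refraction angle
#' `alpha = (lambda / 2 pi) * grad(phi)`. Scatter deposits
#' `halo_coef * sum(scatter_i * t_i)` counts uniformly in an annulus outside
#' the beam; hot pixels are overwritten last; Poisson noise, encoder jitter
#' and monitor drift are applied when configured.
#'
#' @param phantom a [phantom_spec()].
#' @param acq an [acquisition_spec()].
#' @return list with `frames` (4D), `pos_x`, `pos_y`, `monitor` and `truth`
#'   (phi, gx, gy, thickness, transmission, darkfield maps on the scan grid).
#' @export
synth_frames <- function(phantom, acq) {
  sl <- acq$scan_shape[1]; sc <- acq$scan_shape[2]
  n <- max(sl, sc)
  pg <- phase_and_gradients(phantom, grid_n = n)
  crop_r <- floor((n - sl) / 2) + seq_len(sl)
  crop_c <- floor((n - sc) / 2) + seq_len(sc)
  lam <- phantom$wavelength_um
  t_tot <- pg$thickness$total[crop_r, crop_c, drop = FALSE]
  gx <- pg$gx[crop_r, crop_c, drop = FALSE]
  gy <- pg$gy[crop_r, crop_c, drop = FALSE]
  phi <- pg$phi[crop_r, crop_c, drop = FALSE]
  beta_t <- matrix(0, sl, sc)
  scatter_t <- matrix(0, sl, sc)
  for (k in seq_along(phantom$primitives)) {
    p <- phantom$primitives[[k]]
    tk <- pg$thickness$per_primitive[[k]][crop_r, crop_c, drop = FALSE]
    beta_t <- beta_t + p$beta * tk
    scatter_t <- scatter_t + p$scatter * tk
  }
  transmission <- exp(-4 * pi * beta_t / lam)
  L_um <- acq$distance_mm * 1e3
  shift_c <- (lam / (2 * pi)) * gx * L_um / acq$pixel_pitch_um
  shift_r <- (lam / (2 * pi)) * gy * L_um / acq$pixel_pitch_um
  fs <- acq$frame_shape
  max_r <- max(abs(shift_r)); max_c <- max(abs(shift_c))
  if (acq$beam_center[1] + max_r + 1 > fs[1] || acq$beam_center[1] - max_r < 1 ||
      acq$beam_center[2] + max_c + 1 > fs[2] || acq$beam_center[2] - max_c < 1)
    stop_scan("beam centre displaced outside the detector frame")
  halo_tot <- acq$halo_coef * scatter_t
  # annulus receiving the scattered halo, outside the direct beam
  rr <- matrix(seq_len(fs[1]), fs[1], fs[2])
  cc <- matrix(seq_len(fs[2]), fs[1], fs[2], byrow = TRUE)
  dist2 <- (rr - acq$beam_center[1])^2 + (cc - acq$beam_center[2])^2
  r_in <- 4 * acq$beam_sigma_px
  r_out <- min(6 * acq$beam_sigma_px,
               min(acq$beam_center - 1, fs - acq$beam_center))
  annulus <- dist2 >= r_in^2 & dist2 <= r_out^2
  n_halo <- sum(annulus)
  if (any(halo_tot > 0) && n_halo == 0)
    stop_scan("frame too small to host the dark-field halo annulus")
  if (!is.null(acq$seed)) set.seed(acq$seed)
  npix <- sl * sc
  drift <- 1 + acq$monitor_drift * sin(2 * pi * seq_len(npix) / npix)
  monitor <- matrix(0, sl, sc)
  frames <- array(0, c(sl, sc, fs[1], fs[2]))
  for (j in seq_len(sc)) {
    for (i in seq_len(sl)) {
      idx <- (i - 1) * sc + j  # acquisition order: line by line
      m <- drift[idx]
      monitor[i, j] <- m
      kern <- beam_kernel(fs, acq$beam_center + c(shift_r[i, j], shift_c[i, j]),
                          acq$beam_sigma_px)
      fr <- acq$beam_amplitude * transmission[i, j] * m * kern
      if (halo_tot[i, j] > 0)
        fr[annulus] <- fr[annulus] + halo_tot[i, j] * m / n_halo
      if (acq$noise) fr[] <- rpois(length(fr), fr)
      if (!is.null(acq$hot_pixels)) {
        hp <- acq$hot_pixels
        fr[cbind(hp$row, hp$col)] <- hp$value
      }
      frames[i, j, , ] <- fr
    }
  }
  step <- phantom$pixel_size_um
  px <- matrix(rep((seq_len(sc) - 1) * step, each = sl), sl, sc)
  py <- matrix(rep((seq_len(sl) - 1) * step, sc), sl, sc)
  if (acq$jitter_sigma_um > 0) {
    px <- px + matrix(rnorm(npix, 0, acq$jitter_sigma_um), sl, sc)
    py <- py + matrix(rnorm(npix, 0, acq$jitter_sigma_um), sl, sc)
  }
  list(frames = frames, pos_x = px, pos_y = py, monitor = monitor,
       truth = list(phi = phi, gx = gx, gy = gy, thickness = t_tot,
                    transmission = acq$beam_amplitude * transmission,
                    darkfield = halo_tot, shift_r = shift_r,
                    shift_c = shift_c))
}

#' Simulate XRF spectra for a scan
#'
#' Per pixel, each primitive carrying an element emits a Gaussian peak at
#' its line energy with total area `emissivity * path length`, on top of a
#' flat continuum. Peaks are binned exactly (Gaussian integral per channel).
#'
#' @inheritParams synth_frames
#' @return list with `spectra` (3D array lines x cols x channels) and
#'   `truth` (per-element path-length maps).
#' @export
synth_xrf <- function(phantom, acq) {
  nch <- acq$n_channels
  if (nch < 1) stop_scan("acq$n_channels must be >= 1 for synth_xrf")
  sl <- acq$scan_shape[1]; sc <- acq$scan_shape[2]
  n <- max(sl, sc)
  tm <- thickness_map(phantom, grid_n = n)
  crop_r <- floor((n - sl) / 2) + seq_len(sl)
  crop_c <- floor((n - sc) / 2) + seq_len(sc)
  edges <- acq$xrf_offset + acq$xrf_gain * (0:nch - 0.5)
  spectra <- array(acq$xrf_continuum, c(sl, sc, nch))
  truth <- list()
  for (k in seq_along(phantom$primitives)) {
    p <- phantom$primitives[[k]]
    if (is.null(p$element) || p$emissivity <= 0) next
    if (p$line_kev < edges[1] || p$line_kev > edges[nch + 1])
      stop_scan("line energy ", p$line_kev, " keV outside the channel range")
    w <- diff(pnorm(edges, mean = p$line_kev, sd = acq$xrf_sigma_kev))
    path <- tm$per_primitive[[k]][crop_r, crop_c, drop = FALSE]
    truth[[p$element]] <- (truth[[p$element]] %||% 0) + path
    area <- p$emissivity * path
    spectra <- spectra + outer(area, w)
  }
  if (acq$noise) {
    if (!is.null(acq$seed)) set.seed(acq$seed + 1L)
    spectra[] <- rpois(length(spectra), spectra)
  }
  list(spectra = spectra, truth = truth)
}

#' Simulate a tomographic sinogram of a phantom slice
#'
#' Forward-projects a cross-section property map at the given angles, then
#' applies the configured rotation-axis offset and sinusoidal wobble as
#' sub-pixel projection shifts, and optionally Poisson noise after scaling
#' the line integrals to `peak_counts` at the densest ray.
#'
#' @inheritParams synth_frames
#' @param property slice property to project (see [phantom_slice()]).
#' @param element element label when `property = "element"`.
#' @param peak_counts expected counts at the densest ray when noise is on
#'   (`NULL` keeps the raw line-integral scale).
#' @return a [sinogram()] plus attribute `truth` (the slice image) and
#'   `shifts` (applied per-angle shifts, detector steps).
#' @export
synth_sinogram <- function(phantom, acq, property = "scatter", element = NULL,
                           peak_counts = NULL) {
  if (is.null(acq$angles)) stop_scan("acquisition_spec has no angles")
  slice <- phantom_slice(phantom, property, element)
  sino <- forward_project(slice, acq$angles, step_um = phantom$pixel_size_um,
                          modality = property)
  th <- acq$angles * pi / 180
  # wobble is modelled on the second harmonic: a first-harmonic lateral
  # deviation is indistinguishable from a constant object offset in the
  # centre-of-mass sine fit, so it could never be separated downstream
  shifts <- acq$axis_offset_px +
    acq$wobble_amplitude_px * sin(2 * th + acq$wobble_phase)
  if (any(shifts != 0)) sino$values <- shift_rows(sino$values, shifts)
  if (acq$noise) {
    if (!is.null(acq$seed)) set.seed(acq$seed)
    sc <- if (is.null(peak_counts)) 1 else peak_counts / max(sino$values)
    sino$values[] <- rpois(length(sino$values), pmax(sino$values * sc, 0)) / sc
  }
  attr(sino, "truth") <- slice
  attr(sino, "shifts") <- shifts
  sino
}

# shift each row of a matrix by a sub-pixel amount (linear interpolation,
# edge values extended)
shift_rows <- function(m, shifts) {
  P <- ncol(m)
  out <- m
  for (i in seq_len(nrow(m))) {
    if (shifts[i] == 0) next
    out[i, ] <- approx(seq_len(P), m[i, ], xout = seq_len(P) - shifts[i],
                       rule = 2)$y
  }
  out
}

#' Simulate a full scan and write it as an HDF5 container
#'
#' Runs [synth_frames()] (and [synth_xrf()] when `n_channels > 0`), writes
#' the container via [write_scan()] and, when `truth_dir` is given, the
#' ground-truth maps as TIFFs.
#'
#' @inheritParams synth_frames
#' @param path output HDF5 path.
#' @param truth_dir optional directory for ground-truth TIFF maps.
#' @return invisible list with the layout and the truth maps.
#' @export
simulate_scan <- function(phantom, acq, path, truth_dir = NULL) {
  fr <- synth_frames(phantom, acq)
  spectra <- NULL
  if (acq$n_channels > 0) {
    xr <- synth_xrf(phantom, acq)
    spectra <- list(xr$spectra)
    fr$truth$elements <- xr$truth
  }
  write_scan(path, fr$frames, spectra = spectra, pos_x = fr$pos_x,
             pos_y = fr$pos_y, monitor = fr$monitor)
  if (!is.null(truth_dir)) {
    dir.create(truth_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("phi", "gx", "gy", "thickness", "transmission", "darkfield"))
      write_map_tiff(fr$truth[[nm]], file.path(truth_dir, paste0(nm, ".tif")),
                     meta = list(content = nm, synthetic = TRUE))
  }
  invisible(list(path = path, truth = fr$truth))
}
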