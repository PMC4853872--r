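wire_reduction <- function() {
  memo("wire_reduction", function() {
    fx <- wire_scan_fixture()
    h <- open_scan(fx$path)
    roi <- auto_roi(h, margin = 2)
    illum <- build_illumination_mask(h, roi, min_value = 1e-3)
    list(fx = fx, h = h, roi = roi, illum = illum)
  })
}

test_that("transmission map tracks the forward-model attenuation exactly", {
  w <- wire_reduction()
  tr <- transmission_map(w$h, w$illum)
  # zero frames reduce to zero
  z <- structure(list(lines = 1:2, cols = 1:2,
                      frames = array(0, c(2, 2, 4, 4)), spectra = list(),
                      pos_x = matrix(0, 2, 2), pos_y = matrix(0, 2, 2),
                      monitor = matrix(1, 2, 2)), class = "scan_block")
  roi_all <- structure(list(rows = 1:4, cols = 1:4), class = "detector_roi")
  il0 <- illumination_model(roi_all, matrix(1, 4, 4))
  expect_true(all(transmission_map(list(z), il0)[1:2, 1:2] == 0))
  # noise-free: perfectly correlated with the ground-truth attenuation
  truth <- w$fx$sim$truth$transmission
  expect_gt(cor(as.vector(tr), as.vector(truth)), 0.999999)
  # the ROI misses only far Gaussian tails
  expect_equal(tr, truth, tolerance = 1e-3)
})

test_that("transmission + dark field partition the total ROI counts", {
  w <- wire_reduction()
  tr <- transmission_map(w$h, w$illum)
  df <- darkfield_map(w$h, w$illum)
  all_mask <- matrix(TRUE, length(w$illum$roi$rows), length(w$illum$roi$cols))
  total <- tr  # transmission_map sums the whole ROI by construction
  beam_only <- scanxray:::block_mask_sum(w$fx$sim$frames, w$illum$roi,
                                         w$illum$beam_mask)
  expect_equal(as.vector(tr - df), beam_only, tolerance = 1e-9)
  # all counts inside the beam mask -> dark field is exactly zero
  fr0 <- array(0, c(2, 2, 6, 6)); fr0[, , 3, 3] <- 50
  il <- build_illumination_mask(fr0, min_value = 1)
  blk <- structure(list(lines = 1:2, cols = 1:2, frames = fr0,
                        spectra = list(), pos_x = matrix(0, 2, 2),
                        pos_y = matrix(0, 2, 2), monitor = matrix(1, 2, 2)),
                   class = "scan_block")
  expect_true(all(darkfield_map(list(blk), il)[1:2, 1:2] == 0))
})

test_that("a halo-only fixture lands entirely in the dark-field map", {
  ph <- phantom_spec(list(wire_primitive(60, delta = 0, beta = 0,
                                         scatter = 2)),
                     pixel_size_um = 2, energy_kev = 14, grid_n = 24)
  acq <- acquisition_spec(c(24, 24), frame_shape = c(32, 32),
                          beam_sigma_px = 2, halo_coef = 0.5)
  fr <- synth_frames(ph, acq)
  il <- build_illumination_mask(fr$frames, min_value = 1)
  blks <- list(structure(list(lines = 1:24, cols = 1:24, frames = fr$frames,
                              spectra = list(), pos_x = fr$pos_x,
                              pos_y = fr$pos_y, monitor = fr$monitor),
                         class = "scan_block"))
  df <- darkfield_map(blks, il)
  # the injected halo is recovered exactly up to the constant residual of
  # the Gaussian beam tail beyond the mask (identical in every frame here)
  delta <- df - fr$truth$darkfield
  expect_lt(sd(delta), 1e-9)
  expect_gt(cor(as.vector(df), as.vector(fr$truth$darkfield)), 0.999999)
})

test_that("DPC centroids recover the phase gradients to <1% of peak", {
  w <- wire_reduction()
  dp <- dpc_map(w$h, w$illum, geometry = w$fx$geometry)
  truth <- w$fx$sim$truth
  expect_lt(rmse_ <- sqrt(mean((dp$dpc_x - truth$gx)^2)),
            0.01 * max(abs(truth$gx)))
  expect_lt(sqrt(mean((dp$dpc_y - truth$gy)^2)), 1e-10)  # vertical wire: gy = 0

  # no sample: zero shift, zero angle
  flat <- array(0, c(3, 3, 16, 16))
  k <- scanxray:::beam_kernel(c(16, 16), c(8.5, 8.5), 2)
  for (i in 1:3) for (j in 1:3) flat[i, j, , ] <- 1000 * k
  il <- build_illumination_mask(flat, min_value = 1e-3)
  dp0 <- dpc_map(list(structure(list(lines = 1:3, cols = 1:3, frames = flat,
                                     spectra = list(),
                                     pos_x = matrix(0, 3, 3),
                                     pos_y = matrix(0, 3, 3),
                                     monitor = matrix(1, 3, 3)),
                                class = "scan_block")),
                 il, unit = "shift_px")
  expect_equal(dp0$dpc_x, matrix(0, 3, 3), tolerance = 1e-9)

  # a beam displaced by exactly one detector pixel maps to alpha = p / L
  shifted <- flat
  for (i in 1:3) for (j in 1:3)
    shifted[i, j, , ] <- 1000 * scanxray:::beam_kernel(c(16, 16), c(8.5, 9.5), 2)
  shifted[2, 2, , ] <- flat[2, 2, , ]  # reference pixel keeps the nominal centre
  dp1 <- dpc_map(list(structure(list(lines = 1:3, cols = 1:3, frames = shifted,
                                     spectra = list(),
                                     pos_x = matrix(0, 3, 3),
                                     pos_y = matrix(0, 3, 3),
                                     monitor = matrix(1, 3, 3)),
                                class = "scan_block")),
                 il, geometry = list(pixel_pitch_um = 130, distance_mm = 1000,
                                     energy_kev = 14),
                 unit = "angle_rad", reference = c(8.5, 8.5))
  # exact up to the sub-permille truncation asymmetry of the sampled beam
  expect_equal(dp1$dpc_x[1, 1], 130 / 1e6, tolerance = 5e-3)
})

test_that("XRF ROI maps integrate the configured channel windows", {
  set.seed(21)
  sp <- array(rpois(5 * 4 * 64, 3), c(5, 4, 64))
  total <- xrf_roi_maps(sp, list(all = c(0L, 63L)))$all
  expect_equal(total, apply(sp, c(1, 2), sum))
  halves <- xrf_roi_maps(sp, list(a = c(0L, 31L), b = c(32L, 63L)))
  expect_equal(halves$a + halves$b, total)  # disjoint ROIs sum independently

  # capillary fixture: the Cu window lights up only on the 40 um wire
  ph <- capillary_phantom(grid_n = 120, pixel_size_um = 16)
  acq <- acquisition_spec(c(120, 120), n_channels = 512)
  xr <- synth_xrf(ph, acq)
  cal <- calibrate_energy(data.frame(channel = c(0, 100),
                                     energy_kev = c(0, 2)))
  rg <- select_spectral_rois(cal, list(Cu = c(7.8, 8.3)), 512)
  cu <- xrf_roi_maps(xr$spectra, rg)$Cu
  on_wire <- cu[disc_mask(120, c(-40, -30), 15, 16)]
  off_wire <- cu[disc_mask(120, c(100, -90), 30, 16)]  # a nylon fibre
  expect_gt(min(on_wire), 0)
  expect_equal(max(off_wire), 0)
})

test_that("mca spectra and fitted-map TIFFs round-trip", {
  spec <- c(0, 3, 120, 4039, 120, 3, 0, 1)
  cal <- calibrate_energy(data.frame(channel = c(0, 100),
                                     energy_kev = c(0.1, 2.1)))
  p <- tempfile(fileext = ".mca")
  export_spectrum_mca(spec, cal, p)
  back <- read_spectrum_mca(p)
  expect_equal(back$counts, spec)
  expect_equal(back$calibration$gain, cal$gain, tolerance = 1e-9)
  expect_equal(back$calibration$offset, cal$offset, tolerance = 1e-9)
  # zero spectrum -> all-zero body, channel count preserved
  p0 <- tempfile(fileext = ".mca")
  export_spectrum_mca(rep(0, 16), NULL, p0)
  expect_equal(read_spectrum_mca(p0)$counts, rep(0, 16))

  m <- matrix(rnorm(30), 5, 6); m[2, 3] <- NaN
  pt <- tempfile(fileext = ".tif")
  write_map_tiff(m, pt, meta = list(modality = "fit"))
  got <- import_fitted_maps(c(fit = pt), c(5, 6))$fit
  expect_true(is.na(got[2, 3]))
  expect_equal(got[-8], m[-8], tolerance = 1e-6)
  expect_error(import_fitted_maps(c(fit = pt), c(6, 5)), "shape")
})

test_that("reduction is linear: maps of summed frames equal summed maps", {
  set.seed(31)
  a <- array(rpois(2 * 2 * 36, 20), c(2, 2, 6, 6))
  b <- array(rpois(2 * 2 * 36, 20), c(2, 2, 6, 6))
  il <- build_illumination_mask(a + b, min_value = 0)
  mk <- function(fr) list(structure(
    list(lines = 1:2, cols = 1:2, frames = fr, spectra = list(),
         pos_x = matrix(0, 2, 2), pos_y = matrix(0, 2, 2),
         monitor = matrix(1, 2, 2)), class = "scan_block"))
  expect_equal(transmission_map(mk(a + b), il),
               transmission_map(mk(a), il) + transmission_map(mk(b), il))
  expect_equal(darkfield_map(mk(a + b), il),
               darkfield_map(mk(a), il) + darkfield_map(mk(b), il))
})
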