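flat_maps <- function(nl = 12, nc = 16, value = 100) {
  tr <- matrix(value, nl, nc)
  modality_maps(tr, darkfield = matrix(value / 10, nl, nc),
                dpc = list(dpc_x = matrix(0, nl, nc),
                           dpc_y = matrix(0, nl, nc), unit = "gradient",
                           geometry = NULL))
}

test_that("monitor normalisation corrects drift and spares the DPC", {
  m <- flat_maps()
  # constant monitor: identity
  out <- normalize_by_monitor(m, matrix(3, 12, 16))
  expect_equal(out$transmission, m$transmission)
  # monitor = transmission (self-normalisation): flat map
  m2 <- flat_maps()
  m2$transmission <- matrix(runif(12 * 16, 50, 150), 12, 16)
  out2 <- normalize_by_monitor(m2, m2$transmission)
  expect_lt(diff(range(out2$transmission)), 1e-9)
  # a 2x dip at one pixel on a flat fixture is corrected to its neighbours
  mon <- matrix(1, 12, 16); mon[5, 5] <- 0.5
  m3 <- flat_maps()
  m3$transmission <- m3$transmission * mon  # dip imprinted in the counts
  out3 <- normalize_by_monitor(m3, mon)
  expect_equal(out3$transmission[5, 5], out3$transmission[5, 6],
               tolerance = 1e-9)
  expect_equal(out3$dpc_x, m3$dpc_x)  # DPC untouched
  # non-positive monitor invalidates the pixel
  mon0 <- matrix(1, 12, 16); mon0[2, 2] <- 0
  out4 <- normalize_by_monitor(flat_maps(), mon0)
  expect_false(out4$valid[2, 2])
  expect_true(is.na(out4$transmission[2, 2]))
})

test_that("virtual-grid regridding is exact on ideal grids and conservative under jitter", {
  nl <- 20; nc <- 24
  px <- matrix(rep(seq_len(nc) * 2.0, each = nl), nl, nc)
  py <- matrix(rep(seq_len(nl) * 2.0, nc), nl, nc)
  m <- flat_maps(nl, nc)
  m$transmission <- matrix(runif(nl * nc, 90, 110), nl, nc)
  out <- regrid_virtual(m, px, py)
  expect_equal(out$transmission, m$transmission, tolerance = 1e-12)  # identity
  # idempotence on an already-uniform grid
  out2 <- regrid_virtual(out, px, py)
  expect_equal(out2$transmission, out$transmission, tolerance = 1e-12)

  set.seed(42)
  jx <- px + matrix(rnorm(nl * nc, 0, 0.3 * 2.0), nl, nc)
  jy <- py + matrix(rnorm(nl * nc, 0, 0.3 * 2.0), nl, nc)
  mf <- flat_maps(nl, nc)
  outj <- regrid_virtual(mf, jx, jy)
  # noise-free flat map stays flat within 1%
  expect_lt(diff(range(outj$transmission)) / 100, 0.01)
  # total intensity conserved within 1%
  expect_lt(abs(sum(outj$transmission) - sum(mf$transmission)) /
              sum(mf$transmission), 0.01)
  expect_error(regrid_virtual(mf, px * 0, py * 0), "degenerate")
})

test_that("background referencing normalises rows and brackets isolated objects", {
  # object-free map: reference = row level, normalised map = 1
  m <- flat_maps()
  m$transmission <- matrix(rep(seq(90, 112, length.out = 12), 16), 12, 16)
  br <- background_reference(m)
  expect_equal(br$maps$transmission, matrix(1, 12, 16), tolerance = 1e-9)
  expect_length(br$flagged_rows, 0)

  # isolated wire: detected edges bracket the true support
  fx <- wire_scan_fixture()
  tr <- fx$sim$truth$transmission
  maps <- modality_maps(tr, dpc = list(dpc_x = fx$sim$truth$gx,
                                       dpc_y = fx$sim$truth$gy,
                                       unit = "gradient", geometry = NULL))
  br2 <- background_reference(maps)
  support <- tr[20, ] < max(tr) * 0.999
  bg_row <- br2$background_mask[20, ]
  expect_true(all(!bg_row[support]))       # no object pixel in the background
  expect_gt(sum(bg_row), 0)
  # transmission normalised to ~1 in the background
  expect_equal(mean(br2$maps$transmission[br2$background_mask]), 1,
               tolerance = 1e-6)
  # phase gradients have the background offset subtracted
  expect_lt(max(abs(br2$maps$dpc_x[br2$background_mask])), 1e-9)

  # manual region: whole map as background equals global normalisation
  mask <- matrix(TRUE, 12, 16)
  br3 <- background_reference(m, mask)
  expect_equal(br3$maps$transmission,
               m$transmission / apply(m$transmission, 1, median),
               tolerance = 1e-12)
})

test_that("the centre-of-mass sine fit recovers axis offset and wobble", {
  # centred symmetric phantom: centre at the detector midline, amplitude ~ 0
  ph <- capillary_phantom(grid_n = 160, pixel_size_um = 12.5)
  sino0 <- synth_sinogram(ph, acquisition_spec(
    c(72, 160), angles = seq(0, 355, by = 5)))
  # the capillary shell is centred; inner fibres make the COM genuinely sinusoidal
  fit0 <- estimate_rotation_axis(sino0)
  expect_equal(fit0$center, (160 + 1) / 2, tolerance = 0.05)

  # exactness premise: a compact object's centre of mass is a pure sine;
  # discrete ray weights leave sub-percent-of-orbit residuals and the
  # centre itself is recovered essentially exactly
  cc <- (1:101) - 51
  pt <- exp(-(outer((cc - 15)^2, (cc + 20)^2, `+`)) / (2 * 4^2))
  sp <- forward_project(pt, seq(0, 359, by = 3))
  fitp <- estimate_rotation_axis(sp)
  orbit <- sqrt(15^2 + 20^2)
  expect_lt(max(abs(fitp$residuals)), 0.01 * orbit)
  expect_equal(fitp$center, 51, tolerance = 1e-3)
  expect_equal(fitp$amplitude, orbit, tolerance = 0.01)

  # injected 7 px offset on a noise-free 360 degree sinogram: within 0.25 px
  acq <- acquisition_spec(c(120, 160), angles = seq(0, 357, by = 3),
                          axis_offset_px = 7.0)
  sino7 <- synth_sinogram(ph, acq)
  fit7 <- estimate_rotation_axis(sino7)
  expect_lt(abs(fit7$center - ((160 + 1) / 2 + 7)), 0.25)

  # injected 2 px wobble: residuals match the injected shifts to 0.5 px RMS
  acqw <- acquisition_spec(c(120, 160), angles = seq(0, 357, by = 3),
                           axis_offset_px = 7, wobble_amplitude_px = 2,
                           wobble_phase = 0.7)
  sinow <- synth_sinogram(ph, acqw)
  fitw <- estimate_rotation_axis(sinow)
  wob <- attr(sinow, "shifts") - 7
  expect_lt(sqrt(mean((fitw$residuals - wob)^2)), 0.5)
  expect_error(estimate_rotation_axis(
    sinogram(matrix(0, 4, 8), c(0, 90, 180, 270))), "mass")
  # half-turn coverage is flagged wide-confidence
  expect_true(estimate_rotation_axis(
    sinogram(sino0$values[1:36, ], sino0$angles_deg[1:36]))$wide_confidence)
})

test_that("shift correction recentres all modalities and helps reconstruction", {
  ph <- capillary_phantom(grid_n = 160, pixel_size_um = 12.5)
  angles <- seq(0, 357, by = 3)
  acq <- acquisition_spec(c(120, 160), angles = angles, axis_offset_px = 5,
                          wobble_amplitude_px = 2)
  sino <- synth_sinogram(ph, acq)
  fit <- estimate_rotation_axis(sino)
  # zero-correction identity
  fit0 <- fit; fit0$center <- (160 + 1) / 2; fit0$residuals[] <- 0
  same <- apply_shift_correction(sino, fit0)
  expect_equal(same$values, sino$values, tolerance = 1e-12)

  corr <- apply_shift_correction(sino, fit)
  truth <- attr(sino, "truth")
  e_un <- sqrt(mean((fbp(sino)$values - truth)^2))
  e_co <- sqrt(mean((fbp(corr)$values - truth)^2))
  expect_lt(e_co, e_un)

  # the transmission-derived fit also fixes a co-simulated XRF sinogram
  xrf <- synth_sinogram(ph, acq, property = "element", element = "Cu")
  both <- apply_shift_correction(list(sino, xrf), fit)
  truth_x <- attr(xrf, "truth")
  ex_un <- sqrt(mean((fbp(xrf)$values - truth_x)^2))
  ex_co <- sqrt(mean((fbp(both[[2]])$values - truth_x)^2))
  expect_lt(ex_co, ex_un)

  # correction quality improves monotonically as wobble shrinks
  errs <- vapply(c(3, 2, 1), function(A) {
    aq <- acquisition_spec(c(120, 160), angles = angles,
                           wobble_amplitude_px = A)
    s <- synth_sinogram(ph, aq)
    f <- estimate_rotation_axis(s)
    sqrt(mean((fbp(apply_shift_correction(s, f))$values -
                 attr(s, "truth"))^2))
  }, 0)
  raw3 <- local({
    aq <- acquisition_spec(c(120, 160), angles = angles,
                           wobble_amplitude_px = 3)
    s <- synth_sinogram(ph, aq)
    sqrt(mean((fbp(s)$values - attr(s, "truth"))^2))
  })
  expect_lt(errs[1], raw3)  # correcting 3 px wobble beats not correcting
})
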