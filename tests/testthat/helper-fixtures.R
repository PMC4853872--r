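# fixtures are generated in code at test time; heavier ones are memoised per
# test run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

gauss_bump <- function(n, amp = 1, sigma = n / 10, center = c(0, 0)) {
  cc <- (1:n) - (n + 1) / 2
  x <- matrix(cc, n, n, byrow = TRUE)
  y <- matrix(rev(cc), n, n)
  amp * exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * sigma^2))
}

periodic_phi <- function(n) {
  xx <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yy <- matrix(0:(n - 1), n, n)
  sin(2 * pi * 3 * xx / n) + 0.5 * cos(2 * pi * 5 * yy / n) +
    0.3 * sin(2 * pi * (2 * xx + 4 * yy) / n)
}

# small noise-free wire scan with frames (memoised; used across modules)
wire_scan_fixture <- function() memo("wire_scan", function() {
  ph <- wire_phantom("large", grid_n = 40, pixel_size_um = 3.2)
  acq <- acquisition_spec(c(40, 40), frame_shape = c(24, 24),
                          beam_amplitude = 1e4, beam_sigma_px = 2.5)
  fr <- synth_frames(ph, acq)
  path <- tempfile(fileext = ".h5")
  write_scan(path, fr$frames, pos_x = fr$pos_x, pos_y = fr$pos_y,
             monitor = fr$monitor)
  list(path = path, phantom = ph, acq = acq, sim = fr,
       geometry = list(pixel_pitch_um = 130, distance_mm = 1000,
                       energy_kev = 14))
})

# tiny deterministic scan with spectra for the I/O tests
tiny_scan_fixture <- function() memo("tiny_scan", function() {
  set.seed(11)
  sl <- 6L; sc <- 5L
  frames <- array(runif(sl * sc * 8 * 7), c(sl, sc, 8, 7))
  spectra <- list(array(rpois(sl * sc * 16, 4), c(sl, sc, 16)))
  path <- tempfile(fileext = ".h5")
  write_scan(path, frames, spectra = spectra)
  list(path = path, frames = frames, spectra = spectra)
})

capillary_sub_fixture <- function() memo("capillary_sub", function() {
  ph <- capillary_phantom()
  slice <- phantom_slice(ph, "scatter")
  clean <- forward_project(slice, attr(ph, "angles_sub"),
                           step_um = ph$pixel_size_um, modality = "scatter")
  list(phantom = ph, slice = slice, clean = clean)
})

noisy_capillary_sino <- function(seed, peak = 100) {
  fx <- capillary_sub_fixture()
  sino <- fx$clean
  set.seed(seed)
  sc <- peak / max(sino$values)
  sino$values[] <- rpois(length(sino$values), sino$values * sc) / sc
  sino
}
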