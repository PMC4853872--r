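test_that("forward projection conserves mass and matches the explicit weights", {
  expect_true(all(forward_project(matrix(0, 16, 16), c(0, 45, 90))$values == 0))
  # single unit pixel at the centre: constant-position trace over angles
  x <- matrix(0, 17, 17); x[9, 9] <- 1
  s <- forward_project(x, seq(0, 350, by = 10))
  expect_true(all(apply(s$values, 1, which.max) == 9))
  # Radon mass invariant on a smooth extended object
  f <- gauss_bump(32, amp = 1, sigma = 6)
  sf <- forward_project(f, seq(0, 170, by = 10))
  masses <- rowSums(sf$values)
  expect_lt(diff(range(masses)) / mean(masses), 5e-3)

  # matrix-free projector agrees with the explicit sparse W
  W <- projection_weights(32, seq(0, 170, by = 10))
  p_w <- matrix(as.vector(W %*% as.vector(f)), nrow(sf$values),
                ncol(sf$values), byrow = TRUE)
  expect_equal(p_w, sf$values, tolerance = 1e-12)
  expect_true(all(W@x >= 0) && all(W@x <= sqrt(2) + 1e-9))
})

test_that("FBP sharpens with angular sampling and reconstructs densities", {
  # point phantom: reconstruction peaks at the point
  x <- matrix(0, 33, 33); x[12, 22] <- 1
  rec <- fbp(forward_project(x, seq(0, 359, by = 1)))
  expect_equal(which(rec$values == max(rec$values), arr.ind = TRUE)[1, ],
               c(row = 12, col = 22))

  # disc density plateau near truth (ramp x Hamming)
  disc <- disc_mask(128, c(0, 0), 30) * 1.0
  reconst <- fbp(forward_project(disc, seq(0, 359, by = 1)), "ramp_hamming")
  expect_equal(mean(reconst$values[disc_mask(128, c(0, 0), 20)]), 1,
               tolerance = 0.05)

  # RMSE decreases through {30, 90, 180, 360} projections down to the
  # discretisation floor of the interpolating backprojector
  ph <- gauss_bump(128, amp = 1, sigma = 5) +
    gauss_bump(128, amp = 0.7, sigma = 3, center = c(30, -20)) +
    gauss_bump(128, amp = 0.5, sigma = 4, center = c(-35, 25))
  errs <- vapply(c(30, 90, 180, 360), function(M) {
    ang <- seq(0, 360, length.out = M + 1)[1:M]
    sqrt(mean((fbp(forward_project(ph, ang))$values - ph)^2))
  }, 0)
  expect_true(all(diff(errs) < 1e-4))
  expect_lt(errs[2], 0.5 * errs[1])   # undersampled regime improves sharply
  expect_error(fbp(sinogram(matrix(1, 1, 8), 0)), "at least 2")
})

test_that("capillary FBP with 500 projections beats the 30-projection subset", {
  fx <- capillary_sub_fixture()
  ang_full <- attr(fx$phantom, "angles_full")
  sino_full <- forward_project(fx$slice, ang_full)
  e500 <- sqrt(mean((fbp(sino_full)$values - fx$slice)^2))
  e30 <- sqrt(mean((fbp(fx$clean)$values - fx$slice)^2))
  expect_lt(e500, e30)   # 12-degree sampling leaves star artefacts
})

test_that("the Hilbert filter reconstructs a flat disc from DPC sinograms", {
  disc <- disc_mask(128, c(0, 0), 30) * 1.0
  sino <- forward_project(disc, seq(0, 359, by = 1))
  dsino <- sino
  P <- ncol(sino$values)
  dsino$values <- t(apply(sino$values, 1, function(r) {
    g <- numeric(P)
    g[2:(P - 1)] <- (r[3:P] - r[1:(P - 2)]) / 2
    g[1] <- r[2] - r[1]; g[P] <- r[P] - r[P - 1]
    g
  }))
  rec <- fbp(dsino, "hilbert")
  inner <- disc_mask(128, c(0, 0), 20)
  plateau <- rec$values[inner]
  expect_lt(sd(plateau) / mean(plateau), 0.05)     # flat interior
  expect_equal(mean(plateau), 1, tolerance = 0.05) # correct density scale
})

test_that("ART solves trivial systems exactly and contracts the residual", {
  # one-pixel, one-ray system: solved in a single update
  s1 <- sinogram(matrix(5, 1, 1), 0)
  r1 <- art(s1, relaxation = 1, n_iter = 1, n = 1)
  expect_equal(r1$values[1, 1], 5, tolerance = 1e-12)
  # relaxation 0: the initial image is returned unchanged
  f0 <- matrix(2, 16, 16)
  s <- forward_project(gauss_bump(16, 1, 3), seq(0, 170, by = 30))
  r0 <- art(s, relaxation = 0, n_iter = 2, init = f0)
  expect_equal(r0$values, f0)
  # consistent noise-free system: Kaczmarz residual decreases over cycles
  ra <- art(s, relaxation = 0.25, n_iter = 6)
  expect_true(all(diff(ra$residuals) < 1e-9))
})

test_that("SIRT contracts residuals monotonically and matches FBP quality", {
  fx <- capillary_sub_fixture()
  small <- gauss_bump(48, amp = 2, sigma = 8)
  s <- forward_project(small, seq(0, 350, by = 10))
  rs <- sirt(s, relaxation = 1, n_iter = 60)
  expect_true(all(diff(rs$residuals) <= 1e-9))
  expect_lt(sqrt(mean((rs$values - small)^2)),
            1.2 * sqrt(mean((fbp(s)$values - small)^2)))
  # the trivial one-pixel system again
  r1 <- sirt(sinogram(matrix(5, 1, 1), 0), relaxation = 1, n_iter = 50, n = 1)
  expect_equal(r1$values[1, 1], 5, tolerance = 1e-6)
})

test_that("SIRT suppresses the 30-projection star artefacts that FBP shows", {
  noisy <- noisy_capillary_sino(seed = 42)
  bg <- rect_mask(500, c(400, 800), c(400, 800), 4)
  rec_fbp <- fbp(noisy, "ramp_hamming")
  rec_sirt <- sirt(noisy, relaxation = 1, n_iter = 40)
  expect_gt(var(rec_fbp$values[bg]), var(rec_sirt$values[bg]))
})

test_that("fractional-area weights locate a sub-pixel point better than binary", {
  n <- 33
  f <- matrix(0, n, n)
  f[15, 20] <- 0.7; f[15, 21] <- 0.3   # sub-pixel feature between two cells
  ang <- seq(0, 350, by = 10)
  com_err <- function(mode) {
    s <- forward_project(f, ang, weights = mode)
    rec <- sirt(s, weights = mode, n_iter = 80)
    v <- pmax(rec$values, 0)
    cx <- sum(col(v) * v) / sum(v)
    abs(cx - (20 * 0.7 + 21 * 0.3))
  }
  expect_lt(com_err("fractional_area"), com_err("binary"))
})

test_that("Rose SNR follows its construction and guards degenerate input", {
  set.seed(9)
  img <- matrix(rnorm(64 * 64, 10, 2), 64, 64)
  obj <- rect_mask(64, c(-10, 10), c(-10, 10))
  bgm <- rect_mask(64, c(20, 30), c(-30, 30))
  img[obj] <- img[obj] + 6
  snr <- rose_snr(img, obj, bgm)
  expect_equal(snr, (mean(img[obj]) - mean(img[bgm])) / sd(img[bgm]))
  # identical statistics: SNR ~ 0
  obj100 <- rect_mask(100, c(-10, 10), c(-10, 10))
  bgm100 <- rect_mask(100, c(20, 30), c(-30, 30))
  expect_lt(abs(rose_snr(matrix(rnorm(1e4), 100), obj100, bgm100)), 0.2)
  expect_warning(s_inf <- rose_snr(matrix(c(rep(1, 50), rep(0, 50)), 10),
                                   matrix(rep(c(TRUE, FALSE), each = 50), 10),
                                   matrix(rep(c(FALSE, TRUE), each = 50), 10)),
                 "constant")
  expect_identical(s_inf, Inf)
})

test_that("the angular sampling advisory fires below half the resolution", {
  s500 <- sinogram(matrix(1, 500, 500), seq(0, 360, length.out = 501)[1:500])
  expect_true(sampling_check(s500)$ok)
  s30 <- sinogram(matrix(1, 30, 500), seq(0, 348, by = 12))
  expect_warning(chk <- sampling_check(s30), "undersampling")
  expect_false(chk$ok)
  expect_warning(chk2 <- sampling_check(sinogram(matrix(1, 1, 2), 0)))
  expect_false(chk2$ok)
})

test_that("sinogram and tomogram TIFF round trips keep geometry metadata", {
  fx <- capillary_sub_fixture()
  p <- tempfile(fileext = ".tif")
  write_sinogram_tiff(fx$clean, p)
  back <- read_sinogram_tiff(p)
  expect_equal(back$values, fx$clean$values, tolerance = 1e-5)
  expect_equal(back$angles_deg, fx$clean$angles_deg)
  expect_equal(back$step_um, 4)
})
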