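# ---- phase retrieval: gradient integration and thickness conversion

#' Calibrated phase-gradient pair
#'
#' Container for the horizontal/vertical phase gradients feeding the
#' integrators. Gradients are stored in rad/pixel internally; pass
#' `unit = "per_um"` to convert from rad/um using `pixel_size_um`.
#'
#' @param gx,gy gradient matrices (same shape).
#' @param pixel_size_um grid pixel size.
#' @param unit `"per_pixel"` or `"per_um"`.
#' @return object of class `phase_gradient_pair`.
#' @export
phase_gradient_pair <- function(gx, gy, pixel_size_um = 1,
                                unit = c("per_pixel", "per_um")) {
  unit <- match.arg(unit)
  stopifnot(identical(dim(gx), dim(gy)), pixel_size_um > 0)
  if (unit == "per_um") {
    gx <- gx * pixel_size_um
    gy <- gy * pixel_size_um
  }
  structure(list(gx = gx, gy = gy, pixel_size_um = pixel_size_um),
            class = "phase_gradient_pair")
}

as_gradient_pair <- function(g, pixel_size_um = 1, unit = "per_pixel") {
  if (inherits(g, "phase_gradient_pair")) g
  else phase_gradient_pair(g$gx, g$gy, pixel_size_um, unit)
}

new_phase_map <- function(phi, residual, pixel_size_um, method, extra = list()) {
  structure(c(list(phi = phi, residual = residual,
                   pixel_size_um = pixel_size_um, method = method), extra),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("phase_map (%s): %d x %d px, range [%.4g, %.4g] rad\n",
              x$method, nrow(x$phi), ncol(x$phi), min(x$phi), max(x$phi)))
  invisible(x)
}

# spectral eigenvalues of the centred-difference derivative, spacing 1 px:
# mode u (0-based) maps to i sin(2 pi u / n). Using the same convention the
# gradients were formed with makes (differentiate, integrate) exactly
# inverse on periodic fields.
fd_eigen <- function(n) 1i * sin(2 * pi * (0:(n - 1)) / n)

#' Fourier-derivative integration of a phase-gradient pair
#'
#' The complex image `gx + i gy` is Fourier transformed, divided by the
#' complex frequency sum, and inverse transformed; the real part is the
#' phase, the imaginary part the reconstruction residual. The zero
#' frequency of the phase transform is set to zero to avoid the divergence,
#' so the offset is lost and must be re-calibrated on object-free areas
#' (`calib_region`). Mirroring in both directions before integrating —
#' plain mirrored derivatives (`"MDI"`) or the antisymmetric mirror of the
#' normal derivative (`"ASDI"`) — imposes Neumann-like boundaries and
#' suppresses the wrap-around artefacts of the periodic transform when the
#' sample touches the field edge; the result is cropped back to the
#' original window.
#'
#' @param g a [phase_gradient_pair()] or list with `gx`, `gy` (rad/pixel).
#' @param boundary `"none"`, `"MDI"`, or `"ASDI"`.
#' @param calib_region logical matrix marking object-free pixels; default
#'   `NULL` leaves the zero-mean convention.
#' @return a `phase_map`: `phi` (rad), `residual` (imaginary part),
#'   `residual_ratio` (summed |Im| over summed |Re|).
#' @export
fourier_integrate <- function(g, boundary = c("none", "MDI", "ASDI"),
                              calib_region = NULL) {
  boundary <- match.arg(boundary)
  g <- as_gradient_pair(g)
  gx <- g$gx; gy <- g$gy
  if (!any(is.finite(gx)) || !any(is.finite(gy)))
    stop_scan("all-invalid gradient input")
  gx[!is.finite(gx)] <- 0
  gy[!is.finite(gy)] <- 0
  nr0 <- nrow(gx); nc0 <- ncol(gx)
  if (boundary != "none") {
    fx <- function(m) m[, nc0:1]
    fy <- function(m) m[nr0:1, ]
    if (boundary == "ASDI") {
      # antisymmetric mirror of the normal derivative: consistent with an
      # even (mirror) extension of the phase itself
      gx <- rbind(cbind(gx, -fx(gx)), cbind(fy(gx), -fy(fx(gx))))
      gy <- rbind(cbind(gy, fx(gy)), cbind(-fy(gy), -fy(fx(gy))))
    } else {
      # plain mirrored derivatives
      gx <- rbind(cbind(gx, fx(gx)), cbind(fy(gx), fy(fx(gx))))
      gy <- rbind(cbind(gy, fx(gy)), cbind(fy(gy), fy(fx(gy))))
    }
  }
  nr <- nrow(gx); nc <- ncol(gx)
  G <- fft(gx + 1i * gy)
  dx <- matrix(fd_eigen(nc), nr, nc, byrow = TRUE)
  dy <- matrix(fd_eigen(nr), nr, nc)
  den <- dx + 1i * dy
  Phi <- G / den
  Phi[Mod(den) < 1e-14] <- 0  # zero frequency (and centred-diff nulls)
  z <- fft(Phi, inverse = TRUE) / (nr * nc)
  phi <- Re(z)[seq_len(nr0), seq_len(nc0)]
  resid <- Im(z)[seq_len(nr0), seq_len(nc0)]
  if (!is.null(calib_region)) phi <- phi - mean(phi[calib_region])
  new_phase_map(phi, resid, g$pixel_size_um, paste0("fourier_", boundary),
                list(residual_ratio = sum(abs(resid)) / sum(abs(phi))))
}

#' Southwell least-squares integration of a phase-gradient pair
#'
#' Iterative finite-difference integration: each pixel is repeatedly
#' replaced by the relaxed average of its neighbours' phase corrected by
#' the measured mid-point gradients, until the largest update falls below
#' `tol`. With the `"jacobi"` scheme the map updates once per sweep and the
#' relaxation `w` must lie in (0, 1]; with `"gauss_seidel"` each pixel
#' updates in place and `w` has an optimal over-relaxation value depending
#' only on the number of measured gradient values N, used as the default:
#' `w = 2 / (1 + sin(pi / (sqrt(N) + 1)))`. Missing neighbours drop out of
#' the average with renormalised counts, and hard discontinuities in the
#' data stay circumscribed instead of contaminating the full field.
#'
#' @inheritParams fourier_integrate
#' @param scheme `"gauss_seidel"` (default) or `"jacobi"`.
#' @param w relaxation factor; `NULL` picks the scheme default.
#' @param max_iter,tol convergence controls (rad).
#' @return a `phase_map` with `iterations` and `converged` (non-convergence
#'   is flagged, the partial result is returned).
#' @export
southwell_integrate <- function(g, scheme = c("gauss_seidel", "jacobi"),
                                w = NULL, max_iter = 1e4, tol = 1e-6,
                                calib_region = NULL) {
  scheme <- match.arg(scheme)
  g <- as_gradient_pair(g)
  n_meas <- sum(is.finite(g$gx)) + sum(is.finite(g$gy))
  if (n_meas == 0) stop_scan("all-invalid gradient input")
  if (is.null(w)) {
    w <- if (scheme == "jacobi") 1
         else 2 / (1 + sin(pi / (sqrt(n_meas / 2) + 1)))
  }
  if (scheme == "jacobi" && (w <= 0 || w > 1))
    stop_scan("jacobi relaxation must lie in the interval ]0, 1]")
  if (scheme == "gauss_seidel" && (w <= 0 || w >= 2))
    stop_scan("gauss_seidel relaxation must lie in ]0, 2[")
  res <- southwell_cpp(g$gx, g$gy, w, scheme == "gauss_seidel",
                       as.integer(max_iter), tol)
  phi <- res$phi
  if (!is.null(calib_region)) phi <- phi - mean(phi[calib_region])
  else phi <- phi - mean(phi)
  if (!res$converged)
    warning("Southwell iteration did not converge (max change ",
            signif(res$max_change, 3), " rad)")
  new_phase_map(phi, matrix(0, nrow(phi), ncol(phi)), g$pixel_size_um,
                paste0("southwell_", scheme),
                list(iterations = res$iterations, converged = res$converged,
                     w = w))
}

#' Convert a phase map to projected thickness
#'
#' `t = phi * lambda / (2 pi delta)` with `lambda = 12.398 / E` Angstrom;
#' output in micrometres.
#'
#' @param phi a `phase_map` or a numeric matrix (rad).
#' @param delta real refractive-index decrement (> 0).
#' @param energy_kev beam energy.
#' @return thickness matrix (um).
#' @export
phase_to_thickness <- function(phi, delta, energy_kev) {
  stopifnot(delta > 0)
  m <- if (inherits(phi, "phase_map")) phi$phi else phi
  lam_um <- xray_wavelength(energy_kev)
  m * lam_um / (2 * pi * delta)
}
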