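#' Phantom specification
#'
#' A phantom is a set of cylindrical primitives (wires and capillary shells)
#' with optical and fluorescence properties, sampled on a square grid. All
#' lengths are micrometres; `delta` and `beta` are the refractive-index
#' decrement and absorption index of n = 1 - delta + i beta.
#'
#' @param primitives list of primitives from [wire_primitive()] /
#'   [shell_primitive()].
#' @param pixel_size_um grid pixel size.
#' @param energy_kev beam energy.
#' @param grid_n grid side length in pixels (square grid).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(primitives, pixel_size_um, energy_kev, grid_n) {
  stopifnot(pixel_size_um > 0, energy_kev > 0, grid_n >= 1)
  for (p in primitives) {
    stopifnot(p$diameter > 0, p$delta >= 0, p$beta >= 0)
    if (!is.null(p$wall)) stopifnot(p$wall > 0, 2 * p$wall < p$diameter)
  }
  structure(list(primitives = primitives, pixel_size_um = pixel_size_um,
                 energy_kev = energy_kev, grid_n = as.integer(grid_n),
                 wavelength_um = xray_wavelength(energy_kev)),
            class = "phantom_spec")
}

#' Phantom primitives
#'
#' `wire_primitive()` is a solid cylinder, `shell_primitive()` a hollow
#' cylindrical shell (capillary wall). For 2D scans the cylinder axis lies
#' in the scan plane (`orientation` `"vertical"` or `"horizontal"`); for a
#' tomographic virtual slice the axis is the rotation axis and only the
#' in-plane `center` matters.
#'
#' @param diameter outer diameter (um).
#' @param center `c(x, y)` axis position (um) in the grid frame.
#' @param orientation axis orientation for 2D scans.
#' @param delta,beta refractive-index decrement and absorption index.
#' @param wall shell wall thickness (um), `shell_primitive()` only.
#' @param element optional element label (enables an XRF line).
#' @param line_kev fluorescence line energy (keV).
#' @param emissivity fluorescence counts per um of path through the element.
#' @param scatter relative dark-field scatter strength (counts per um path).
#' @return a primitive list usable in [phantom_spec()].
#' @export
wire_primitive <- function(diameter, center = c(0, 0),
                           orientation = c("vertical", "horizontal"),
                           delta = 0, beta = 0, element = NULL,
                           line_kev = NA_real_, emissivity = 0, scatter = 0) {
  list(type = "wire", diameter = diameter, center = center,
       orientation = match.arg(orientation), delta = delta, beta = beta,
       element = element, line_kev = line_kev, emissivity = emissivity,
       scatter = scatter)
}

#' @rdname wire_primitive
#' @export
shell_primitive <- function(diameter, wall, center = c(0, 0),
                            orientation = c("vertical", "horizontal"),
                            delta = 0, beta = 0, element = NULL,
                            line_kev = NA_real_, emissivity = 0, scatter = 0) {
  list(type = "shell", diameter = diameter, wall = wall, center = center,
       orientation = match.arg(orientation), delta = delta, beta = beta,
       element = element, line_kev = line_kev, emissivity = emissivity,
       scatter = scatter)
}

# chord length through a cylinder of diameter D at distance d from the axis
chord_length <- function(d, D) {
  r2 <- pmax((D / 2)^2 - d^2, 0)
  2 * sqrt(r2)
}

# grid coordinates (um): x along columns, y along rows (y up, row 1 on top)
grid_coords <- function(n, pixel) {
  cc <- ((1:n) - (n + 1) / 2) * pixel
  list(x = cc, y = rev(cc))
}

#' Projected thickness maps of a phantom
#'
#' Beam along the viewing axis (z for 2D scans): for a wire of diameter D
#' the projected thickness at in-plane distance d from its axis is
#' `2 * sqrt((D/2)^2 - d^2)` (0 beyond the radius); a shell contributes the
#' outer chord minus the inner chord, so twice the wall thickness on the
#' centreline.
#'
#' @param phantom a [phantom_spec()].
#' @param grid_n optional grid override (pixels).
#' @return list with `per_primitive` (list of matrices, um) and `total`.
#' @export
thickness_map <- function(phantom, grid_n = NULL) {
  n <- grid_n %||% phantom$grid_n
  g <- grid_coords(n, phantom$pixel_size_um)
  x <- matrix(g$x, n, n, byrow = TRUE)
  y <- matrix(g$y, n, n)
  per <- lapply(phantom$primitives, function(p) {
    d <- switch(p$orientation,
                vertical = abs(x - p$center[1]),    # axis along y
                horizontal = abs(y - p$center[2]))  # axis along x
    t <- chord_length(d, p$diameter)
    if (identical(p$type, "shell"))
      t <- t - chord_length(d, p$diameter - 2 * p$wall)
    t
  })
  total <- Reduce(`+`, per, matrix(0, n, n))
  list(per_primitive = per, total = total)
}

#' Phase map and finite-difference gradient ground truth
#'
#' The projected phase is `phi = 2 pi delta t / lambda` summed over
#' primitives. Gradients are centred finite differences of phi (one-sided at
#' the borders), so integration tests are discretisation-consistent; the
#' analytic derivative of a chord diverges at the wire edge.
#'
#' @inheritParams thickness_map
#' @return list: `phi` (rad), `gx`, `gy` (rad/um), `pixel_size_um`,
#'   `thickness` (the per-primitive thickness result).
#' @export
phase_and_gradients <- function(phantom, grid_n = NULL) {
  n <- grid_n %||% phantom$grid_n
  tm <- thickness_map(phantom, n)
  lam <- phantom$wavelength_um
  phi <- matrix(0, n, n)
  for (k in seq_along(phantom$primitives)) {
    p <- phantom$primitives[[k]]
    phi <- phi + 2 * pi * p$delta * tm$per_primitive[[k]] / lam
  }
  gr <- fd_gradient(phi, h = phantom$pixel_size_um)
  list(phi = phi, gx = gr$gx, gy = gr$gy,
       pixel_size_um = phantom$pixel_size_um, thickness = tm)
}

#' Nylon-wire phantom presets
#'
#' The validation wires: nylon, delta = 1.63e-6 at 14 keV. `"large"` is the
#' 100 um vertical wire, `"small"` the 50 um horizontal one. Default grid:
#' 256 x 256 pixels of 0.5 um, wire centred, which samples the large wire
#' with 200 points across its diameter.
#'
#' @param preset `"large"` or `"small"`.
#' @param grid_n grid side (pixels).
#' @param pixel_size_um grid pixel size.
#' @return a [phantom_spec()].
#' @export
wire_phantom <- function(preset = c("large", "small"), grid_n = 256,
                         pixel_size_um = 0.5) {
  preset <- match.arg(preset)
  prim <- switch(preset,
    large = wire_primitive(100, orientation = "vertical",
                           delta = 1.63e-6, beta = 2e-10),
    small = wire_primitive(50, orientation = "horizontal",
                           delta = 1.63e-6, beta = 2e-10))
  phantom_spec(list(prim), pixel_size_um, 14, grid_n)
}

#' Capillary test-sample phantom preset
#'
#' Cross-section of the tomography test object: a glass capillary of 500 um
#' outer diameter containing two 100 um and one 50 um nylon fibres and a
#' 40 um copper wire. The tomographic preset scans 500 detector positions of
#' 4 um step; the full angular set is 500 projections equally spaced over
#' 360 degrees and the sparse subset is 30 projections (12 degrees apart).
#'
#' @param grid_n tomogram grid side (pixels).
#' @param pixel_size_um detector step / tomogram pixel (um).
#' @return a [phantom_spec()] with an `angles` attribute:
#'   `attr(, "angles_full")` (500) and `attr(, "angles_sub")` (30), degrees.
#' @export
capillary_phantom <- function(grid_n = 500, pixel_size_um = 4) {
  prims <- list(
    shell_primitive(500, wall = 20, center = c(0, 0),
                    delta = 3.0e-6, beta = 5e-9, element = "Si",
                    line_kev = 1.74, emissivity = 0.4, scatter = 1.0),
    wire_primitive(100, center = c(-120, 60), delta = 1.63e-6, beta = 2e-10,
                   scatter = 0.6),
    wire_primitive(100, center = c(100, -90), delta = 1.63e-6, beta = 2e-10,
                   scatter = 0.6),
    wire_primitive(50, center = c(30, 120), delta = 1.63e-6, beta = 2e-10,
                   scatter = 0.6),
    wire_primitive(40, center = c(-40, -30), delta = 2.5e-5, beta = 5e-7,
                   element = "Cu", line_kev = 8.048, emissivity = 5,
                   scatter = 3.0)
  )
  ph <- phantom_spec(prims, pixel_size_um, 14, grid_n)
  attr(ph, "angles_full") <- seq(0, 360, length.out = 501)[1:500]
  attr(ph, "angles_sub") <- seq(0, 360 - 12, by = 12)
  ph
}

#' Cross-section property map of a phantom (tomography ground truth)
#'
#' Rasterises the in-plane discs of the phantom onto the grid, painting each
#' pixel with the chosen per-primitive property (later primitives overwrite
#' earlier ones where discs overlap, so inclusions sit inside the shell).
#'
#' @param phantom a [phantom_spec()].
#' @param property `"scatter"`, `"delta"`, `"beta"`, `"emissivity"`, or
#'   `"element"` with `element` naming which line's emissivity to paint.
#' @param element element label used when `property = "element"`.
#' @inheritParams thickness_map
#' @return numeric matrix `grid_n x grid_n`.
#' @export
phantom_slice <- function(phantom, property = "scatter", element = NULL,
                          grid_n = NULL) {
  n <- grid_n %||% phantom$grid_n
  g <- grid_coords(n, phantom$pixel_size_um)
  x <- matrix(g$x, n, n, byrow = TRUE)
  y <- matrix(g$y, n, n)
  img <- matrix(0, n, n)
  for (p in phantom$primitives) {
    d2 <- (x - p$center[1])^2 + (y - p$center[2])^2
    inside <- d2 <= (p$diameter / 2)^2
    if (identical(p$type, "shell"))
      inside <- inside & d2 >= (p$diameter / 2 - p$wall)^2
    val <- switch(property,
      scatter = p$scatter, delta = p$delta, beta = p$beta,
      emissivity = p$emissivity,
      element = if (!is.null(p$element) && identical(p$element, element))
        p$emissivity else 0,
      stop_scan("unknown property: ", property))
    img[inside] <- val
  }
  img
}
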