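# ---- reduction: raw blocks -> modality maps

# drive a per-block accumulator over a handle (streamed), a block list, or a
# raw frame/spectra bundle
reduce_driver <- function(x, init, step, requests = NULL) {
  acc <- init
  if (inherits(x, "scan_handle")) {
    reqs <- requests %||% plan_requests(x)
    it <- iterate_blocks(x, reqs)
    while (!is.null(b <- it$next_block())) acc <- step(acc, b)
  } else if (is.list(x) && length(x) && inherits(x[[1]], "scan_block")) {
    for (b in x) acc <- step(acc, b)
  } else if (inherits(x, "scan_block")) {
    acc <- step(acc, x)
  } else {
    stop_scan("expected a scan handle, scan_block(s)")
  }
  acc
}

# apply hot-pixel repair to every frame of a block (frames: nl x nc x fr x fc)
repair_block_frames <- function(frames, hot) {
  if (is.null(hot) || nrow(hot$pixels) == 0) return(frames)
  d <- dim(frames)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    frames[i, j, , ] <- repair_frame(matrix(frames[i, j, , ], d[3], d[4]), hot)
  frames
}

# sum of frame values over a detector-pixel mask, per scan pixel of a block
block_mask_sum <- function(frames, roi, mask) {
  sub <- frames[, , roi$rows, roi$cols, drop = FALSE]
  d <- dim(sub)
  flat <- matrix(sub, d[1] * d[2], d[3] * d[4])
  colSel <- as.vector(mask)
  rowSums(flat[, colSel, drop = FALSE], na.rm = TRUE)
}

empty_maps <- function(scan_shape) matrix(NA_real_, scan_shape[1], scan_shape[2])

scan_shape_of <- function(x) {
  if (inherits(x, "scan_handle")) return(x$layout$scan_shape)
  if (inherits(x, "scan_block")) x <- list(x)
  if (is.list(x) && length(x) && inherits(x[[1]], "scan_block")) {
    lines <- sort(unique(unlist(lapply(x, `[[`, "lines"))))
    cols <- sort(unique(unlist(lapply(x, `[[`, "cols"))))
    return(c(max(lines), max(cols)))
  }
  stop_scan("cannot infer scan shape")
}

#' Transmission map
#'
#' Per scan pixel, the numerical sum of the (repaired) frame values inside
#' the beam ROI — the absorption-contrast image.
#'
#' @param x scan handle, list of `scan_block`s, or one block.
#' @param illum an `illumination_model` (its `roi` defines the summation
#'   window).
#' @param hot optional `hot_pixel_table`.
#' @param requests optional request plan when `x` is a handle.
#' @return numeric matrix on the scan grid.
#' @export
transmission_map <- function(x, illum, hot = NULL, requests = NULL) {
  shape <- scan_shape_of(x)
  all_mask <- matrix(TRUE, length(illum$roi$rows), length(illum$roi$cols))
  step <- function(acc, b) {
    fr <- repair_block_frames(b$frames, hot)
    acc[b$lines, b$cols] <- block_mask_sum(fr, illum$roi, all_mask)
    acc
  }
  reduce_driver(x, empty_maps(shape), step, requests)
}

#' Dark-field map
#'
#' Per scan pixel, the scattered intensity integrated inside the ROI but
#' outside the transmitted-beam support (`beam_mask`).
#'
#' @inheritParams transmission_map
#' @return numeric matrix on the scan grid.
#' @export
darkfield_map <- function(x, illum, hot = NULL, requests = NULL) {
  shape <- scan_shape_of(x)
  step <- function(acc, b) {
    fr <- repair_block_frames(b$frames, hot)
    acc[b$lines, b$cols] <- block_mask_sum(fr, illum$roi, !illum$beam_mask)
    acc
  }
  reduce_driver(x, empty_maps(shape), step, requests)
}

#' Differential phase contrast maps
#'
#' Per scan pixel the centroid of the transmitted beam inside the ROI is
#' computed along the horizontal and vertical detector directions; the
#' displacement from a reference centroid is converted to refraction angle
#' `alpha = shift * p / L` and then to phase gradient
#' `dphi/dx = 2 pi alpha / lambda`. Scanning DPC measures the gradient
#' directly, so no phase wrapping can occur.
#'
#' The reference centroid defaults to the per-scan median of the centroids
#' (an estimate of the unperturbed beam position); pass `reference` to use a
#' background region instead.
#'
#' @inheritParams transmission_map
#' @param geometry list with `pixel_pitch_um`, `distance_mm`, `energy_kev`.
#' @param unit `"gradient"` (rad/um, default), `"angle_rad"`, or
#'   `"shift_px"`.
#' @param reference optional `c(row, col)` reference centroid (detector
#'   pixels, ROI frame) or logical scan mask of background pixels.
#' @return list with `dpc_x`, `dpc_y` matrices, the `unit`, `geometry`, and
#'   `reference` actually used.
#' @export
dpc_map <- function(x, illum, hot = NULL, geometry = NULL,
                    unit = c("gradient", "angle_rad", "shift_px"),
                    reference = NULL, requests = NULL) {
  unit <- match.arg(unit)
  if (unit != "shift_px" && is.null(geometry))
    stop_scan("geometry (pixel_pitch_um, distance_mm, energy_kev) needed for ",
              unit)
  shape <- scan_shape_of(x)
  rr <- matrix(seq_along(illum$roi$rows), length(illum$roi$rows),
               length(illum$roi$cols))
  cc <- matrix(seq_along(illum$roi$cols), length(illum$roi$rows),
               length(illum$roi$cols), byrow = TRUE)
  step <- function(acc, b) {
    fr <- repair_block_frames(b$frames, hot)
    sub <- fr[, , illum$roi$rows, illum$roi$cols, drop = FALSE]
    d <- dim(sub)
    flat <- matrix(sub, d[1] * d[2], d[3] * d[4])
    tot <- rowSums(flat, na.rm = TRUE)
    cr <- rowSums(sweep(flat, 2, as.vector(rr), `*`), na.rm = TRUE) / tot
    ccol <- rowSums(sweep(flat, 2, as.vector(cc), `*`), na.rm = TRUE) / tot
    bad <- !is.finite(tot) | tot <= 0
    cr[bad] <- NA; ccol[bad] <- NA
    acc$cr[b$lines, b$cols] <- matrix(cr, d[1], d[2])
    acc$cc[b$lines, b$cols] <- matrix(ccol, d[1], d[2])
    acc
  }
  acc <- reduce_driver(x, list(cr = empty_maps(shape), cc = empty_maps(shape)),
                       step, requests)
  if (is.null(reference)) {
    ref <- c(median(acc$cr, na.rm = TRUE), median(acc$cc, na.rm = TRUE))
  } else if (is.matrix(reference) && is.logical(reference)) {
    ref <- c(median(acc$cr[reference], na.rm = TRUE),
             median(acc$cc[reference], na.rm = TRUE))
  } else {
    ref <- reference
  }
  shift_r <- acc$cr - ref[1]
  shift_c <- acc$cc - ref[2]
  conv <- switch(unit,
    shift_px = 1,
    angle_rad = geometry$pixel_pitch_um / (geometry$distance_mm * 1e3),
    gradient = {
      lam <- xray_wavelength(geometry$energy_kev)
      (geometry$pixel_pitch_um / (geometry$distance_mm * 1e3)) * 2 * pi / lam
    })
  list(dpc_x = shift_c * conv, dpc_y = shift_r * conv, unit = unit,
       geometry = geometry, reference = ref)
}

#' XRF region-of-interest elemental maps
#'
#' Per scan pixel and spectral ROI, the summed counts over the channel
#' range — the peak area without background subtraction (deconvolution is
#' delegated to dedicated fitting software).
#'
#' @param x scan handle, 3D spectra array, or list of `scan_block`s.
#' @param channel_ranges list of inclusive `c(lo, hi)` 0-based channel
#'   ranges (see [select_spectral_rois()]); names label the output maps.
#' @param detector XRF detector index.
#' @return named list of matrices on the scan grid.
#' @export
xrf_roi_maps <- function(x, channel_ranges, detector = 1L) {
  if (is.array(x) && length(dim(x)) == 3) {
    sp <- x
    lapply(channel_ranges, function(rg)
      apply(sp[, , (rg[1] + 1):(rg[2] + 1), drop = FALSE], c(1, 2), sum))
  } else {
    shape <- scan_shape_of(x)
    init <- lapply(channel_ranges, function(rg) empty_maps(shape))
    step <- function(acc, b) {
      sp <- b$spectra[[detector]]
      for (k in seq_along(channel_ranges)) {
        rg <- channel_ranges[[k]]
        acc[[k]][b$lines, b$cols] <-
          apply(sp[, , (rg[1] + 1):(rg[2] + 1), drop = FALSE], c(1, 2), sum)
      }
      acc
    }
    reduce_driver(x, init, step)
  }
}

#' Bundle reduced maps into a modality set
#'
#' @param transmission,darkfield matrices on the scan grid.
#' @param dpc result of [dpc_map()] (or `NULL`).
#' @param elemental named list of elemental maps.
#' @param meta free-form metadata list.
#' @return object of class `modality_maps`; `valid` marks pixels finite in
#'   every constituent map.
#' @export
modality_maps <- function(transmission = NULL, darkfield = NULL, dpc = NULL,
                          elemental = list(), meta = list()) {
  maps <- c(list(transmission = transmission, darkfield = darkfield,
                 dpc_x = dpc$dpc_x, dpc_y = dpc$dpc_y), elemental)
  maps <- maps[!vapply(maps, is.null, logical(1))]
  if (!length(maps)) stop_scan("no maps given")
  valid <- Reduce(`&`, lapply(maps, is.finite))
  structure(list(transmission = transmission, darkfield = darkfield,
                 dpc_x = dpc$dpc_x, dpc_y = dpc$dpc_y,
                 dpc_unit = dpc$unit, elemental = elemental,
                 valid = valid, meta = c(meta, list(geometry = dpc$geometry))),
            class = "modality_maps")
}

#' @export
print.modality_maps <- function(x, ...) {
  nm <- c(names(Filter(Negate(is.null),
                       x[c("transmission", "darkfield", "dpc_x", "dpc_y")])),
          names(x$elemental))
  d <- dim(x$valid)
  cat("modality_maps:", d[1], "x", d[2], "scan pixels;",
      paste(nm, collapse = ", "), "\n")
  invisible(x)
}

#' Export modality maps as 32-bit TIFF files
#'
#' One TIFF (plus JSON sidecar) per modality, named
#' `<prefix>_<modality>.tif`.
#'
#' @param maps a `modality_maps`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of written paths.
#' @export
export_modality_tiffs <- function(maps, dir, prefix = "map") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  base <- Filter(Negate(is.null),
                 maps[c("transmission", "darkfield", "dpc_x", "dpc_y")])
  for (nm in names(base)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    write_map_tiff(base[[nm]], p, meta = list(modality = nm))
    out <- c(out, p)
  }
  for (nm in names(maps$elemental)) {
    p <- file.path(dir, sprintf("%s_xrf_%s.tif", prefix, nm))
    write_map_tiff(maps$elemental[[nm]], p,
                   meta = list(modality = "xrf", element = nm))
    out <- c(out, p)
  }
  out
}

#' Import externally fitted elemental maps
#'
#' Loads fitted maps (e.g. per-element intensities from a spectrum-fitting
#' package) from TIFF files back onto the scan grid for further processing.
#' Non-finite pixels are kept as `NA` and flagged invalid downstream.
#'
#' @param paths character vector of TIFF paths; names label the maps.
#' @param scan_shape expected `c(lines, cols)`; mismatch is an error.
#' @return named list of matrices.
#' @export
import_fitted_maps <- function(paths, scan_shape) {
  nm <- names(paths) %||% tools::file_path_sans_ext(basename(paths))
  out <- lapply(paths, read_map_tiff)
  names(out) <- nm
  for (k in seq_along(out)) {
    if (!identical(dim(out[[k]]), as.integer(scan_shape)))
      stop_scan("fitted map ", nm[k], " shape ",
                paste(dim(out[[k]]), collapse = "x"),
                " does not match scan shape ",
                paste(scan_shape, collapse = "x"))
    out[[k]][!is.finite(out[[k]])] <- NA_real_
  }
  out
}

#' Export a spectrum in mca text form
#'
#' Plain-text single-spectrum exchange format with the energy calibration in
#' the header, consumed by XRF peak-fitting software; round-trips through
#' [read_spectrum_mca()].
#'
#' @param spectrum numeric vector of channel counts.
#' @param calibration an `energy_calibration` (or `NULL`).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_spectrum_mca <- function(spectrum, calibration, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("<<PMCA SPECTRUM>>",
               paste0("TAG - scanxray"),
               paste0("CHANNELS - ", length(spectrum))), con)
  if (!is.null(calibration)) {
    writeLines(c("<<CALIBRATION>>",
                 "LABEL - Channel Energy",
                 sprintf("0 %.10g", channel_to_energy(calibration, 0)),
                 sprintf("1 %.10g", channel_to_energy(calibration, 1))), con)
  }
  writeLines("<<DATA>>", con)
  writeLines(format(spectrum, scientific = FALSE, trim = TRUE), con)
  writeLines("<<END>>", con)
  invisible(path)
}

#' @rdname export_spectrum_mca
#' @return `read_spectrum_mca()`: list with `counts` and `calibration`.
#' @export
read_spectrum_mca <- function(path) {
  ln <- readLines(path)
  d0 <- which(ln == "<<DATA>>")
  d1 <- which(ln == "<<END>>")
  if (!length(d0) || !length(d1)) stop_scan("malformed mca file: ", path)
  counts <- as.numeric(ln[(d0 + 1):(d1 - 1)])
  cal <- NULL
  c0 <- which(ln == "<<CALIBRATION>>")
  if (length(c0)) {
    p0 <- as.numeric(strsplit(ln[c0 + 2], " ")[[1]])
    p1 <- as.numeric(strsplit(ln[c0 + 3], " ")[[1]])
    gain <- (p1[2] - p0[2]) / (p1[1] - p0[1])
    cal <- structure(list(gain = gain, offset = p0[2] - gain * p0[1]),
                     class = "energy_calibration")
  }
  list(counts = counts, calibration = cal)
}
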