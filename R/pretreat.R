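# ---- pre-treatment: beam ROI, illumination mask, hot pixels, XRF calibration

# accept a scan handle, a list of scan_blocks, or a raw 4D array and return
# frames as a 4D array (optionally subsampled scan pixels)
as_frames_array <- function(x) {
  if (inherits(x, "scan_handle")) return(read_scan(x)$frames)
  if (inherits(x, "scan_block")) return(x$frames)
  if (is.list(x) && length(x) && inherits(x[[1]], "scan_block")) {
    stop_scan("pass blocks one at a time or use the streaming reducers")
  }
  if (is.array(x) && length(dim(x)) == 4) return(x)
  stop_scan("expected a scan handle or a 4D frame array")
}

#' Automatic detector ROI from a scan subsample
#'
#' Reads a uniformly distributed subsample of the transmission frames
#' (default 10% of the scan pixels), sums them, thresholds the sum and
#' returns the bounding rectangle of the above-threshold support — the
#' region holding the whole transmitted and scattered beam — padded by
#' `margin` and clipped to the frame.
#'
#' @param x scan handle or 4D frame array.
#' @param sample_fraction fraction of scan pixels to read (default 0.10).
#' @param min_threshold absolute threshold on the summed frame; default 1%
#'   of its maximum.
#' @param margin padding in detector pixels.
#' @return list with `rows`, `cols` (index ranges) of class `detector_roi`.
#' @export
auto_roi <- function(x, sample_fraction = 0.10, min_threshold = NULL,
                     margin = 2L) {
  if (inherits(x, "scan_handle")) {
    ss <- x$layout$scan_shape
    stride <- max(1L, round(sqrt(1 / sample_fraction)))
    lines <- seq(1L, ss[1], by = stride)
    cols <- seq(1L, ss[2], by = stride)
    frames <- rhdf5::h5read(x$path, x$layout$paths$frames,
                            index = list(lines, cols, NULL, NULL))
    rhdf5::H5close()
  } else {
    frames <- as_frames_array(x)
    d <- dim(frames)
    stride <- max(1L, round(sqrt(1 / sample_fraction)))
    frames <- frames[seq(1L, d[1], by = stride), seq(1L, d[2], by = stride),
                     , , drop = FALSE]
  }
  s <- apply(frames, c(3, 4), sum)
  thr <- min_threshold %||% (0.01 * max(s))
  hit <- which(s > thr, arr.ind = TRUE)
  if (nrow(hit) == 0) stop_scan("no detector pixel above the ROI threshold")
  rows <- range(hit[, 1]); cols <- range(hit[, 2])
  rows <- c(max(1L, rows[1] - margin), min(nrow(s), rows[2] + margin))
  cols <- c(max(1L, cols[1] - margin), min(ncol(s), cols[2] + margin))
  structure(list(rows = rows[1]:rows[2], cols = cols[1]:cols[2]),
            class = "detector_roi")
}

#' Build the illumination mask
#'
#' Within the ROI each frame is thresholded at `min_value`, binarised and
#' summed over the scan: `mask_counts[p]` counts the frames in which
#' detector pixel `p` was illuminated. The transmitted-beam support
#' (`beam_mask`) keeps the pixels illuminated within the
#' `threshold_fraction`–100% band of the mask maximum (default 95%); the
#' remaining ROI pixels integrate the dark-field signal.
#'
#' @param x scan handle or 4D frame array.
#' @param roi a `detector_roi` (default: full frame).
#' @param min_value illumination threshold in counts (default 5 above a zero
#'   pedestal).
#' @param threshold_fraction beam-support band lower edge.
#' @return object of class `illumination_model` with `roi`, `mask_counts`,
#'   `beam_mask`, `threshold_fraction`.
#' @export
build_illumination_mask <- function(x, roi = NULL, min_value = 5,
                                    threshold_fraction = 0.95) {
  frames <- as_frames_array(x)
  d <- dim(frames)
  if (is.null(roi))
    roi <- structure(list(rows = seq_len(d[3]), cols = seq_len(d[4])),
                     class = "detector_roi")
  sub <- frames[, , roi$rows, roi$cols, drop = FALSE]
  if (prod(dim(sub)[1:2]) == 0) stop_scan("empty frame stream")
  counts <- apply(sub > min_value, c(3, 4), sum)
  illumination_model(roi, counts, threshold_fraction)
}

#' @rdname build_illumination_mask
#' @param mask_counts per-ROI-pixel illumination counts.
#' @export
illumination_model <- function(roi, mask_counts, threshold_fraction = 0.95) {
  beam <- mask_counts >= threshold_fraction * max(mask_counts)
  structure(list(roi = roi, mask_counts = mask_counts, beam_mask = beam,
                 threshold_fraction = threshold_fraction),
            class = "illumination_model")
}

#' Detect hot detector pixels
#'
#' Flags pixels significantly different from their neighbourhood using
#' windowed local statistics: a pixel is suspicious in a frame when
#' `|value - local median| > variance_threshold * (local MAD + eps)`, and
#' enters the look-up table when suspicious in at least
#' `persistence` of the sampled frames (photon shot noise is transient,
#' detector defects persist).
#'
#' @param x scan handle, 4D frame array, or 3D array of sampled frames.
#' @param kernel_size odd window size (default 3).
#' @param variance_threshold multiple of the local spread (default 8).
#' @param persistence fraction of frames a pixel must be flagged in.
#' @param eps additive floor on the local spread, in counts.
#' @param max_frames at most this many frames are sampled.
#' @param policy repair policy recorded in the table.
#' @return object of class `hot_pixel_table`: data.frame `row`, `col` plus
#'   the policy.
#' @export
detect_hot_pixels <- function(x, kernel_size = 3L, variance_threshold = 8,
                              persistence = 0.8, eps = 1,
                              max_frames = 64L,
                              policy = c("replace_neighbour_mean", "exclude")) {
  policy <- match.arg(policy)
  if (is.array(x) && length(dim(x)) == 3) {
    stack <- x
  } else {
    fr <- as_frames_array(x)
    d <- dim(fr)
    npix <- d[1] * d[2]
    pick <- unique(round(seq(1, npix, length.out = min(max_frames, npix))))
    stack <- array(0, c(d[3], d[4], length(pick)))
    for (q in seq_along(pick)) {
      i <- (pick[q] - 1) %% d[1] + 1
      j <- (pick[q] - 1) %/% d[1] + 1
      stack[, , q] <- fr[i, j, , ]
    }
  }
  d <- dim(stack)
  if (kernel_size > min(d[1:2])) stop_scan("kernel larger than frame")
  votes <- matrix(0L, d[1], d[2])
  for (q in seq_len(d[3])) {
    st <- local_stats_cpp(stack[, , q], as.integer(kernel_size))
    dev <- abs(stack[, , q] - st$median)
    votes <- votes + (dev > variance_threshold * (st$mad + eps))
  }
  hit <- which(votes >= persistence * d[3], arr.ind = TRUE)
  tab <- data.frame(row = as.integer(hit[, 1]), col = as.integer(hit[, 2]))
  tab <- tab[!duplicated(tab), , drop = FALSE]
  structure(list(pixels = tab, policy = policy), class = "hot_pixel_table")
}

#' @rdname detect_hot_pixels
#' @param pixels data.frame with `row`, `col` detector coordinates.
#' @export
hot_pixel_table <- function(pixels = data.frame(row = integer(),
                                                col = integer()),
                            policy = c("replace_neighbour_mean", "exclude")) {
  policy <- match.arg(policy)
  if (anyDuplicated(pixels)) stop_scan("duplicate hot-pixel coordinates")
  structure(list(pixels = pixels, policy = policy), class = "hot_pixel_table")
}

#' Repair a detector frame using a hot-pixel table
#'
#' Policy `"replace_neighbour_mean"` overwrites each listed pixel with the
#' mean of its non-hot 8-neighbours; `"exclude"` sets it to `NA` so every
#' downstream sum and centroid skips it.
#'
#' @param frame numeric matrix.
#' @param table a `hot_pixel_table`.
#' @return repaired frame.
#' @export
repair_frame <- function(frame, table) {
  px <- table$pixels
  if (nrow(px) == 0) return(frame)
  bad <- matrix(FALSE, nrow(frame), ncol(frame))
  bad[cbind(px$row, px$col)] <- TRUE
  out <- frame
  if (identical(table$policy, "exclude")) {
    out[bad] <- NA_real_
    return(out)
  }
  for (k in seq_len(nrow(px))) {
    r <- px$row[k]; c <- px$col[k]
    rs <- max(1, r - 1):min(nrow(frame), r + 1)
    cs <- max(1, c - 1):min(ncol(frame), c + 1)
    nb <- frame[rs, cs]
    keep <- !bad[rs, cs]
    keep[which(rs == r), which(cs == c)] <- FALSE
    out[r, c] <- mean(nb[keep])
  }
  out
}

#' Sum spectrum of a fluorescence detector
#'
#' Channel-wise sum over the selected scan pixels, one spectrum per
#' detector.
#'
#' @param x scan handle or 3D spectra array (lines x cols x channels).
#' @param detector 1-based XRF detector index (handles only).
#' @param selection `"all"` or `list(lines =, cols =)`.
#' @return numeric vector of channel sums.
#' @export
sum_spectrum <- function(x, detector = 1L, selection = "all") {
  if (inherits(x, "scan_handle")) {
    if (x$layout$n_xrf_detectors < detector)
      stop_scan("scan has no XRF detector ", detector)
    sp <- rhdf5::h5read(x$path, x$layout$paths$spectra[detector])
    rhdf5::H5close()
  } else if (is.array(x) && length(dim(x)) == 3) {
    sp <- x
  } else stop_scan("expected a scan handle or 3D spectra array")
  if (!identical(selection, "all"))
    sp <- sp[selection$lines, selection$cols, , drop = FALSE]
  apply(sp, 3, sum)
}

#' Energy calibration from reference lines
#'
#' Least-squares line `energy = offset + gain * channel` through at least
#' two identified X-ray lines; exact for two points.
#'
#' @param lines data.frame (or 2-column matrix) with `channel`, `energy_kev`.
#' @return object of class `energy_calibration` with `gain` (keV/channel)
#'   and `offset` (keV).
#' @export
calibrate_energy <- function(lines) {
  lines <- as.data.frame(lines)
  names(lines)[1:2] <- c("channel", "energy_kev")
  if (nrow(lines) < 2)
    stop_scan("at least two known X-ray lines are required")
  if (anyDuplicated(lines$channel))
    stop_scan("duplicate channels in calibration lines")
  fit <- lm(energy_kev ~ channel, data = lines)
  structure(list(gain = unname(coef(fit)[2]), offset = unname(coef(fit)[1])),
            class = "energy_calibration")
}

#' @export
print.energy_calibration <- function(x, ...) {
  cat(sprintf("energy calibration: E[keV] = %.6g + %.6g * channel\n",
              x$offset, x$gain))
  invisible(x)
}

channel_to_energy <- function(cal, channel) cal$offset + cal$gain * channel
energy_to_channel <- function(cal, energy) (energy - cal$offset) / cal$gain

#' Convert energy windows to spectral channel ranges
#'
#' Each `(E_low, E_high)` window in keV maps through the calibration to an
#' inclusive channel range used by [xrf_roi_maps()].
#'
#' @param calibration an `energy_calibration`.
#' @param rois list of `c(E_low, E_high)` pairs (keV).
#' @param n_channels optional channel count for upper clipping.
#' @return list of integer ranges `c(lo, hi)` (0-based channels).
#' @export
select_spectral_rois <- function(calibration, rois, n_channels = NULL) {
  lapply(rois, function(w) {
    stopifnot(length(w) == 2, w[1] <= w[2])
    # channels are bins of width `gain` centred on their nominal energy: the
    # window keeps every channel whose bin it overlaps
    lo <- round(energy_to_channel(calibration, w[1]))
    hi <- round(energy_to_channel(calibration, w[2]))
    if (hi < 0) stop_scan("energy window entirely below channel 0")
    lo <- max(0L, as.integer(lo))
    hi <- as.integer(hi)
    if (!is.null(n_channels)) hi <- min(hi, n_channels - 1L)
    if (hi < lo) stop_scan("energy window narrower than one channel")
    c(lo, hi)
  })
}

#' Serialize pre-treatment models to a sidecar file
#'
#' Writes (or reads back) the illumination model and hot-pixel table as a
#' plain JSON sidecar, for reuse across runs on the same acquisition.
#'
#' @param illum an `illumination_model` (or `NULL`).
#' @param hot a `hot_pixel_table` (or `NULL`).
#' @param path sidecar path (`.json`).
#' @return `write_pretreatment()`: the path; `read_pretreatment()`: a list
#'   with `illum` and `hot`.
#' @export
write_pretreatment <- function(illum, hot, path) {
  payload <- list()
  if (!is.null(illum))
    payload$illumination <- list(
      rows = illum$roi$rows, cols = illum$roi$cols,
      mask_counts = as.vector(illum$mask_counts),
      dim = dim(illum$mask_counts),
      threshold_fraction = illum$threshold_fraction)
  if (!is.null(hot))
    payload$hot_pixels <- list(row = hot$pixels$row, col = hot$pixels$col,
                               policy = hot$policy)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pretreatment
#' @export
read_pretreatment <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(illum = NULL, hot = NULL)
  if (!is.null(p$illumination)) {
    il <- p$illumination
    roi <- structure(list(rows = il$rows, cols = il$cols),
                     class = "detector_roi")
    out$illum <- illumination_model(
      roi, matrix(il$mask_counts, il$dim[1], il$dim[2]),
      il$threshold_fraction)
  }
  if (!is.null(p$hot_pixels)) {
    out$hot <- hot_pixel_table(
      data.frame(row = as.integer(p$hot_pixels$row),
                 col = as.integer(p$hot_pixels$col)),
      p$hot_pixels$policy)
  }
  out
}
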