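# ---- correction: normalisation, regridding, referencing, axis alignment

#' Normalise count modalities by the incoming-beam monitor
#'
#' Transmission, dark-field and elemental maps are divided pixel-wise by the
#' monitor scaled to its mean (magnitudes preserved). DPC is left untouched:
#' a centroid is invariant under intensity scaling. Pixels with
#' non-positive monitor are invalidated.
#'
#' @param maps a [modality_maps()].
#' @param monitor matrix on the scan grid.
#' @return corrected `modality_maps`.
#' @export
normalize_by_monitor <- function(maps, monitor) {
  stopifnot(inherits(maps, "modality_maps"))
  bad <- !is.finite(monitor) | monitor <= 0
  rel <- monitor / mean(monitor[!bad])
  rel[bad] <- NA_real_
  for (nm in c("transmission", "darkfield"))
    if (!is.null(maps[[nm]])) maps[[nm]] <- maps[[nm]] / rel
  maps$elemental <- lapply(maps$elemental, function(m) m / rel)
  maps$valid <- maps$valid & !bad
  maps
}

#' Virtual-grid regridding of jittered scan positions
#'
#' Continuous-motion scans have unequal measured pixel extents; every map is
#' reassigned to a perfect uniform grid whose pixel height/width is the mean
#' of the measured extents. Grid cells hit by several measured pixels are
#' averaged; empty cells are filled from their neighbourhood, and a 3x3
#' median smoothing pass is applied only where aberrant values appear
#' (filled cells and cells deviating more than 3 local MADs).
#'
#' @param maps a [modality_maps()].
#' @param pos_x,pos_y measured positions (same physical unit, matrices on
#'   the scan grid).
#' @return `modality_maps` on the virtual grid, with a `virtual_grid` entry
#'   in `meta` (pixel sizes, origin, fill diagnostics).
#' @export
regrid_virtual <- function(maps, pos_x, pos_y) {
  stopifnot(inherits(maps, "modality_maps"))
  dx <- mean(abs(diff(t(pos_x))))  # along columns
  dy <- mean(abs(diff(pos_y)))     # along rows
  if (!is.finite(dx) || dx <= 0 || !is.finite(dy) || dy <= 0)
    stop_scan("degenerate measured positions")
  x0 <- min(pos_x); y0 <- min(pos_y)
  ci <- pmin(pmax(round((pos_x - x0) / dx), 0), ncol(pos_x) - 1) + 1L
  ri <- pmin(pmax(round((pos_y - y0) / dy), 0), nrow(pos_y) - 1) + 1L
  nr <- nrow(pos_y); nc <- ncol(pos_x)
  cell <- (ci - 1L) * nr + ri
  regrid_one <- function(m) {
    ok <- is.finite(m)
    num <- tapply_sum(cell[ok], m[ok], nr * nc)
    den <- tapply_sum(cell[ok], rep(1, sum(ok)), nr * nc)
    out <- matrix(num / den, nr, nc)
    filled <- matrix(den == 0, nr, nc)
    if (any(filled)) out <- fill_empty_cells(out)
    # only none- or multi-hit cells can carry aberrant values; one-hit cells
    # are measured data and stay untouched
    smooth_aberrant(out, filled, matrix(den > 1, nr, nc))
  }
  for (nm in c("transmission", "darkfield", "dpc_x", "dpc_y"))
    if (!is.null(maps[[nm]])) maps[[nm]] <- regrid_one(maps[[nm]])
  maps$elemental <- lapply(maps$elemental, regrid_one)
  maps$valid <- matrix(TRUE, nr, nc)
  maps$meta$virtual_grid <- list(dx = dx, dy = dy, x0 = x0, y0 = y0)
  maps
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

fill_empty_cells <- function(m) {
  bad <- which(!is.finite(m), arr.ind = TRUE)
  for (k in seq_len(nrow(bad))) {
    r <- bad[k, 1]; c <- bad[k, 2]
    nb <- m[max(1, r - 1):min(nrow(m), r + 1),
            max(1, c - 1):min(ncol(m), c + 1)]
    m[r, c] <- median(nb, na.rm = TRUE)
  }
  m
}

smooth_aberrant <- function(m, filled, multi) {
  st <- local_stats_cpp(m, 3L)
  aberr <- filled | (multi & abs(m - st$median) > 3 * (st$mad + 1e-12))
  m[aberr] <- st$median[aberr]
  m
}

#' Background referencing to absolute modalities
#'
#' Absolute absorption/dark-field/phase values need the no-sample reference.
#' In `"auto-edges"` mode an edge detector runs on each row of the
#' transmission map: the object support is bracketed by the first and last
#' strong gradient crossings, and the row reference is the robust mean of
#' the pixels outside it. This requires well isolated objects producing
#' background pixels on both sides of each row; rows without background are
#' flagged (and fall back to the global reference). A manual region
#' (logical mask) is recommended for non-isolated specimens.
#'
#' Transmission and dark-field are divided by the reference; DPC gradients
#' have the row background offset subtracted.
#'
#' @param maps a [modality_maps()].
#' @param mode `"auto-edges"` or a logical background mask on the scan grid.
#' @return list: `maps` (referenced), `reference` (per-row values),
#'   `flagged_rows` (rows lacking background in auto mode).
#' @export
background_reference <- function(maps, mode = "auto-edges") {
  stopifnot(inherits(maps, "modality_maps"))
  tr <- maps$transmission
  if (is.null(tr)) stop_scan("background referencing needs a transmission map")
  nr <- nrow(tr); nc <- ncol(tr)
  bg_mask <- matrix(FALSE, nr, nc)
  flagged <- integer()
  if (is.matrix(mode)) {
    bg_mask <- mode
  } else if (identical(mode, "auto-edges")) {
    ek <- max(2L, nc %/% 10)  # row ends assumed object-free, define the base
    for (i in seq_len(nr)) {
      row <- tr[i, ]
      sm <- if (nc >= 5) runmed(row, 5) else row
      edges <- c(sm[1:ek], sm[(nc - ek + 1):nc])
      base <- median(edges)
      dev <- abs(sm - base)
      noise <- mad(dev[c(1:ek, (nc - ek + 1):nc)], constant = 1.4826)
      thr <- 5 * noise + 1e-6 * max(abs(base), 1)
      inside <- which(dev > thr)
      if (length(inside) == 0) {
        bg_mask[i, ] <- TRUE  # object-free row
      } else {
        # widen by the median-filter half-width: smoothing diffuses edges
        lo <- max(1L, min(inside) - 2L)
        hi <- min(nc, max(inside) + 2L)
        if (lo > 1) bg_mask[i, 1:(lo - 1)] <- TRUE
        if (hi < nc) bg_mask[i, (hi + 1):nc] <- TRUE
        # an object reaching into the baseline window invalidates the row
        if (lo <= ek || hi > nc - ek) flagged <- c(flagged, i)
      }
    }
  } else stop_scan("mode must be 'auto-edges' or a logical mask")
  robust_mean <- function(v) if (length(v)) median(v, na.rm = TRUE) else NA
  ref_row <- function(m) {
    r <- vapply(seq_len(nr), function(i) robust_mean(m[i, bg_mask[i, ]]), 0)
    glob <- robust_mean(m[bg_mask])
    r[!is.finite(r)] <- glob
    r
  }
  refs <- list()
  for (nm in c("transmission", "darkfield")) {
    if (is.null(maps[[nm]])) next
    r <- ref_row(maps[[nm]])
    refs[[nm]] <- r
    maps[[nm]] <- maps[[nm]] / r
  }
  for (nm in c("dpc_x", "dpc_y")) {
    if (is.null(maps[[nm]])) next
    r <- ref_row(maps[[nm]])
    refs[[nm]] <- r
    maps[[nm]] <- maps[[nm]] - r
  }
  list(maps = maps, reference = refs, flagged_rows = unique(flagged),
       background_mask = bg_mask)
}

#' Estimate the rotation axis and wobble from a sinogram
#'
#' Centre-of-mass sine fit: the per-angle centre of mass of each projection
#' of an in-field object traces `c + A sin(theta + psi)` exactly; the fit
#' offset `c` is the rotation centre and the residuals are the per-angle
#' wobble shifts. The linear least-squares fit in `(c, A cos psi, A sin
#' psi)` is followed by one iteratively reweighted pass with Tukey weights
#' to resist noisy projections. A 360-degree sinogram is preferred; for
#' half-turn coverage the sine term is poorly constrained and the result is
#' flagged wide-confidence.
#'
#' @param sino a [sinogram()].
#' @return object of class `axis_fit`: `center` (detector position index
#'   units), `amplitude`, `phase`, `residuals` (wobble, per angle),
#'   `fitted`, `wide_confidence`.
#' @export
estimate_rotation_axis <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  v <- sino$values
  mass <- rowSums(v)
  if (any(mass <= 0)) stop_scan("non-positive projection mass; centre of mass undefined")
  pos <- seq_len(ncol(v))
  com <- as.vector(v %*% pos) / mass
  th <- sino$angles_deg * pi / 180
  X <- cbind(1, sin(th), cos(th))
  w <- rep(1, length(th))
  for (pass in 1:2) {
    fit <- lm.wfit(X, com, w)
    r <- fit$residuals
    s <- mad(r, constant = 1.4826) + 1e-12
    u <- abs(r) / (4.685 * s)
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) { w <- rep(1, length(th)); break }
  }
  cf <- fit$coefficients
  fitted <- as.vector(X %*% cf)
  structure(list(center = unname(cf[1]),
                 amplitude = unname(sqrt(cf[2]^2 + cf[3]^2)),
                 phase = unname(atan2(cf[3], cf[2])),
                 residuals = com - fitted, fitted = fitted,
                 com = com, angles_deg = sino$angles_deg,
                 wide_confidence = diff(range(sino$angles_deg)) < 270),
            class = "axis_fit")
}

#' @export
print.axis_fit <- function(x, ...) {
  cat(sprintf(
    "axis_fit: centre %.3f px, wobble sine amplitude %.3f px, residual RMS %.3f px%s\n",
    x$center, x$amplitude, sqrt(mean(x$residuals^2)),
    if (x$wide_confidence) " [wide confidence: <360 deg coverage]" else ""))
  invisible(x)
}

#' Apply the axis/wobble shift correction to sinograms
#'
#' Shifts each projection by minus its wobble residual and recentres the
#' rotation axis on the sinogram midline (sub-pixel linear interpolation,
#' edge values extended). The fit is typically estimated on the modality
#' with the largest signal contrast (transmission by default) and applied
#' to all modalities, which share the acquisition geometry.
#'
#' @param sinos a [sinogram()] or a list of them (all modalities).
#' @param fit an `axis_fit`.
#' @return corrected sinogram(s), same structure as the input.
#' @export
apply_shift_correction <- function(sinos, fit) {
  one <- inherits(sinos, "sinogram")
  if (one) sinos <- list(sinos)
  for (k in seq_along(sinos)) {
    s <- sinos[[k]]
    stopifnot(inherits(s, "sinogram"))
    mid <- (ncol(s$values) + 1) / 2
    shifts <- (mid - fit$center) - fit$residuals
    s$values <- shift_rows(s$values, shifts)
    s$axis_corrected <- TRUE
    sinos[[k]] <- s
  }
  if (one) sinos[[1]] else sinos
}
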