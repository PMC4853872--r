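# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_scan <- function(..., class = "scanxray_error", data = NULL) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  )
  if (!is.null(data)) cond[names(data)] <- data
  stop(cond)
}

#' Write a matrix as a 32-bit TIFF with a JSON restore sidecar
#'
#' The TIFF container stores samples in \[0, 1\]; values are min/max scaled
#' and the affine restore parameters (`offset`, `scale`) are written to a
#' `<path>.json` sidecar together with any extra metadata, so the companion
#' reader recovers the original values exactly (up to float32 rounding).
#'
#' @param x numeric matrix (NA allowed; stored as zero and flagged in the
#'   sidecar validity bitmap).
#' @param path output file path (`.tif`).
#' @param meta named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(x, path, meta = list()) {
  stopifnot(is.matrix(x))
  na <- !is.finite(x)
  v <- x
  v[na] <- NA
  rng <- range(v, na.rm = !all(na))
  if (all(na) || !is.finite(rng[1])) rng <- c(0, 1)
  scale <- rng[2] - rng[1]
  if (scale <= 0) scale <- 1
  y <- (v - rng[1]) / scale
  y[na] <- 0
  tiff::writeTIFF(y, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  side <- c(list(offset = rng[1], scale = scale, nrow = nrow(x), ncol = ncol(x),
                 na_cells = which(na) - 1L), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a map written by [write_map_tiff()]
#'
#' Plain TIFFs without a sidecar are returned as read (values as stored).
#'
#' @param path TIFF file path.
#' @return numeric matrix with an attribute `meta` carrying sidecar metadata.
#' @export
read_map_tiff <- function(path) {
  if (!file.exists(path)) stop_scan("no such TIFF: ", path)
  y <- tiff::readTIFF(path)
  if (is.array(y) && length(dim(y)) == 3) y <- y[, , 1]
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    x <- y * side$scale + side$offset
    if (length(side$na_cells)) x[side$na_cells + 1L] <- NA_real_
    extra <- side[setdiff(names(side), c("offset", "scale", "nrow", "ncol", "na_cells"))]
    attr(x, "meta") <- extra
    x
  } else {
    y
  }
}

# centred finite differences, one-sided at the borders; h = sample spacing
fd_gradient <- function(phi, h = 1) {
  nr <- nrow(phi); nc <- ncol(phi)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  if (nc >= 3) gx[, 2:(nc - 1)] <- (phi[, 3:nc] - phi[, 1:(nc - 2)]) / (2 * h)
  if (nc >= 2) {
    gx[, 1] <- (phi[, 2] - phi[, 1]) / h
    gx[, nc] <- (phi[, nc] - phi[, nc - 1]) / h
  }
  if (nr >= 3) gy[2:(nr - 1), ] <- (phi[3:nr, ] - phi[1:(nr - 2), ]) / (2 * h)
  if (nr >= 2) {
    gy[1, ] <- (phi[2, ] - phi[1, ]) / h
    gy[nr, ] <- (phi[nr, ] - phi[nr - 1, ]) / h
  }
  list(gx = gx, gy = gy)
}

# circular (periodic) centred differences, used by the spectral oracle tests
fd_gradient_periodic <- function(phi, h = 1) {
  nr <- nrow(phi); nc <- ncol(phi)
  right <- phi[, c(2:nc, 1)]; left <- phi[, c(nc, 1:(nc - 1))]
  down <- phi[c(2:nr, 1), ]; up <- phi[c(nr, 1:(nr - 1)), ]
  list(gx = (right - left) / (2 * h), gy = (down - up) / (2 * h))
}

#' Circular and rectangular region masks
#'
#' Helpers for defining measurement regions (e.g. for [rose_snr()]) on an
#' image grid whose pixel centres are `(col - (n+1)/2) * pixel` horizontally
#' and `((n+1)/2 - row) * pixel` vertically.
#'
#' @param n image side length in pixels.
#' @param center `c(x, y)` centre in physical units.
#' @param radius disc radius in physical units.
#' @param pixel pixel size in physical units.
#' @return logical `n x n` matrix.
#' @export
disc_mask <- function(n, center, radius, pixel = 1) {
  cc <- ((1:n) - (n + 1) / 2) * pixel
  x <- matrix(cc, n, n, byrow = TRUE)
  y <- matrix(rev(cc), n, n)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' @rdname disc_mask
#' @param xlim,ylim rectangle bounds in physical units.
#' @export
rect_mask <- function(n, xlim, ylim, pixel = 1) {
  cc <- ((1:n) - (n + 1) / 2) * pixel
  x <- matrix(cc, n, n, byrow = TRUE)
  y <- matrix(rev(cc), n, n)
  x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]
}

rmse <- function(a, b) sqrt(mean((a - b)^2, na.rm = TRUE))
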