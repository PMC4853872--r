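#' Scan container layout
#'
#' Describes where the datasets of a 2D-scan acquisition live inside a
#' hierarchical (HDF5) container and how their shapes relate. The frames
#' dataset is 4D (`scan_shape` then `frame_shape`), each fluorescence
#' detector's spectra are 3D (`scan_shape` then channels), and positions and
#' monitor are 2D (`scan_shape`).
#'
#' @param scan_shape integer(2): scan lines x columns (or angles x positions
#'   for a tomographic virtual slice).
#' @param frame_shape integer(2): 2D detector rows x columns.
#' @param n_channels XRF channels per spectrum (0 disables XRF datasets).
#' @param n_xrf_detectors number of fluorescence detectors.
#' @param paths named list of dataset paths: `frames`, `spectra` (character
#'   vector, one per detector), `pos_x`, `pos_y`, `monitor`.
#' @return object of class `scan_layout`.
#' @export
scan_layout <- function(scan_shape, frame_shape,
                        n_channels = 0L, n_xrf_detectors = 0L,
                        paths = NULL) {
  scan_shape <- as.integer(scan_shape)
  frame_shape <- as.integer(frame_shape)
  if (length(scan_shape) != 2 || any(scan_shape < 1))
    stop_scan("scan_shape must be two dims >= 1")
  if (length(frame_shape) != 2 || any(frame_shape < 1))
    stop_scan("frame_shape must be two dims >= 1")
  n_xrf_detectors <- as.integer(n_xrf_detectors)
  n_channels <- as.integer(n_channels)
  default_paths <- list(
    frames = "/entry/scan_data/frames",
    spectra = if (n_xrf_detectors > 0)
      sprintf("/entry/scan_data/xrf_%d", seq_len(n_xrf_detectors) - 1L)
    else character(),
    pos_x = "/entry/scan_data/pos_x",
    pos_y = "/entry/scan_data/pos_y",
    monitor = "/entry/scan_data/monitor"
  )
  if (!is.null(paths)) default_paths[names(paths)] <- paths
  structure(list(scan_shape = scan_shape, frame_shape = frame_shape,
                 n_channels = n_channels, n_xrf_detectors = n_xrf_detectors,
                 paths = default_paths),
            class = "scan_layout")
}

#' @export
print.scan_layout <- function(x, ...) {
  cat("scan_layout:", x$scan_shape[1], "x", x$scan_shape[2], "scan pixels;",
      "frames", x$frame_shape[1], "x", x$frame_shape[2], ";",
      x$n_xrf_detectors, "XRF detector(s) x", x$n_channels, "channels\n")
  invisible(x)
}

#' Write a scan acquisition container
#'
#' Fixture/export writer mirroring the NeXus-style layout: one 4D frames
#' dataset, one 3D spectrum dataset per XRF detector, 2D positions and
#' monitor. The file re-opens through [open_scan()] with `layout = "auto"`.
#'
#' @param path output HDF5 file path (overwritten).
#' @param frames 4D array `(lines, cols, det_rows, det_cols)`.
#' @param spectra list of 3D arrays `(lines, cols, channels)`, one per XRF
#'   detector, or `NULL` for a transmission-only scan.
#' @param pos_x,pos_y,monitor 2D matrices `(lines, cols)`; defaults are an
#'   ideal unit grid and a constant monitor.
#' @param layout optional [scan_layout()] fixing dataset paths.
#' @return the path, invisibly.
#' @export
write_scan <- function(path, frames, spectra = NULL, pos_x = NULL,
                       pos_y = NULL, monitor = NULL, layout = NULL) {
  d <- dim(frames)
  if (length(d) != 4) stop_scan("frames must be a 4D array")
  sl <- d[1]; sc <- d[2]
  if (is.null(pos_x)) pos_x <- matrix(rep(seq_len(sc), each = sl), sl, sc)
  if (is.null(pos_y)) pos_y <- matrix(rep(seq_len(sl), sc), sl, sc)
  if (is.null(monitor)) monitor <- matrix(1, sl, sc)
  spectra <- spectra %||% list()
  if (!is.list(spectra)) spectra <- list(spectra)
  for (sp in spectra) {
    if (!identical(dim(sp)[1:2], d[1:2]))
      stop_scan("spectra scan dims inconsistent with frames")
  }
  for (m in list(pos_x, pos_y, monitor)) {
    if (!identical(dim(m), d[1:2]))
      stop_scan("positions/monitor dims inconsistent with frames")
  }
  nch <- if (length(spectra)) dim(spectra[[1]])[3] else 0L
  if (is.null(layout))
    layout <- scan_layout(d[1:2], d[3:4], nch, length(spectra))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5_ensure_group(path, dirname(layout$paths$frames))
  rhdf5::h5write(frames, path, layout$paths$frames)
  if (length(spectra)) {
    for (k in seq_along(spectra)) {
      h5_ensure_group(path, dirname(layout$paths$spectra[k]))
      rhdf5::h5write(spectra[[k]], path, layout$paths$spectra[k])
    }
  }
  h5_ensure_group(path, dirname(layout$paths$pos_x))
  rhdf5::h5write(pos_x, path, layout$paths$pos_x)
  rhdf5::h5write(pos_y, path, layout$paths$pos_y)
  rhdf5::h5write(monitor, path, layout$paths$monitor)
  rhdf5::H5close()
  invisible(path)
}

h5_ensure_group <- function(path, group) {
  if (group %in% c("/", "")) return(invisible())
  parts <- strsplit(sub("^/", "", group), "/")[[1]]
  acc <- ""
  ls <- rhdf5::h5ls(path)
  existing <- paste0(ls$group, ifelse(ls$group == "/", "", "/"), ls$name)
  for (p in parts) {
    acc <- paste0(acc, "/", p)
    if (!(acc %in% existing)) rhdf5::h5createGroup(path, acc)
    existing <- c(existing, acc)
  }
  invisible()
}

#' Open a scan container
#'
#' With `layout = "auto"` the datasets are discovered by array rank and
#' shape consistency rather than by group names: the single 4D dataset is
#' the frame stack; 3D datasets whose leading dims match the scan shape are
#' per-detector spectra; matching 2D datasets are positions and monitor (a
#' path containing "monitor" is preferred for the monitor, otherwise the
#' last 2D dataset is taken). Pass an explicit [scan_layout()] for dialects
#' this heuristic cannot resolve.
#'
#' @param path HDF5 file path.
#' @param layout `"auto"` or a [scan_layout()].
#' @return a scan handle (class `scan_handle`) exposing `$layout`.
#' @export
open_scan <- function(path, layout = "auto") {
  if (!file.exists(path)) stop_scan("no such scan file: ", path)
  ls <- tryCatch(rhdf5::h5ls(path), error = function(e)
    stop_scan("not a readable HDF5 container: ", path))
  ls <- ls[ls$otype == "H5I_DATASET", , drop = FALSE]
  dsets <- paste0(ifelse(ls$group == "/", "", ls$group), "/", ls$name)
  dims <- lapply(strsplit(ls$dim, " x "), function(v) as.integer(v))
  if (identical(layout, "auto")) {
    rank4 <- which(vapply(dims, length, 1L) == 4)
    if (length(rank4) == 0)
      stop_scan("no dataset matching the 4D frame pattern in ", path)
    if (length(rank4) > 1)
      stop_scan("ambiguous: several 4D datasets; pass an explicit layout")
    fdim <- dims[[rank4]]
    ss <- fdim[1:2]
    is3 <- vapply(seq_along(dims), function(i)
      length(dims[[i]]) == 3 && identical(dims[[i]][1:2], ss), logical(1))
    is2 <- vapply(seq_along(dims), function(i)
      length(dims[[i]]) == 2 && identical(dims[[i]][1:2], ss), logical(1))
    sp_paths <- dsets[is3]
    two <- dsets[is2]
    if (any(vapply(dims, length, 1L) %in% 2:3 & !(is2 | is3)))
      stop_scan("dataset shapes inconsistent with the 4D frame scan shape")
    mon <- grep("monitor", two, value = TRUE)
    mon <- if (length(mon)) mon[1] else if (length(two) >= 3) two[length(two)] else NA
    rest <- setdiff(two, mon)
    px <- grep("pos_x|sample_x|/x$", rest, value = TRUE)
    py <- grep("pos_y|sample_y|/y$", rest, value = TRUE)
    px <- if (length(px)) px[1] else if (length(rest) >= 1) rest[1] else NA
    py <- if (length(py)) py[1] else if (length(rest) >= 2) setdiff(rest, px)[1] else NA
    nch <- if (length(sp_paths)) dims[[which(is3)[1]]][3] else 0L
    layout <- scan_layout(ss, fdim[3:4], nch, length(sp_paths),
                          paths = list(frames = dsets[rank4],
                                       spectra = sp_paths,
                                       pos_x = px, pos_y = py, monitor = mon))
  } else {
    stopifnot(inherits(layout, "scan_layout"))
    fd <- dims[[match(layout$paths$frames, dsets)]]
    if (is.null(fd) || !identical(fd, c(layout$scan_shape, layout$frame_shape)))
      stop_scan("frames dataset shape inconsistent with the given layout")
  }
  structure(list(path = path, layout = layout), class = "scan_handle")
}

#' @export
print.scan_handle <- function(x, ...) {
  cat("scan_handle:", x$path, "\n")
  print(x$layout)
  invisible(x)
}

#' Plan ordered read requests over a scan
#'
#' Builds the list of hyperslab read requests the streaming reader will
#' serve, in acquisition (row-major, line-by-line) order. The default block
#' size is one scan line. `low_res = TRUE` selects every second pixel in
#' both scan dimensions for a fast overview pass. Rectangular exclusion
#' masks drop the excluded pixels from the plan.
#'
#' @param handle a `scan_handle` (or `scan_layout`).
#' @param selection `"all"`, or `list(lines =, cols =)` index vectors.
#' @param low_res logical; stride-2 decimation in every scan dimension.
#' @param block_pixels pixels per block, or `"one-line"` (default).
#' @param exclude optional list of rectangles `list(lines = range, cols =
#'   range)` to skip.
#' @return list of `read_request` objects (possibly empty).
#' @export
plan_requests <- function(handle, selection = "all", low_res = FALSE,
                          block_pixels = "one-line", exclude = NULL) {
  layout <- if (inherits(handle, "scan_handle")) handle$layout else handle
  ss <- layout$scan_shape
  if (identical(selection, "all"))
    selection <- list(lines = seq_len(ss[1]), cols = seq_len(ss[2]))
  lines <- as.integer(selection$lines)
  cols <- as.integer(selection$cols)
  if (any(lines < 1 | lines > ss[1]) || any(cols < 1 | cols > ss[2]))
    stop_scan("selection outside scan bounds")
  if (low_res) {
    lines <- lines[seq(1, length(lines), by = 2)]
    cols <- cols[seq(1, length(cols), by = 2)]
  }
  if (length(lines) == 0 || length(cols) == 0) return(list())
  excl_mask <- matrix(FALSE, ss[1], ss[2])
  for (ex in exclude %||% list())
    excl_mask[ex$lines, ex$cols] <- TRUE
  if (identical(block_pixels, "one-line")) {
    lines_per_block <- 1L
  } else {
    block_pixels <- as.integer(block_pixels)
    if (block_pixels < 1) stop_scan("block_pixels must be >= 1")
    lines_per_block <- max(1L, block_pixels %/% length(cols))
  }
  requests <- list()
  sub <- if (identical(block_pixels, "one-line") || block_pixels >= length(cols))
    NULL else block_pixels
  li <- 1L
  while (li <= length(lines)) {
    blk_lines <- lines[li:min(li + lines_per_block - 1L, length(lines))]
    keep_cols <- cols[!apply(excl_mask[blk_lines, cols, drop = FALSE], 2, all)]
    if (length(keep_cols)) {
      if (is.null(sub)) {
        requests[[length(requests) + 1L]] <-
          new_read_request(layout, blk_lines, keep_cols)
      } else {
        for (st in seq(1L, length(keep_cols), by = sub)) {
          requests[[length(requests) + 1L]] <- new_read_request(
            layout, blk_lines, keep_cols[st:min(st + sub - 1L, length(keep_cols))])
        }
      }
    }
    li <- li + lines_per_block
  }
  requests
}

new_read_request <- function(layout, lines, cols) {
  structure(list(lines = lines, cols = cols,
                 n_pixels = length(lines) * length(cols)),
            class = "read_request")
}

read_block <- function(handle, request) {
  layout <- handle$layout
  idx <- list(request$lines, request$cols, NULL, NULL)
  frames <- rhdf5::h5read(handle$path, layout$paths$frames, index = idx)
  spectra <- lapply(layout$paths$spectra, function(p)
    rhdf5::h5read(handle$path, p, index = idx[1:3]))
  p2 <- list(request$lines, request$cols)
  blk <- structure(list(
    lines = request$lines, cols = request$cols,
    frames = frames, spectra = spectra,
    pos_x = rhdf5::h5read(handle$path, layout$paths$pos_x, index = p2),
    pos_y = rhdf5::h5read(handle$path, layout$paths$pos_y, index = p2),
    monitor = rhdf5::h5read(handle$path, layout$paths$monitor, index = p2)
  ), class = "scan_block")
  rhdf5::H5close()
  blk
}

#' Stream scan blocks
#'
#' Bounded producer/consumer reader: blocks are delivered in request order
#' and at most one block is prefetched ahead of the one being consumed, so
#' resident memory never exceeds the data of two requests. I/O failure
#' surfaces on the failing block with its request attached; blocks already
#' delivered stay valid.
#'
#' @param handle a `scan_handle`.
#' @param requests list from [plan_requests()].
#' @return an iterator object; call `$next_block()` until it returns `NULL`.
#'   `$stats()` reports the peak number of simultaneously resident pixels.
#' @export
iterate_blocks <- function(handle, requests) {
  k <- 0L
  prefetched <- NULL
  peak <- 0L
  fetch <- function(i) {
    tryCatch(read_block(handle, requests[[i]]),
             error = function(e) structure(
               class = c("scanxray_io_error", "error", "condition"),
               list(message = paste0("read failure at request ", i, ": ",
                                     conditionMessage(e)),
                    call = NULL, request = requests[[i]], request_index = i)))
  }
  list(
    next_block = function() {
      if (k >= length(requests)) return(NULL)
      k <<- k + 1L
      blk <- if (!is.null(prefetched)) prefetched else fetch(k)
      prefetched <<- NULL
      # a failed prefetch surfaces here, on its own block, so every block
      # before the failing request has already been delivered intact
      if (inherits(blk, "condition")) stop(blk)
      # producer reads ahead one request while the consumer holds blk
      if (k < length(requests)) {
        prefetched <<- fetch(k + 1L)
        peak <<- max(peak, length(blk$monitor) + length(prefetched$monitor))
      } else {
        peak <<- max(peak, length(blk$monitor))
      }
      blk
    },
    stats = function() list(peak_resident_pixels = peak),
    reset = function() { k <<- 0L; prefetched <<- NULL; invisible(NULL) }
  )
}

#' Collect all blocks of a plan into a list
#'
#' Convenience eager driver over [iterate_blocks()].
#' @inheritParams iterate_blocks
#' @export
collect_blocks <- function(handle, requests) {
  it <- iterate_blocks(handle, requests)
  out <- list()
  while (!is.null(b <- it$next_block())) out[[length(out) + 1L]] <- b
  out
}

#' Read a whole scan eagerly
#'
#' @param handle a `scan_handle`.
#' @return list with `frames`, `spectra`, `pos_x`, `pos_y`, `monitor`.
#' @export
read_scan <- function(handle) {
  layout <- handle$layout
  out <- list(
    frames = rhdf5::h5read(handle$path, layout$paths$frames),
    spectra = lapply(layout$paths$spectra, function(p)
      rhdf5::h5read(handle$path, p)),
    pos_x = rhdf5::h5read(handle$path, layout$paths$pos_x),
    pos_y = rhdf5::h5read(handle$path, layout$paths$pos_y),
    monitor = rhdf5::h5read(handle$path, layout$paths$monitor)
  )
  rhdf5::H5close()
  out
}
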