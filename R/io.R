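# Data-exchange-style HDF5 layout:
#   exchange/data        projections, (angle, slice, detector)
#   exchange/data_white  flat fields, (frame, slice, detector)
#   exchange/data_dark   dark fields, (frame, slice, detector)
#   exchange/theta       projection angles, degrees on disk
#   truth/...            optional simulator ground truth (readers of the
#                        standard layout ignore it)
# Angles are converted to radians on read; all arrays are 64-bit floats on
# disk so the write/read round trip is bit-exact.

#' Write a raw dataset to a data-exchange-style HDF5 file
#'
#' @param dataset A `raw_dataset` (see [simulate_counts()]).
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_exchange <- function(dataset, path) {
  stopifnot(inherits(dataset, "raw_dataset"))
  if (length(dataset$angles) != dim(dataset$data)[1] ||
      any(!is.finite(dataset$angles)))
    stop("dataset has no valid angle list (one finite angle per projection)")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "exchange")
  rhdf5::h5write(dataset$data, path, "exchange/data")
  rhdf5::h5write(dataset$flats, path, "exchange/data_white")
  rhdf5::h5write(dataset$darks, path, "exchange/data_dark")
  rhdf5::h5write(dataset$angles * 180 / pi, path, "exchange/theta")
  rhdf5::h5write(as.integer(dataset$seed), path, "exchange/seed")
  if (!is.null(dataset$truth)) {
    rhdf5::h5createGroup(path, "truth")
    if (!is.null(dataset$truth$image))
      rhdf5::h5write(dataset$truth$image, path, "truth/image")
    if (!is.null(dataset$truth$sinogram))
      rhdf5::h5write(dataset$truth$sinogram, path, "truth/sinogram")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a data-exchange-style HDF5 file
#'
#' @param path File written by [write_exchange()] or any file following
#'   the exchange layout.
#' @return A `raw_dataset`; angles are converted from degrees to radians.
#' @export
read_exchange <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  on.exit(rhdf5::h5closeAll())
  contents <- rhdf5::h5ls(path)
  present <- file.path(contents$group, contents$name)
  need <- c("/exchange/data", "/exchange/data_white", "/exchange/data_dark",
            "/exchange/theta")
  for (g in need)
    if (!g %in% present)
      stop(sprintf("exchange file lacks required dataset '%s'", sub("^/", "", g)))
  data <- rhdf5::h5read(path, "exchange/data")
  flats <- rhdf5::h5read(path, "exchange/data_white")
  darks <- rhdf5::h5read(path, "exchange/data_dark")
  theta <- as.numeric(rhdf5::h5read(path, "exchange/theta"))
  if (length(theta) != dim(data)[1])
    stop(sprintf("theta length %d does not match %d projection frames",
                 length(theta), dim(data)[1]))
  seed <- if ("/exchange/seed" %in% present)
    as.integer(rhdf5::h5read(path, "exchange/seed")) else NA_integer_
  truth <- NULL
  if ("/truth/image" %in% present || "/truth/sinogram" %in% present) {
    truth <- list()
    if ("/truth/image" %in% present)
      truth$image <- rhdf5::h5read(path, "truth/image")
    if ("/truth/sinogram" %in% present)
      truth$sinogram <- rhdf5::h5read(path, "truth/sinogram")
  }
  structure(list(data = data, flats = flats, darks = darks,
                 angles = theta * pi / 180, truth = truth, seed = seed,
                 n_zinger = NA_integer_),
            class = "raw_dataset")
}

# Minimal single-strip little-endian 32-bit float TIFF writer. Installed
# raster writers assume display data in [0, 1]; reconstructed slices are
# unbounded physical values, so the few required TIFF structures are
# emitted directly. Files read back exactly (at float32 precision) with
# any libtiff-based reader, e.g. tiff::readTIFF.
write_float_tiff <- function(m, path) {
  stopifnot(is.matrix(m))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- ncol(m); h <- nrow(m)
  data_bytes <- w * h * 4L
  ifd_offset <- 8L + data_bytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4L, endian = "little")
  # pixel data, row-major, immediately after the 8-byte header
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(c(id, type)), con, size = 2L, endian = "little")
    writeBin(as.integer(c(count, value)), con, size = 4L, endian = "little")
  }
  writeBin(10L, con, size = 2L, endian = "little")  # tag count
  tag(256, 4, 1, w)            # ImageWidth
  tag(257, 4, 1, h)            # ImageLength
  tag(258, 3, 1, 32)           # BitsPerSample
  tag(259, 3, 1, 1)            # Compression: none
  tag(262, 3, 1, 1)            # Photometric: BlackIsZero
  tag(273, 4, 1, 8)            # StripOffsets
  tag(277, 3, 1, 1)            # SamplesPerPixel
  tag(278, 4, 1, h)            # RowsPerStrip
  tag(279, 4, 1, data_bytes)   # StripByteCounts
  tag(339, 3, 1, 3)            # SampleFormat: IEEE float
  writeBin(0L, con, size = 4L, endian = "little")   # no further IFD
  invisible(path)
}

#' Write a reconstruction volume as a 32-bit float TIFF stack
#'
#' One single-image float TIFF per slice, named
#' `prefix_000.tif, prefix_001.tif, ...` (suffix width grows with the
#' slice count, minimum three digits), in deterministic slice order.
#' Values are written as IEEE float32 without scaling or clipping, so
#' read-back (e.g. via [tiff::readTIFF()]) reproduces the stored values
#' exactly at float32 precision.
#'
#' @param volume `n_y` x `n_x` x n_slices array (a matrix is treated as
#'   one slice); finite, non-empty.
#' @param directory Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written.
#' @export
write_tiff_stack <- function(volume, directory, prefix = "recon") {
  if (is.matrix(volume)) volume <- array(volume, c(dim(volume), 1L))
  if (length(volume) == 0L) stop("empty volume")
  stopifnot(length(dim(volume)) == 3L)
  if (any(!is.finite(volume))) stop("volume must be finite")
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  n <- dim(volume)[3]
  width <- max(3L, nchar(as.character(n - 1L)))
  files <- file.path(directory,
                     sprintf("%s_%0*d.tif", prefix, width, seq_len(n) - 1L))
  for (s in seq_len(n)) write_float_tiff(volume[, , s], files[s])
  files
}

#' Read a float TIFF stack written by [write_tiff_stack()]
#'
#' @param directory Directory holding the stack.
#' @param prefix File-name prefix used at write time.
#' @return `n_y` x `n_x` x n_slices array.
#' @export
read_tiff_stack <- function(directory, prefix = "recon") {
  files <- sort(list.files(directory, pattern = paste0("^", prefix,
                                                       "_[0-9]+\\.tif$"),
                           full.names = TRUE))
  if (!length(files)) stop(sprintf("no %s_*.tif files in %s", prefix,
                                   directory))
  slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = FALSE))
  out <- array(0, c(dim(slices[[1]]), length(slices)))
  for (s in seq_along(slices)) out[, , s] <- slices[[s]]
  out
}

#' Read and write flat key-value configuration files
#'
#' Configuration files are YAML with flat keys mirroring the command-line
#' flags (e.g. `algorithm`, `num_iter`, `center`, geometry keys from
#' [geometry_to_config()]). [write_config()] followed by [read_config()]
#' round-trips the list.
#'
#' @param path File path.
#' @return `read_config`: a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) list() else cfg
}

#' @rdname read_config
#' @param cfg Named list of scalar or vector values.
#' @export
write_config <- function(cfg, path) {
  stopifnot(is.list(cfg))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# -- logging ----------------------------------------------------------------

log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' Messages below the level are suppressed. `info` logs every resolved
#' reconstruction call (the one-line-change audit trail); `debug` adds
#' per-iteration diagnostics where available.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("warn", "info", "debug", "error")) {
  level <- match.arg(level)
  old <- getOption("tomoslice.log_level", "warn")
  options(tomoslice.log_level = level)
  invisible(old)
}

log_msg <- function(level, msg) {
  cur <- getOption("tomoslice.log_level", "warn")
  if (log_levels[[level]] >= log_levels[[cur]])
    message(sprintf("[%s] %s", toupper(level), msg))
  invisible(NULL)
}
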