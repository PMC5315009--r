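#' Parallel-beam scan geometry
#'
#' Describes a parallel-beam acquisition of one slice: the detector, the
#' projection angles, and where the rotation axis projects onto the detector.
#' The Radon convention used throughout the package is
#' \eqn{p(\theta, t) = \int_{x\cos\theta + y\sin\theta = t} f \, dl},
#' with angles in radians in memory (degrees at the CLI and on disk).
#'
#' Detector bins are indexed 0-based; bin \eqn{j} is centred at detector
#' coordinate \eqn{t_j = (j - \mathrm{center}) \cdot \mathrm{det\_width}},
#' i.e. the ray through the rotation axis has \eqn{t = 0} and hits the
#' (possibly fractional) bin coordinate `center`.
#'
#' @param n_det Number of detector bins (>= 1).
#' @param angles Projection angles in radians, non-empty, all finite.
#' @param center Rotation-center position in 0-based detector-pixel
#'   coordinates; fractional values allowed. Default: detector midpoint
#'   `(n_det - 1) / 2`. A center outside `[0, n_det - 1]` is legal but
#'   recorded as a warning state (and a warning is issued).
#' @param det_width Detector bin width in length units (default 1).
#'
#' @return An object of class `scan_geometry`: a list with fields `n_det`,
#'   `det_width`, `angles`, `center`, and `center_in_range`.
#' @seealso [translate_geometry()], [build_angles()], [limited_angle_mask()]
#' @export
#' @examples
#' g <- scan_geometry(256, build_angles(180, 0, pi))
#' g$center  # 127.5, the detector midpoint
scan_geometry <- function(n_det, angles, center = (n_det - 1) / 2,
                          det_width = 1) {
  if (length(n_det) != 1L || !is.finite(n_det) || n_det < 1)
    stop("`n_det` must be a single value >= 1")
  n_det <- as.integer(n_det)
  if (length(angles) < 1L || !all(is.finite(angles)))
    stop("`angles` must be non-empty and finite")
  if (length(center) != 1L || !is.finite(center))
    stop("`center` must be a single finite value")
  if (!is.finite(det_width) || det_width <= 0)
    stop("`det_width` must be positive")
  in_range <- center >= 0 && center <= n_det - 1
  if (!in_range)
    warning(sprintf("rotation center %.3f lies outside the detector [0, %d]",
                    center, n_det - 1L))
  structure(
    list(n_det = n_det, det_width = as.numeric(det_width),
         angles = as.numeric(angles), center = as.numeric(center),
         center_in_range = in_range),
    class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %d detector bins (width %g), %d angles [%.2f, %.2f] deg, center %.3f%s\n",
    x$n_det, x$det_width, length(x$angles),
    min(x$angles) * 180 / pi, max(x$angles) * 180 / pi, x$center,
    if (x$center_in_range) "" else " (outside detector!)"))
  invisible(x)
}

#' Projector-level geometry
#'
#' The reconstruction back end describes the rotation axis as a signed
#' offset from the detector midpoint rather than an absolute pixel
#' coordinate. [translate_geometry()] converts a [scan_geometry()] into this
#' form losslessly; [untranslate_geometry()] inverts it exactly.
#'
#' @param n_det,det_width,angles As in [scan_geometry()].
#' @param center_offset Signed displacement of the rotation axis from the
#'   detector midpoint `(n_det - 1) / 2`, in detector bins.
#' @return An object of class `projector_geometry`.
#' @export
projector_geometry <- function(n_det, angles, center_offset = 0,
                               det_width = 1) {
  if (length(n_det) != 1L || !is.finite(n_det) || n_det < 1)
    stop("`n_det` must be a single value >= 1")
  if (length(angles) < 1L || !all(is.finite(angles)))
    stop("`angles` must be non-empty and finite")
  if (!is.finite(center_offset))
    stop("`center_offset` must be finite")
  structure(
    list(n_det = as.integer(n_det), det_width = as.numeric(det_width),
         angles = as.numeric(angles),
         center_offset = as.numeric(center_offset)),
    class = "projector_geometry")
}

#' Translate between workflow and projector geometries
#'
#' The workflow layer addresses the rotation center in absolute detector
#' pixels; the projector layer uses a signed offset from the detector
#' midpoint: `center_offset = center - (n_det - 1) / 2`. The pair of
#' translations is an exact bijection.
#'
#' @param scan A [scan_geometry()].
#' @return `translate_geometry`: a [projector_geometry()].
#' @export
translate_geometry <- function(scan) {
  stopifnot(inherits(scan, "scan_geometry"))
  projector_geometry(scan$n_det, scan$angles,
                     center_offset = scan$center - (scan$n_det - 1) / 2,
                     det_width = scan$det_width)
}

#' @rdname translate_geometry
#' @param proj A [projector_geometry()].
#' @return `untranslate_geometry`: the corresponding [scan_geometry()].
#' @export
untranslate_geometry <- function(proj) {
  stopifnot(inherits(proj, "projector_geometry"))
  scan_geometry(proj$n_det, proj$angles,
                center = proj$center_offset + (proj$n_det - 1) / 2,
                det_width = proj$det_width)
}

#' Build an equally spaced angle list
#'
#' @param n Number of angles (>= 1).
#' @param start,stop Interval bounds in radians, `stop > start`.
#' @param endpoint If `FALSE` (default) the interval is half-open and `stop`
#'   is excluded — the usual half-turn convention where 0 and pi coincide.
#' @return Numeric vector of `n` strictly increasing angles (radians).
#' @export
#' @examples
#' build_angles(4, 0, pi)  # 0, pi/4, pi/2, 3*pi/4
build_angles <- function(n, start = 0, stop = pi, endpoint = FALSE) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a single value >= 1")
  if (!is.finite(start) || !is.finite(stop) || stop <= start)
    stop("`stop` must be greater than `start`")
  n <- as.integer(n)
  if (n == 1L) return(start)
  if (endpoint) seq(start, stop, length.out = n)
  else start + (stop - start) * (seq_len(n) - 1L) / n
}

#' Mask a blocked angular wedge
#'
#' Removes the projections whose angle falls in the half-open interval
#' `(blocked_lo, blocked_hi]`, the situation arising when part of the sample
#' environment (e.g. a pressure-cell frame) blocks the beam over a
#' contiguous range of rotation angles, leaving a limited-angle problem.
#' The half-open convention lets adjacent wedges tile without
#' double-counting.
#'
#' @param angles Projection angles (radians), non-empty.
#' @param blocked_lo,blocked_hi Wedge bounds in radians,
#'   `blocked_lo <= blocked_hi`. An empty interval (`lo == hi`) blocks
#'   nothing.
#' @return A list with `usable` (the retained angles, order preserved),
#'   `keep` (logical mask into `angles`), and `blocked` (count removed).
#'   `length(usable) + blocked == length(angles)` always.
#' @export
#' @examples
#' th <- build_angles(359, 0, 359 * 0.5 * pi / 180)     # 0 .. 179 deg
#' m <- limited_angle_mask(th, 136 * pi / 180, pi)
#' length(m$usable)  # 273
#' m$blocked         # 86
limited_angle_mask <- function(angles, blocked_lo, blocked_hi) {
  if (length(angles) < 1L) stop("`angles` must be non-empty")
  if (!is.finite(blocked_lo) || !is.finite(blocked_hi) ||
      blocked_lo > blocked_hi)
    stop("need finite `blocked_lo` <= `blocked_hi`")
  keep <- !(angles > blocked_lo & angles <= blocked_hi)
  list(usable = angles[keep], keep = keep, blocked = sum(!keep))
}

#' Square reconstruction raster
#'
#' The image grid is centred on the rotation axis: pixel `i` (0-based) along
#' each axis has its centre at `(i - (n - 1) / 2) * pixel_size`.
#'
#' @param n_x,n_y Raster size in pixels (>= 1); `n_y` defaults to `n_x`.
#' @param pixel_size Pixel edge length; conventionally equal to the detector
#'   bin width.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(n_x, n_y = n_x, pixel_size = 1) {
  if (!is.finite(n_x) || n_x < 1 || !is.finite(n_y) || n_y < 1)
    stop("grid dimensions must be >= 1")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive")
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 pixel_size = as.numeric(pixel_size)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, pixel size %g\n",
              x$n_x, x$n_y, x$pixel_size))
  invisible(x)
}

# Pixel-centre coordinates of a grid axis (length n), centred on the axis.
grid_axis <- function(n, pixel_size) {
  (seq_len(n) - 1 - (n - 1) / 2) * pixel_size
}

#' Serialize a scan geometry to a flat configuration list
#'
#' Geometry travels in configuration files as a flat key-value section with
#' angles in degrees (the beamline convention): either an explicit
#' `angles_deg` list or an `angles_start_deg`/`angles_step_deg`/`angles_n`
#' triple.
#'
#' @param geom A [scan_geometry()].
#' @return A named list suitable for [write_config()].
#' @export
geometry_to_config <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  deg <- geom$angles * 180 / pi
  cfg <- list(n_det = geom$n_det, det_width = geom$det_width,
              center = geom$center)
  d <- diff(deg)
  if (length(deg) > 1L && diff(range(d)) < 1e-9) {
    cfg$angles_start_deg <- deg[1]
    cfg$angles_step_deg <- d[1]
    cfg$angles_n <- length(deg)
  } else {
    cfg$angles_deg <- deg
  }
  cfg
}

#' @rdname geometry_to_config
#' @param cfg A named list as produced by [geometry_to_config()].
#' @export
geometry_from_config <- function(cfg) {
  if (is.null(cfg$n_det)) stop("geometry config lacks `n_det`")
  if (!is.null(cfg$angles_deg)) {
    deg <- as.numeric(cfg$angles_deg)
  } else if (!is.null(cfg$angles_n)) {
    deg <- as.numeric(cfg$angles_start_deg) +
      as.numeric(cfg$angles_step_deg) * (seq_len(cfg$angles_n) - 1)
  } else stop("geometry config needs `angles_deg` or a start/step/n triple")
  scan_geometry(cfg$n_det, deg * pi / 180,
                center = if (is.null(cfg$center)) (cfg$n_det - 1) / 2
                         else cfg$center,
                det_width = if (is.null(cfg$det_width)) 1 else cfg$det_width)
}
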