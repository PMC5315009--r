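#' Additive ellipse phantoms
#'
#' An ellipse phantom is a list of ellipses, each contributing an additive
#' value `rho` (attenuation per unit length) inside its boundary. Because
#' the Radon transform of an ellipse has a classical closed form, these
#' phantoms double as the analytic oracle for the projection operators.
#'
#' @param cx,cy Ellipse centres in grid length units.
#' @param a,b Semi-axes (> 0).
#' @param phi Rotation of the `a` axis from the x axis, radians.
#' @param rho Additive value inside the ellipse.
#' @return An object of class `ellipse_phantom` (a data frame).
#' @export
ellipse_phantom <- function(cx, cy, a, b, phi = 0, rho = 1) {
  ph <- data.frame(cx = cx, cy = cy, a = a, b = b, phi = phi, rho = rho)
  if (any(!is.finite(as.matrix(ph)))) stop("phantom parameters must be finite")
  if (any(ph$a <= 0) || any(ph$b <= 0)) stop("semi-axes must be positive")
  class(ph) <- c("ellipse_phantom", "data.frame")
  ph
}

# Shepp-Logan parameter table: additive value, semi-axes, centre, rotation
# (degrees). "modified" uses the high-contrast values common in numerical
# work; "original" the published low-contrast ones.
shepp_logan_table <- function(variant = c("modified", "original")) {
  variant <- match.arg(variant)
  a   <- c(.69, .6624, .11, .16, .21, .046, .046, .046, .023, .023)
  b   <- c(.92, .8740, .31, .41, .25, .046, .046, .023, .023, .046)
  cx  <- c(0, 0, .22, -.22, 0, 0, 0, -.08, 0, .06)
  cy  <- c(0, -.0184, 0, 0, .35, .1, -.1, -.605, -.606, -.605)
  deg <- c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  rho <- if (variant == "modified")
    c(1, -.8, -.2, -.2, .1, .1, .1, .1, .1, .1)
  else
    c(2, -.98, -.02, -.02, .01, .01, .01, .01, .01, .01)
  ellipse_phantom(cx, cy, a, b, deg * pi / 180, rho)
}

#' Rasterize an ellipse phantom
#'
#' Evaluates the additive phantom at pixel centres (optionally supersampled
#' and averaged) on a grid centred at the origin.
#'
#' @param phantom An [ellipse_phantom()].
#' @param grid An [image_grid()].
#' @param supersample Integer; each pixel is averaged over
#'   `supersample^2` sub-samples (1 = pixel centres only).
#' @return `n_y` x `n_x` numeric matrix; rows index y, columns x.
#' @export
rasterize_phantom <- function(phantom, grid, supersample = 1L) {
  stopifnot(inherits(phantom, "ellipse_phantom"), inherits(grid, "image_grid"))
  s <- as.integer(supersample)
  stopifnot(s >= 1L)
  xs <- grid_axis(grid$n_x, grid$pixel_size)
  ys <- grid_axis(grid$n_y, grid$pixel_size)
  if (s > 1L) {
    off <- ((seq_len(s) - 0.5) / s - 0.5) * grid$pixel_size
    xs <- as.vector(outer(off, xs, `+`))
    ys <- as.vector(outer(off, ys, `+`))
  }
  img <- matrix(0, length(ys), length(xs))
  for (k in seq_len(nrow(phantom))) {
    e <- phantom[k, ]
    xr <- xs - e$cx
    yr <- ys - e$cy
    c1 <- cos(e$phi); s1 <- sin(e$phi)
    # inside iff (x' / a)^2 + (y' / b)^2 <= 1 in the ellipse frame
    u <- outer(yr * s1, xr * c1, `+`) / e$a
    v <- outer(yr * c1, -xr * s1, `+`) / e$b
    img <- img + e$rho * (u * u + v * v <= 1)
  }
  if (s > 1L) {
    # average s x s blocks back to the requested raster
    img <- apply(array(img, c(s, grid$n_y, s * grid$n_x)), c(2, 3), mean)
    img <- t(apply(array(t(img), c(s, grid$n_x, grid$n_y)), c(2, 3), mean))
  }
  img
}

#' The Shepp-Logan head phantom
#'
#' The standard 10-ellipse Shepp-Logan parameter set rasterized on an
#' `n` x `n` grid covering the square \eqn{[-1, 1]^2} (pixel size `2 / n`).
#'
#' @param n Raster size, at least 16.
#' @param variant `"modified"` (default, high-contrast values) or
#'   `"original"`.
#' @param supersample Passed to [rasterize_phantom()]; the default 2x2
#'   sub-sampling anti-aliases the ellipse edges.
#' @return List with `image` (`n` x `n` matrix), `phantom` (the
#'   [ellipse_phantom()] for analytic projection) and `grid`.
#' @export
#' @examples
#' sl <- shepp_logan(64)
#' range(sl$image)
shepp_logan <- function(n, variant = c("modified", "original"),
                        supersample = 2L) {
  if (!is.finite(n) || n < 16) stop("`n` must be at least 16")
  n <- as.integer(n)
  ph <- shepp_logan_table(match.arg(variant))
  grid <- image_grid(n, n, pixel_size = 2 / n)
  list(image = rasterize_phantom(ph, grid, supersample), phantom = ph,
       grid = grid)
}

#' Closed-form sinogram of an ellipse phantom
#'
#' For a single ellipse with semi-axes \eqn{a, b}, rotation \eqn{\phi} and
#' value \eqn{\rho}, the line integral at angle \eqn{\theta} and ray offset
#' \eqn{t'} (relative to the ellipse centre) is
#' \deqn{p = 2\rho ab \sqrt{\alpha^2 - t'^2} / \alpha^2, \qquad
#'       \alpha^2 = a^2\cos^2(\theta-\phi) + b^2\sin^2(\theta-\phi),}
#' when \eqn{t'^2 < \alpha^2} and zero otherwise; the phantom sinogram is
#' the sum over ellipses. The rotation-center position of `geom` is
#' honoured.
#'
#' @param phantom An [ellipse_phantom()].
#' @param geom A [scan_geometry()].
#' @return Sinogram matrix, rows = angles, columns = detector bins.
#' @export
analytic_sinogram <- function(phantom, geom) {
  stopifnot(inherits(phantom, "ellipse_phantom"),
            inherits(geom, "scan_geometry"))
  tvals <- (seq_len(geom$n_det) - 1 - geom$center) * geom$det_width
  th <- geom$angles
  sino <- matrix(0, length(th), geom$n_det)
  for (k in seq_len(nrow(phantom))) {
    e <- phantom[k, ]
    alpha2 <- e$a^2 * cos(th - e$phi)^2 + e$b^2 * sin(th - e$phi)^2
    # per-angle offset of the ellipse centre along the detector axis
    tc <- e$cx * cos(th) + e$cy * sin(th)
    tp <- outer(-tc, tvals, `+`)              # t' = t - tc
    disc <- alpha2 - tp * tp                  # recycled by column: alpha2[row]
    pos <- disc > 0
    contrib <- matrix(0, length(th), geom$n_det)
    contrib[pos] <- 2 * e$rho * e$a * e$b *
      sqrt(disc[pos]) / rep(alpha2, times = geom$n_det)[pos]
    sino <- sino + contrib
  }
  sino
}

#' Simulate raw counts from a line-integral sinogram
#'
#' Emulates a synchrotron acquisition: ideal counts
#' \eqn{I = I_0 e^{-p}}, per-detector-column multiplicative gains
#' (lognormal, sd `ring_gain_sd`) shared by flats and data, an independent
#' per-column gain *drift* of the same magnitude applied to the data only
#' (the component of ring artifacts that flat-field normalization cannot
#' remove), optional Poisson counting noise, and zingers — isolated spurious
#' detector hits — implanted as multiplicative spikes on the raw counts.
#'
#' With all corruptions off the simulation is exactly inverted by
#' [normalize_raw()] followed by [minus_log()].
#'
#' @param sino Line-integral sinogram (angles x detector matrix, or an
#'   angles x slices x detector array); finite and non-negative.
#' @param I0 Incident counts per pixel (> 0).
#' @param n_flat,n_dark Number of flat-/dark-field frames.
#' @param ring_gain_sd Lognormal sd of the per-column gains (0 disables).
#' @param ring_drift Multiplier on the sd of the data-only gain drift
#'   (default 1; with `ring_gain_sd = 0` no drift either).
#' @param zinger_rate Per-pixel probability of a zinger in the data frames.
#' @param zinger_scale Multiplicative spike factor for zingers.
#' @param dark_level Mean dark counts per pixel.
#' @param noise Apply Poisson noise to data, flats and darks.
#' @param seed Integer seed; the whole dataset flows from one seeded
#'   generator so regeneration is bit-for-bit reproducible.
#' @param truth Optional list carried into the dataset (e.g. reference
#'   slice and clean sinogram).
#' @return An object of class `raw_dataset`: list with `data`, `flats`,
#'   `darks` (counts arrays, frames x slices x detector), `angles`
#'   (set by the caller or `NA`), `truth`, `seed`, and `n_zinger` (number
#'   of implanted zingers).
#' @export
simulate_counts <- function(sino, I0 = 1e4, n_flat = 10L, n_dark = 10L,
                            ring_gain_sd = 0, ring_drift = 1,
                            zinger_rate = 0, zinger_scale = 20,
                            dark_level = 10, noise = TRUE, seed = 1L,
                            truth = NULL) {
  if (is.matrix(sino)) sino <- array(sino, c(nrow(sino), 1L, ncol(sino)))
  stopifnot(length(dim(sino)) == 3L)
  if (any(!is.finite(sino))) stop("sinogram must be finite")
  if (any(sino < 0)) stop("sinogram must be non-negative (line integrals)")
  if (!is.finite(I0) || I0 <= 0) stop("`I0` must be positive")
  na <- dim(sino)[1]; ns <- dim(sino)[2]; nd <- dim(sino)[3]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  gain <- if (ring_gain_sd > 0)
    exp(stats::rnorm(ns * nd, sd = ring_gain_sd)) else rep(1, ns * nd)
  drift <- if (ring_gain_sd > 0 && ring_drift > 0)
    exp(stats::rnorm(ns * nd, sd = ring_gain_sd * ring_drift))
  else rep(1, ns * nd)
  gmat <- array(rep(gain, each = na), c(na, ns, nd))
  dmat <- array(rep(drift, each = na), c(na, ns, nd))

  ideal <- I0 * exp(-sino) * gmat * dmat
  data <- if (noise) array(stats::rpois(length(ideal), ideal), dim(ideal))
          else ideal
  n_zinger <- 0L
  if (zinger_rate > 0) {
    hit <- stats::runif(length(data)) < zinger_rate
    n_zinger <- sum(hit)
    data[hit] <- data[hit] * zinger_scale
  }
  data <- data + dark_level

  flat_ideal <- array(rep(I0 * gain, each = n_flat), c(n_flat, ns, nd))
  flats <- if (noise)
    array(stats::rpois(length(flat_ideal), flat_ideal), dim(flat_ideal))
  else flat_ideal
  flats <- flats + dark_level
  dark_ideal <- array(dark_level, c(n_dark, ns, nd))
  darks <- if (noise)
    array(stats::rpois(length(dark_ideal), dark_ideal), dim(dark_ideal))
  else dark_ideal

  structure(list(data = data, flats = flats, darks = darks,
                 angles = NA_real_, truth = truth,
                 seed = as.integer(seed), n_zinger = n_zinger),
            class = "raw_dataset")
}

#' @export
print.raw_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<raw_dataset> %d projections x %d slice(s) x %d detector bins; %d flats, %d darks; seed %d\n",
    d[1], d[2], d[3], dim(x$flats)[1], dim(x$darks)[1], x$seed))
  invisible(x)
}

#' Simulate a limited-angle scan of the Shepp-Logan phantom
#'
#' Builds the half-turn angle list at `step_deg` spacing (endpoint
#' excluded), drops the final angle when `drop_last = TRUE` so that a 0.5
#' degree step yields the canonical 359-projection list, masks the wedge
#' of angles above `block_above_deg` via [limited_angle_mask()], computes
#' the closed-form phantom sinogram and corrupts it with
#' [simulate_counts()]. The clean sinogram (restricted to the usable
#' angles) and the rasterized phantom are retained under `truth`.
#'
#' @param n Raster / detector size (pixels).
#' @param block_above_deg Angles strictly greater than this (degrees) are
#'   blocked; 180 or more blocks nothing.
#' @param step_deg Angular step in degrees (> 0).
#' @param drop_last Drop the final angle of the endpoint-excluded list
#'   (default `TRUE`: 360 angles at 0.5 degrees become 359, last 179).
#' @param center_shift Shift of the rotation center away from the detector
#'   midpoint, in pixels (used by center-finding exercises).
#' @param phantom Optional [ellipse_phantom()]; default Shepp-Logan.
#' @inheritParams simulate_counts
#' @param ... Further arguments to [simulate_counts()].
#' @return A `raw_dataset` with `angles` set to the usable angles (radians)
#'   and `truth` holding `image`, `sinogram`, `geometry` and the blocked
#'   count.
#' @export
make_limited_angle_dataset <- function(n = 128, block_above_deg = 136,
                                       step_deg = 0.5, drop_last = TRUE,
                                       center_shift = 0, phantom = NULL,
                                       seed = 1L, ...) {
  if (!is.finite(step_deg) || step_deg <= 0) stop("`step_deg` must be > 0")
  if (!is.finite(block_above_deg) || block_above_deg <= 0)
    stop("`block_above_deg` must be positive")
  n_ang <- as.integer(round(180 / step_deg))
  th <- build_angles(n_ang, 0, pi)
  if (drop_last && length(th) > 1L) th <- th[-length(th)]
  mask <- limited_angle_mask(th, block_above_deg * pi / 180, pi)
  if (length(mask$usable) == 0L)
    stop("blocked wedge leaves no usable projections")

  if (is.null(phantom)) phantom <- shepp_logan_table("modified")
  grid <- image_grid(n, n, pixel_size = 2 / n)
  geom <- scan_geometry(n, mask$usable,
                        center = (n - 1) / 2 + center_shift,
                        det_width = 2 / n)
  sino <- analytic_sinogram(phantom, geom)
  truth <- list(image = rasterize_phantom(phantom, grid, supersample = 2L),
                sinogram = sino, geometry = geom, grid = grid,
                n_blocked = mask$blocked, n_total = length(th))
  ds <- simulate_counts(sino, seed = seed, truth = truth, ...)
  ds$angles <- mask$usable
  ds
}
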