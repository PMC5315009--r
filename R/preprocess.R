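#' Flat-field / dark-field normalization
#'
#' Converts raw counts to transmittance using the Beer-Lambert references:
#' \eqn{T = (I - \bar D) / (\bar F - \bar D)} with \eqn{\bar F, \bar D} the
#' per-pixel mean (or median) over the flat and dark frames. The
#' denominator is floored at the smallest positive normal double and the
#' result is clipped to `[eps, cutoff]`; a cutoff above 1 is legitimate for
#' phase-contrast data where constructive interference can exceed the
#' incident intensity.
#'
#' @param data Counts: angles x slices x detector array (or a single
#'   angles x detector matrix).
#' @param flats,darks Reference frames, frames x slices x detector (or
#'   frames x detector matching a matrix `data`); at least one frame each.
#' @param cutoff Upper clip for the transmittance (default 1).
#' @param reduce `"mean"` (default) or `"median"` frame reduction.
#' @return Transmittance array shaped like `data`, values in
#'   `[eps, cutoff]`.
#' @details If the flat mean fails to exceed the dark mean on more than 1%
#'   of pixels the data are considered unusable and an error reporting the
#'   offending fraction is raised.
#' @export
normalize_raw <- function(data, flats, darks, cutoff = 1,
                          reduce = c("mean", "median")) {
  reduce <- match.arg(reduce)
  was_matrix <- is.matrix(data)
  if (was_matrix) {
    data <- array(data, c(nrow(data), 1L, ncol(data)))
    if (is.matrix(flats)) flats <- array(flats, c(nrow(flats), 1L, ncol(flats)))
    if (is.matrix(darks)) darks <- array(darks, c(nrow(darks), 1L, ncol(darks)))
  }
  stopifnot(length(dim(data)) == 3L, length(dim(flats)) == 3L,
            length(dim(darks)) == 3L)
  if (any(dim(flats)[2:3] != dim(data)[2:3]) ||
      any(dim(darks)[2:3] != dim(data)[2:3]))
    stop("flat/dark frame shape does not match the data")
  if (dim(flats)[1] < 1L || dim(darks)[1] < 1L)
    stop("need at least one flat and one dark frame")
  red <- function(x) {
    if (reduce == "mean") colMeans(array(x, c(dim(x)[1], prod(dim(x)[2:3]))))
    else apply(array(x, c(dim(x)[1], prod(dim(x)[2:3]))), 2, stats::median)
  }
  fbar <- red(flats); dbar <- red(darks)
  bad <- mean(fbar <= dbar)
  if (bad > 0.01)
    stop(sprintf(
      "flat field does not exceed dark field on %.1f%% of pixels", 100 * bad))
  eps <- .Machine$double.xmin
  denom <- pmax(fbar - dbar, eps)
  na <- dim(data)[1]
  num <- data - rep(dbar, each = na)
  tr <- num / rep(denom, each = na)
  tr <- pmin(pmax(tr, eps), cutoff)
  out <- array(tr, dim(data))
  if (was_matrix) out <- matrix(out, dim(out)[1], dim(out)[3])
  out
}

#' Beer-Lambert log transform
#'
#' `p = -log(T)`: transmittance to attenuation line integrals. Inputs must
#' be strictly positive — normalize first.
#'
#' @param tr Transmittance array (any shape), all entries > 0.
#' @return `-log(tr)`, same shape.
#' @export
minus_log <- function(tr) {
  if (any(!is.finite(tr)) || any(tr <= 0))
    stop("transmittance must be strictly positive; run normalize_raw() first")
  -log(tr)
}

#' Zinger (outlier spike) correction
#'
#' Zingers are isolated abnormally high pixels caused by stray high-energy
#' events. Each projection is compared against its own 2-D median filter
#' (`size` x `size`, edge-replicated); pixels whose ratio to the median
#' exceeds `threshold` are replaced by the median, all others are left
#' untouched. Using a ratio rather than a difference makes the test
#' independent of exposure scale.
#'
#' @param proj Counts or transmittance: a matrix (one projection) or an
#'   angles x slices x detector array (filtered per projection over the
#'   slices x detector plane; for a single-slice array the filter runs
#'   along the detector axis of each projection row of the sinogram).
#' @param threshold Ratio above which a pixel is declared a zinger (> 1).
#' @param size Odd median window edge length (>= 3).
#' @return Corrected array of the same shape, with attribute `n_replaced`.
#' @export
remove_zingers <- function(proj, threshold = 1.5, size = 3L) {
  size <- as.integer(size)
  if (size %% 2L == 0L || size < 3L) stop("`size` must be odd and >= 3")
  if (!is.finite(threshold) || threshold <= 1) stop("`threshold` must be > 1")
  fix_one <- function(m) {
    med <- median_filter_2d(m, size)
    ratio <- m / pmax(med, .Machine$double.xmin)
    hit <- ratio > threshold
    m[hit] <- med[hit]
    attr(m, "n_replaced") <- sum(hit)
    m
  }
  if (is.matrix(proj)) return(fix_one(proj))
  stopifnot(length(dim(proj)) == 3L)
  total <- 0L
  for (a in seq_len(dim(proj)[1])) {
    f <- fix_one(matrix(proj[a, , ], dim(proj)[2], dim(proj)[3]))
    total <- total + attr(f, "n_replaced")
    proj[a, , ] <- f
  }
  attr(proj, "n_replaced") <- total
  proj
}

#' Ring-removal parameters
#'
#' @param n_levels Wavelet decomposition depth (>= 1); must not exceed
#'   `log2` of the smaller sinogram dimension.
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"`, `"db8"`, `"sym8"`.
#' @param sigma Gaussian damping width in angular-frequency bins (> 0).
#' @return List of class `ring_removal_params`.
#' @export
ring_removal_params <- function(n_levels = 5L, wavelet = "sym8", sigma = 2) {
  if (!is.finite(n_levels) || n_levels < 1) stop("`n_levels` must be >= 1")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive")
  wavelet_filters(wavelet)  # validates the name
  structure(list(n_levels = as.integer(n_levels), wavelet = wavelet,
                 sigma = as.numeric(sigma)),
            class = "ring_removal_params")
}

#' Wavelet-Fourier stripe (ring) removal
#'
#' Detector columns with miscalibrated gain leave stripes in the sinogram
#' that reconstruct into concentric rings. Stripes are constant along the
#' angle axis, so at every level of a 2-D wavelet decomposition they
#' condense into the detail band that is high-pass along the detector axis
#' and low-pass along the angle axis. That band is Fourier-transformed
#' along the angle axis and each coefficient at angular frequency \eqn{k}
#' is damped by \eqn{g(k) = 1 - e^{-k^2 / (2\sigma^2)}}, suppressing the
#' stripe-stationary (low angular frequency) content while leaving genuine
#' structure, which moves in the sinogram, untouched. Output shape equals
#' input shape.
#'
#' @param sino Sinogram matrix, rows = angles, columns = detector bins; at
#'   least `2^n_levels` in each dimension.
#' @param params A [ring_removal_params()] (or `NULL` for defaults).
#' @return Filtered sinogram, same shape.
#' @export
remove_rings_wavelet_fourier <- function(sino, params = NULL) {
  if (is.null(params)) params <- ring_removal_params()
  stopifnot(is.matrix(sino), inherits(params, "ring_removal_params"))
  L <- params$n_levels
  if (2^L > min(dim(sino)))
    stop(sprintf("n_levels = %d too deep for a %d x %d sinogram",
                 L, nrow(sino), ncol(sino)))
  flt <- wavelet_filters(params$wavelet)
  blk <- 2L^L
  # mirror-periodic extension: [x, reverse(x)] tiles continuously, so the
  # periodic wavelet transform sees no boundary jump (which would otherwise
  # masquerade as angle-static detail and get damped); then cycle the
  # extension up to a multiple of 2^L
  ext_index <- function(n) {
    m <- ceiling(2L * n / blk) * blk
    j <- (seq_len(m) - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  x <- sino[ext_index(nrow(sino)), ext_index(ncol(sino)), drop = FALSE]

  damp_band <- function(band) {
    # FFT along the angle axis (rows); damp low angular frequencies
    n <- nrow(band)
    k <- pmin(0:(n - 1), n - (0:(n - 1)))   # symmetric frequency index
    g <- 1 - exp(-k^2 / (2 * params$sigma^2))
    Re(stats::mvfft(stats::mvfft(band) * g, inverse = TRUE)) / n
  }

  decompose <- function(x, level) {
    bands <- dwt2(x, flt)
    # stripes: approximation along angle (dim 1), detail along detector
    bands$ad <- damp_band(bands$ad)
    if (level < L) bands$aa <- decompose(bands$aa, level + 1L)
    idwt2(bands, flt)
  }
  out <- decompose(x, 1L)
  out[seq_len(nrow(sino)), seq_len(ncol(sino)), drop = FALSE]
}

#' Paganin phase-retrieval parameters
#'
#' Physical parameters of single-distance propagation-based phase
#' retrieval; all strictly positive, in one consistent length unit.
#' \eqn{\mu = 4\pi\beta/\lambda} is derived, never stored independently.
#'
#' @param pixel_size Detector pixel size.
#' @param dist Sample-detector propagation distance z.
#' @param wavelength X-ray wavelength \eqn{\lambda}; alternatively give
#'   `energy_kev` and the wavelength is derived (lengths then in metres).
#' @param delta Refractive index decrement \eqn{\delta}.
#' @param beta Absorption index \eqn{\beta}.
#' @param energy_kev Photon energy in keV (used if `wavelength` missing).
#' @return List of class `paganin_params` with derived field `mu`.
#' @export
paganin_params <- function(pixel_size, dist, wavelength = NULL, delta, beta,
                           energy_kev = NULL) {
  if (is.null(wavelength)) {
    if (is.null(energy_kev)) stop("give `wavelength` or `energy_kev`")
    wavelength <- 1.23984193e-9 / energy_kev   # metres
  }
  vals <- c(pixel_size = pixel_size, dist = dist, wavelength = wavelength,
            delta = delta, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Paganin parameters must be strictly positive")
  p <- as.list(vals)
  p$mu <- 4 * pi * beta / wavelength
  structure(p, class = "paganin_params")
}

# symmetric-pad a matrix up to nr x nc
pad_symmetric <- function(m, nr, nc) {
  while (nrow(m) < nr) {
    take <- min(nrow(m), nr - nrow(m))
    m <- rbind(m, m[nrow(m):(nrow(m) - take + 1L), , drop = FALSE])
  }
  while (ncol(m) < nc) {
    take <- min(ncol(m), nc - ncol(m))
    m <- cbind(m, m[, ncol(m):(ncol(m) - take + 1L), drop = FALSE])
  }
  m
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

#' Paganin single-step phase retrieval
#'
#' Retrieves projected thickness from a single propagation distance under
#' the homogeneous-object assumption:
#' \deqn{t(x, y) = -\frac{1}{\mu} \ln\!\left( \mathcal F^{-1}\!\left[
#'   \frac{\mathcal F[T]}{1 + (z \delta / \mu) k^2} \right] \right),}
#' with \eqn{k^2 = 4\pi^2 (u^2 + v^2)} in physical spatial-frequency units
#' set by `pixel_size` and \eqn{\mu = 4\pi\beta/\lambda}. Published
#' variants differ in \eqn{4\pi} factors; this convention is pinned by two
#' exact identities: the filter's DC gain is 1 (a constant input maps to
#' \eqn{-\ln(c)/\mu}) and \eqn{\delta \to 0} reduces to plain
#' \eqn{-\ln(T)/\mu}.
#'
#' Each projection is symmetrically padded to the next power of two before
#' the transforms and cropped afterwards. Filtered values that are not
#' strictly positive before the log are floored at the smallest positive
#' normal double; the number of floored pixels is reported via a message
#' and the `n_floored` attribute.
#'
#' @param tr Transmittance: matrix (one projection, rows x cols =
#'   slices x detector) or angles x slices x detector array, all > 0.
#' @param params A [paganin_params()].
#' @return Thickness maps, same shape as `tr` (units of `1/mu` times log
#'   transmittance, i.e. length).
#' @export
paganin_filter <- function(tr, params) {
  stopifnot(inherits(params, "paganin_params"))
  if (any(!is.finite(tr)) || any(tr <= 0))
    stop("transmittance must be strictly positive")
  coef <- params$dist * params$delta / params$mu
  filter_one <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    pr <- if (nr > 1L) next_pow2(nr) else 1L
    pc <- if (nc > 1L) next_pow2(nc) else 1L
    p <- pad_symmetric(m, pr, pc)
    fu <- c(0:(pr %/% 2), -((pr - pr %/% 2 - 1):1)) / (pr * params$pixel_size)
    if (pr == 1L) fu <- 0
    fv <- c(0:(pc %/% 2), -((pc - pc %/% 2 - 1):1)) / (pc * params$pixel_size)
    if (pc == 1L) fv <- 0
    k2 <- 4 * pi^2 * outer(fu^2, fv^2, `+`)
    filt <- 1 / (1 + coef * k2)
    sp <- stats::fft(p) * filt
    out <- Re(stats::fft(sp, inverse = TRUE)) / length(sp)
    out[seq_len(nr), seq_len(nc), drop = FALSE]
  }
  eps <- .Machine$double.xmin
  n_floored <- 0L
  apply_log <- function(f) {
    bad <- f <= 0
    n_floored <<- n_floored + sum(bad)
    f[bad] <- eps
    -log(f) / params$mu
  }
  if (is.matrix(tr)) {
    out <- apply_log(filter_one(tr))
  } else {
    stopifnot(length(dim(tr)) == 3L)
    out <- tr
    for (a in seq_len(dim(tr)[1]))
      out[a, , ] <- apply_log(filter_one(matrix(tr[a, , ],
                                                dim(tr)[2], dim(tr)[3])))
  }
  if (n_floored > 0L)
    message(sprintf("paganin_filter: floored %d non-positive filtered values",
                    n_floored))
  attr(out, "n_floored") <- n_floored
  out
}

#' Shannon entropy of a reconstructed slice
#'
#' 256-bin histogram entropy over the robust (1st-99th percentile)
#' intensity range; the sharpness surrogate minimized by the entropy-based
#' center search.
#' @param img Numeric matrix.
#' @return Entropy in nats.
#' @export
recon_entropy <- function(img) {
  v <- as.vector(img)
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  if (q[2] <= q[1]) return(0)
  v <- pmin(pmax(v, q[1]), q[2])
  h <- tabulate(pmin(1L + as.integer((v - q[1]) / (q[2] - q[1]) * 256), 256L),
                nbins = 256L)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy-based rotation-center search
#'
#' Reconstructs the slice for a grid of trial centers and returns the one
#' whose reconstruction has minimal histogram entropy: a miscentred
#' reconstruction spreads mass into arc artifacts, raising entropy.
#' Ties break toward the smaller center. Optionally one refinement pass
#' repeats the search around the coarse optimum at a tenth of the step.
#'
#' @param sino Sinogram matrix (angles x detector).
#' @param geom A [scan_geometry()] whose `center` seeds the search.
#' @param half_range Search half-width in detector pixels (>= `step`).
#' @param step Search step in pixels (> 0).
#' @param algorithm Reconstruction used for scoring (default `"gridrec"`).
#' @param refine Run the step/10 refinement pass (default `FALSE`).
#' @return The estimated center (0-based detector-pixel coordinate), with
#'   attribute `entropy` holding the evaluated (center, entropy) table.
#' @export
find_center_entropy <- function(sino, geom, half_range = 8, step = 0.5,
                                algorithm = "gridrec", refine = FALSE) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (!is.finite(step) || step <= 0) stop("`step` must be > 0")
  if (half_range < step) stop("`half_range` must be at least `step`")
  scan_once <- function(center0, half, st) {
    trials <- center0 + seq(-half, half, by = st)
    if (length(trials) < 2L) stop("fewer than 2 trial centers")
    ent <- vapply(trials, function(ctr) {
      g <- scan_geometry(geom$n_det, geom$angles, center = ctr,
                         det_width = geom$det_width)
      recon_entropy(recon(sino, geom = g, algorithm = algorithm))
    }, numeric(1))
    list(trials = trials, entropy = ent,
         best = trials[which.min(ent)])   # which.min takes the first tie
  }
  coarse <- scan_once(geom$center, half_range, step)
  best <- coarse$best
  tab <- data.frame(center = coarse$trials, entropy = coarse$entropy)
  if (refine) {
    fine <- scan_once(best, step, step / 10)
    best <- fine$best
    tab <- rbind(tab, data.frame(center = fine$trials, entropy = fine$entropy))
  }
  attr(best, "entropy") <- tab
  best
}
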