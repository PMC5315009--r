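# Per-angle quadrature weights for backprojection-type sums over theta.
# Trapezoidal mid-gap weights with the boundary gaps extended one step, so
# a uniform endpoint-excluded half-turn list reduces exactly to pi / N.
angle_weights <- function(angles) {
  n <- length(angles)
  if (n == 1L) return(pi)
  g <- diff(angles)
  w <- c(g[1], (g[-1] + g[-length(g)]) / 2, g[length(g)])
  w
}

fbp_filter_names <- c("ram-lak", "shepp-logan", "cosine", "hamming", "hann")

# Frequency response (length npad) of the band-limited ramp times an
# apodization window. The ramp is the DFT of the classical discrete
# ramp-filter kernel h[0] = 1/(4 dw^2), h[n odd] = -1/(pi^2 n^2 dw^2),
# which keeps the reconstruction amplitude calibrated.
ramp_filter_response <- function(npad, dw, filter_name) {
  if (!filter_name %in% fbp_filter_names)
    stop(sprintf("unknown filter '%s' (valid: %s)", filter_name,
                 paste(fbp_filter_names, collapse = ", ")))
  n <- c(0:(npad / 2), -(npad / 2 - 1):-1)
  h <- numeric(npad)
  h[n == 0] <- 1 / (4 * dw^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2 * dw^2)
  H <- Re(stats::fft(h))
  f <- n / (npad * dw)                 # signed frequency of each bin
  fn <- 1 / (2 * dw)                   # Nyquist
  r <- abs(f) / fn
  w <- switch(filter_name,
    "ram-lak" = rep(1, npad),
    "shepp-logan" = ifelse(r == 0, 1, sin(pi * r / 2) / (pi * r / 2)),
    "cosine" = cos(pi * r / 2),
    "hamming" = 0.54 + 0.46 * cos(pi * r),
    "hann" = 0.5 * (1 + cos(pi * r)))
  H * w
}

# Ramp-filter every sinogram row (zero-padded circular convolution).
# Returns the filtered sinogram, same shape, scaled as q = (p * h) dw.
filter_sinogram <- function(sino, dw, filter_name) {
  n_det <- ncol(sino)
  npad <- max(64L, 2L^ceiling(log2(2L * n_det)))
  H <- ramp_filter_response(npad, dw, filter_name)
  P <- rbind(t(sino), matrix(0, npad - n_det, nrow(sino)))
  Q <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / npad
  t(Q[seq_len(n_det), , drop = FALSE]) * dw
}

resolve_grid <- function(grid, geom) {
  if (is.null(grid))
    grid <- image_grid(geom$n_det, geom$n_det, pixel_size = geom$det_width)
  grid
}

as_projector_geom <- function(geom) {
  if (inherits(geom, "scan_geometry")) translate_geometry(geom) else geom
}

#' Filtered backprojection
#'
#' Analytic slice reconstruction: each sinogram row is ramp-filtered in the
#' Fourier domain (zero-padded to at least twice the detector length,
#' next power of two; ramp `|f|` apodized by the chosen window), then
#' backprojected with per-angle trapezoidal weights so that non-uniform
#' angle lists are handled and a uniform half-turn list reduces to the
#' classical `pi/N` scaling. The amplitude is calibrated so a unit disk
#' reconstructs to unit value.
#'
#' @param sino Sinogram of line integrals (angles x detector), finite.
#' @param geom A [scan_geometry()] or [projector_geometry()].
#' @param grid Target [image_grid()]; default `n_det` square at detector
#'   pixel size.
#' @param filter_name One of `"ram-lak"`, `"shepp-logan"`, `"cosine"`,
#'   `"hamming"`, `"hann"`.
#' @param kernel Backprojection kernel, `"strip"` (default) or `"line"`.
#' @return Reconstructed slice (`n_y` x `n_x` matrix).
#' @export
fbp <- function(sino, geom, grid = NULL, filter_name = "ram-lak",
                kernel = "strip") {
  pg <- as_projector_geom(geom)
  grid <- resolve_grid(grid, pg)
  if (any(!is.finite(sino))) stop("sinogram must be finite")
  q <- filter_sinogram(sino, pg$det_width, filter_name)
  w <- angle_weights(pg$angles)
  proj <- linear_projector(pg, grid, kernel)
  back_project(q * w, proj) * pg$det_width / grid$pixel_size^2
}

#' Fourier-gridding reconstruction (gridrec)
#'
#' Reconstructs via the Fourier slice theorem: the 1-D FFT of each
#' (window-apodized) projection samples the image's 2-D spectrum along a
#' diametral line; those polar samples are accumulated onto a 2x
#' oversampled Cartesian frequency raster through a separable Kaiser-Bessel
#' kernel (width 7 grid cells, shape parameter per the standard
#' oversampling prescription), with polar density compensation
#' `|f| df dtheta` playing the role of the ramp filter; one inverse 2-D FFT
#' and division by the kernel's deapodization image yield the slice. Cost
#' is dominated by the fixed-size 2-D FFT, making the method attractive
#' when projections are many.
#'
#' Angles are expected approximately uniform (a warning is issued
#' otherwise); the rotation-center offset is applied as a frequency-domain
#' phase ramp.
#'
#' @inheritParams fbp
#' @return Reconstructed slice (`n_y` x `n_x` matrix).
#' @export
gridrec <- function(sino, geom, grid = NULL, filter_name = "ram-lak") {
  pg <- as_projector_geom(geom)
  grid <- resolve_grid(grid, pg)
  if (any(!is.finite(sino))) stop("sinogram must be finite")
  th <- pg$angles
  if (length(th) > 2L) {
    g <- diff(th)
    if (diff(range(g)) > 0.01 * mean(g))
      warning("gridrec expects approximately uniform angles")
  }
  dw <- pg$det_width
  n_det <- pg$n_det
  # radial spectrum sampling at 4x the detector length keeps the polar ->
  # Cartesian interpolation error well below the window roll-off
  npad <- max(64L, 2L^ceiling(log2(4L * n_det)))
  # oversampled Cartesian frequency grid: spacing 1/(M px), M chosen so the
  # image comes out at the grid's pixel size with >= 2x frequency sampling
  px <- grid$pixel_size
  M <- max(2L^ceiling(log2(4L * n_det)),
           2L^ceiling(log2(2 * max(grid$n_x, grid$n_y))))
  dnu <- 1 / (M * px)

  # row FFTs: spectrum sample at f_k = k/(npad dw), with a phase ramp
  # moving the rotation axis (t = 0) to the detector coordinate origin
  P <- rbind(t(sino), matrix(0, npad - n_det, nrow(sino)))
  S <- stats::mvfft(P) * dw
  k <- c(0:(npad / 2 - 1), -(npad / 2):-1)
  f <- k / (npad * dw)
  ctr <- (n_det - 1) / 2 + pg$center_offset
  S <- S * exp(2i * pi * f * ctr * dw)

  # polar density compensation: |f| df dtheta, window-apodized; the f = 0
  # cell carries the mean of |f| over its own half-width (df/8), without
  # which the image DC is lost from the polar quadrature
  fn <- 1 / (2 * dw)
  r <- abs(f) / fn
  win <- switch(filter_name,
    "ram-lak" = rep(1, npad),
    "shepp-logan" = ifelse(r == 0, 1, sin(pi * r / 2) / (pi * r / 2)),
    "cosine" = cos(pi * r / 2),
    "hamming" = 0.54 + 0.46 * cos(pi * r),
    "hann" = 0.5 * (1 + cos(pi * r)),
    stop(sprintf("unknown filter '%s' (valid: %s)", filter_name,
                 paste(fbp_filter_names, collapse = ", "))))
  df <- 1 / (npad * dw)
  absf <- abs(f)
  absf[f == 0] <- df / 8
  ramp <- absf * win * df
  wth <- angle_weights(th)
  kbw <- 7
  osamp <- 2
  beta <- pi * sqrt(kbw^2 / osamp^2 * (osamp - 0.5)^2 - 0.8)

  gu <- gv <- wre <- wim <- vector("list", length(th))
  for (a in seq_along(th)) {
    wk <- S[, a] * (ramp * wth[a])
    gu[[a]] <- f * cos(th[a]) / dnu
    gv[[a]] <- f * sin(th[a]) / dnu
    wre[[a]] <- Re(wk)
    wim[[a]] <- Im(wk)
  }
  G <- kb_grid_cpp(unlist(gu), unlist(gv), unlist(wre), unlist(wim),
                   M, kbw, beta)
  G <- matrix(G, M, M)   # rows = v index, cols = u index, centre at M/2

  # inverse 2-D DFT with the DC bin moved to element (1,1)
  shift <- function(m) {
    ctr2 <- M / 2
    m[c((ctr2 + 1):M, 1:ctr2), c((ctr2 + 1):M, 1:ctr2)]
  }
  img <- Re(stats::fft(shift(G), inverse = TRUE))
  img <- shift(img)      # centre the spatial origin at index M/2

  # deapodization: closed-form continuous transform of the Kaiser-Bessel
  # kernel, including its absolute gain W/I0(beta) so the reconstruction
  # amplitude stays calibrated
  m <- (1:M) - 1 - M / 2
  arg <- beta^2 - (pi * kbw * m / M)^2
  c1 <- ifelse(arg > 0, sinh(sqrt(pmax(arg, 0))) / sqrt(pmax(arg, 1e-300)),
               sin(sqrt(pmax(-arg, 1e-300))) / sqrt(pmax(-arg, 1e-300)))
  c1 <- c1 * kbw / besselI(beta, 0)
  deapo <- outer(c1, c1)
  img <- img / deapo

  # crop the central n_y x n_x block (image pixel i at coordinate
  # (i - (n-1)/2) px corresponds to index M/2 + (i - (n-1)/2))
  iy <- M / 2 + 1 + (seq_len(grid$n_y) - 1 - (grid$n_y - 1) / 2)
  ix <- M / 2 + 1 + (seq_len(grid$n_x) - 1 - (grid$n_x - 1) / 2)
  img[iy, ix, drop = FALSE]
}

#' Simultaneous iterative reconstruction technique (SIRT)
#'
#' Gradient-type iteration on the projection residual with row/column-sum
#' normalization:
#' \deqn{x_{k+1} = \mathrm{clamp}\big(x_k + C A^T R (b - A x_k)\big),}
#' where `R` holds reciprocal row sums and `C` reciprocal column sums of
#' the projection matrix (zero where a sum vanishes), starting from zero.
#' Optional bounds are applied after every update; `min_bound = 0` is the
#' classical nonnegativity constraint. With full column rank the iteration
#' converges to the row-sum-weighted least-squares solution.
#'
#' @inheritParams fbp
#' @param num_iter Number of iterations (>= 1).
#' @param min_bound,max_bound Optional clamp values.
#' @param x0 Optional initial image (default: zeros).
#' @return Reconstructed slice.
#' @export
sirt <- function(sino, geom, grid = NULL, num_iter = 100L, min_bound = NULL,
                 max_bound = NULL, kernel = "strip", x0 = NULL) {
  pg <- as_projector_geom(geom)
  grid <- resolve_grid(grid, pg)
  stopifnot(num_iter >= 1)
  proj <- linear_projector(pg, grid, kernel)
  eps <- .Machine$double.xmin
  rs <- forward_project(matrix(1, grid$n_y, grid$n_x), proj)
  Rinv <- ifelse(rs > eps, 1 / pmax(rs, eps), 0)
  cs <- back_project(matrix(1, nrow(sino), ncol(sino)), proj)
  Cinv <- ifelse(cs > eps, 1 / pmax(cs, eps), 0)
  x <- if (is.null(x0)) matrix(0, grid$n_y, grid$n_x) else x0
  for (k in seq_len(num_iter)) {
    resid <- sino - forward_project(x, proj)
    x <- x + Cinv * back_project(Rinv * resid, proj)
    if (!is.null(min_bound)) x[x < min_bound] <- min_bound
    if (!is.null(max_bound)) x[x > max_bound] <- max_bound
  }
  x
}

#' Conjugate gradient least squares (CGLS)
#'
#' Standard CGLS recurrences on the normal equations
#' \eqn{A^T A x = A^T b}, from a zero initial image, no constraints. The
#' residual norm is non-increasing. On (numerical) breakdown — a vanishing
#' direction norm — the iteration stops early with a message reporting the
#' iteration count.
#'
#' @inheritParams sirt
#' @return Reconstructed slice.
#' @export
cgls <- function(sino, geom, grid = NULL, num_iter = 100L, kernel = "strip") {
  pg <- as_projector_geom(geom)
  grid <- resolve_grid(grid, pg)
  stopifnot(num_iter >= 1)
  proj <- linear_projector(pg, grid, kernel)
  x <- matrix(0, grid$n_y, grid$n_x)
  r <- sino
  s <- back_project(r, proj)
  p <- s
  gamma <- sum(s * s)
  if (gamma == 0) return(x)
  for (k in seq_len(num_iter)) {
    q <- forward_project(p, proj)
    qq <- sum(q * q)
    if (qq == 0) {
      message(sprintf("cgls: breakdown (zero direction norm) at iteration %d",
                      k))
      break
    }
    alpha <- gamma / qq
    x <- x + alpha * p
    r <- r - alpha * q
    s <- back_project(r, proj)
    gamma_new <- sum(s * s)
    if (gamma_new == 0) break
    p <- s + (gamma_new / gamma) * p
    gamma <- gamma_new
  }
  x
}

#' Maximum-likelihood EM and ordered-subset EM reconstruction
#'
#' Multiplicative EM updates for Poisson-distributed projection counts:
#' per sub-iteration over angle subset \eqn{S},
#' \deqn{x \leftarrow \frac{x}{A_S^T 1} \odot
#'       A_S^T\!\left( \frac{b_S}{A_S x} \right),}
#' starting from a uniform positive image; divisions are guarded at the
#' smallest positive normal double. `n_subsets = 1` is classical ML-EM;
#' larger values cycle round-robin interleaved angle blocks (subset `s`
#' takes angles `s, s + n_subsets, ...`), the OSEM acceleration. Updates
#' preserve nonnegativity. Pixels never touched by some subset (zero
#' sensitivity) are only tolerated when no other subset sees them either;
#' an imbalanced subset design raises an error.
#'
#' @param sino Nonnegative counts-domain sinogram (angles x detector).
#' @inheritParams sirt
#' @param n_subsets Number of ordered subsets (>= 1).
#' @return Reconstructed slice.
#' @export
em_recon <- function(sino, geom, grid = NULL, num_iter = 20L,
                     n_subsets = 1L, kernel = "strip") {
  pg <- as_projector_geom(geom)
  grid <- resolve_grid(grid, pg)
  stopifnot(num_iter >= 1, n_subsets >= 1)
  if (any(sino < 0)) stop("EM requires a non-negative sinogram")
  n_ang <- length(pg$angles)
  n_subsets <- as.integer(min(n_subsets, n_ang))
  eps <- .Machine$double.xmin
  subsets <- lapply(seq_len(n_subsets) - 1L,
                    function(s) which((seq_len(n_ang) - 1L) %% n_subsets == s))
  projs <- lapply(subsets, function(idx) {
    g <- projector_geometry(pg$n_det, pg$angles[idx],
                            center_offset = pg$center_offset,
                            det_width = pg$det_width)
    linear_projector(g, grid, kernel)
  })
  sens <- lapply(seq_len(n_subsets), function(s)
    back_project(matrix(1, length(subsets[[s]]), pg$n_det), projs[[s]]))
  touched <- lapply(sens, function(s) s > eps)
  if (n_subsets > 1L) {
    anyhit <- Reduce(`|`, touched)
    allhit <- Reduce(`&`, touched)
    if (any(anyhit & !allhit))
      stop("subset design imbalance: some pixels are seen by only part of ",
           "the subsets; reduce n_subsets")
  }
  x <- matrix(1, grid$n_y, grid$n_x)
  for (k in seq_len(num_iter)) {
    for (s in seq_len(n_subsets)) {
      bs <- sino[subsets[[s]], , drop = FALSE]
      ax <- forward_project(x, projs[[s]])
      ratio <- bs / pmax(ax, eps)
      x <- x / pmax(sens[[s]], eps) * back_project(ratio, projs[[s]])
      x[!touched[[s]]] <- 0
    }
  }
  x
}

#' Poisson log-likelihood of a sinogram given an image
#'
#' \eqn{\sum_i b_i \log (A x)_i - (A x)_i} (constant terms dropped),
#' the objective that ML-EM ascends.
#'
#' @param sino Observed counts-domain sinogram.
#' @param image Current image estimate.
#' @param proj A [linear_projector()].
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(sino, image, proj) {
  ax <- forward_project(image, proj)
  eps <- .Machine$double.xmin
  sum(sino * log(pmax(ax, eps)) - ax)
}
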