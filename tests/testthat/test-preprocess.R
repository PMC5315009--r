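test_that("flat/dark normalization computes and clips transmittance", {
  mk <- function(val, na = 4, nd = 6) array(val, c(na, 1, nd))
  flats <- array(200, c(3, 1, 6))
  darks <- array(100, c(2, 1, 6))
  expect_equal(normalize_raw(mk(200), flats, array(0, c(2, 1, 6))),
               mk(1), tolerance = 1e-15)
  expect_equal(normalize_raw(mk(150), flats, darks), mk(0.5),
               tolerance = 1e-15)
  # I = dark mean: clipped to the positive floor
  t0 <- normalize_raw(mk(100), flats, darks)
  expect_true(all(t0 == .Machine$double.xmin))
  # cutoff above 1 admits phase-contrast overshoot
  t2 <- normalize_raw(mk(260), flats, darks, cutoff = 2)
  expect_equal(t2, mk(1.6), tolerance = 1e-15)
  expect_true(all(normalize_raw(mk(260), flats, darks) <= 1))
  expect_error(normalize_raw(mk(150), array(1, c(2, 1, 6)),
                             array(50, c(2, 1, 6))),
               "does not exceed")
})

test_that("minus_log is the Beer-Lambert inverse and rejects bad input", {
  expect_identical(minus_log(1), 0)
  expect_equal(minus_log(exp(-1)), 1)
  expect_error(minus_log(c(0.5, 0)), "strictly positive")
  expect_error(minus_log(c(0.5, -1)), "strictly positive")
})

test_that("zinger correction leaves a constant image untouched", {
  expect_equal(remove_zingers(matrix(7, 9, 9), 1.5),
               matrix(7, 9, 9), ignore_attr = TRUE)
})

test_that("zinger fill-in equals the brute-force window median", {
  set.seed(3)
  img <- matrix(100 + rnorm(40 * 40, sd = 2), 40, 40)
  spiked <- img
  spiked[12, 25] <- 1000
  fixed <- remove_zingers(spiked, threshold = 1.5, size = 3)
  expect_equal(fixed[12, 25], median(spiked[11:13, 24:26]))
  expect_identical(attr(fixed, "n_replaced"), 1L)
  others <- fixed
  others[12, 25] <- spiked[12, 25]
  expect_identical(others, structure(spiked, n_replaced = 1L))
  # no false replacements on spike-free noise at a conservative threshold
  clean <- remove_zingers(img, threshold = 10)
  expect_identical(attr(clean, "n_replaced"), 0L)
  # idempotence: a second pass replaces nothing and changes no values
  again <- remove_zingers(fixed, threshold = 1.5, size = 3)
  expect_identical(attr(again, "n_replaced"), 0L)
  expect_identical(as.vector(again), as.vector(fixed))
  expect_error(remove_zingers(img, size = 4), "odd")
  expect_error(remove_zingers(img, threshold = 1), "> 1")
})

test_that("the in-package wavelet bank reconstructs perfectly", {
  set.seed(9)
  x <- matrix(rnorm(64 * 96), 64, 96)
  for (w in c("haar", "db2", "db4", "db8", "sym8")) {
    flt <- tomoslice:::wavelet_filters(w)
    bands <- tomoslice:::dwt2(x, flt)
    expect_equal(tomoslice:::idwt2(bands, flt), x, tolerance = 1e-10)
    # orthonormality: energy is conserved across the band split
    expect_equal(sum(x^2),
                 sum(vapply(bands, function(b) sum(b^2), numeric(1))),
                 tolerance = 1e-8)
  }
  expect_error(tomoslice:::wavelet_filters("db97"), "unknown wavelet")
})

test_that("wavelet-Fourier filtering suppresses stripes, spares structure", {
  set.seed(4)
  na <- 360; nd <- 256
  s0 <- gaussian_sinogram(na, nd)
  stripes <- matrix(rnorm(nd, sd = 0.05 * diff(range(s0))), na, nd,
                    byrow = TRUE)
  sc <- s0 + stripes
  out <- remove_rings_wavelet_fourier(sc)
  stat <- function(s) sqrt(mean((colMeans(s) - colMeans(s0))^2))
  expect_identical(dim(out), dim(sc))
  expect_true(all(is.finite(out)))
  expect_gte(1 - stat(out) / stat(sc), 0.8)
  # stripe-free smooth sinogram is barely perturbed
  clean <- remove_rings_wavelet_fourier(s0)
  expect_lte(rmse(clean, s0) / diff(range(s0)), 0.01)
})

test_that("the damping vanishes for moving content as sigma shrinks", {
  set.seed(8)
  na <- 128; nd <- 128
  s0 <- gaussian_sinogram(na, nd)
  # sigma -> 0+: g is ~0 only at k = 0, so only the angle-constant stripe
  # component is removed and the output approaches the input elsewhere
  tiny <- ring_removal_params(n_levels = 4, sigma = 1e-6)
  stripes <- matrix(rnorm(nd, sd = 0.2), na, nd, byrow = TRUE)
  out <- remove_rings_wavelet_fourier(s0 + stripes, tiny)
  resid <- out - s0
  # what survives of the stripes is far smaller than what was injected
  expect_lt(sqrt(mean(resid^2)), 0.5 * sqrt(mean(stripes^2)))
  expect_lte(rmse(remove_rings_wavelet_fourier(s0, tiny), s0) /
               diff(range(s0)), 0.01)
  expect_error(remove_rings_wavelet_fourier(matrix(0, 8, 8),
                                            ring_removal_params(n_levels = 5)),
               "too deep")
  expect_error(ring_removal_params(sigma = 0), "positive")
})

test_that("Paganin filtering reduces to -log(T)/mu when delta vanishes", {
  set.seed(2)
  tr <- matrix(runif(48 * 48, 0.3, 0.9), 48, 48)
  p0 <- paganin_params(pixel_size = 1e-6, dist = 1e-300, energy_kev = 20,
                       delta = 1e-300, beta = 1e-9)
  expect_equal(paganin_filter(tr, p0), -log(tr) / p0$mu,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the Paganin filter has unit DC gain and damps high frequencies", {
  pp <- paganin_params(pixel_size = 1e-6, dist = 0.05, energy_kev = 20,
                       delta = 1e-7, beta = 1e-9)
  out <- paganin_filter(matrix(0.5, 32, 32), pp)
  expect_equal(out, matrix(-log(0.5) / pp$mu, 32, 32),
               tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(6)
  tr <- matrix(runif(64 * 64, 0.2, 0.95), 64, 64)
  out2 <- paganin_filter(tr, pp)
  expect_lte(var(as.vector(out2)), var(as.vector(-log(tr) / pp$mu)))
  expect_true(all(is.finite(out2)))
  expect_error(paganin_params(pixel_size = 0, dist = 1, energy_kev = 20,
                              delta = 1e-7, beta = 1e-9),
               "strictly positive")
  # mu is derived, not free: mu = 4 pi beta / lambda
  expect_equal(pp$mu, 4 * pi * 1e-9 / pp$wavelength)
})

test_that("entropy search recovers an injected rotation-center shift", {
  ds <- make_limited_angle_dataset(n = 128, block_above_deg = 180,
                                   step_deg = 1, drop_last = FALSE,
                                   center_shift = 3.5, seed = 21, I0 = 1e4)
  sino <- minus_log(normalize_raw(ds$data, ds$flats, ds$darks))
  s2 <- matrix(sino[, 1, ], dim(sino)[1], 128)
  guess <- scan_geometry(128, ds$angles, det_width = 2 / 128)
  est <- find_center_entropy(s2, guess, half_range = 8, step = 0.5)
  expect_lte(abs(as.numeric(est) - ds$truth$geometry$center), 0.25)
  # the evaluated entropy curve attains its minimum at the estimate
  tab <- attr(est, "entropy")
  expect_equal(tab$center[which.min(tab$entropy)], as.numeric(est))
})

test_that("a centred scan yields a centred estimate", {
  ds <- make_limited_angle_dataset(n = 96, block_above_deg = 180,
                                   step_deg = 1.5, drop_last = FALSE,
                                   seed = 22, I0 = 1e4)
  sino <- minus_log(normalize_raw(ds$data, ds$flats, ds$darks))
  s2 <- matrix(sino[, 1, ], dim(sino)[1], 96)
  est <- find_center_entropy(s2, scan_geometry(96, ds$angles,
                                               det_width = 2 / 96),
                             half_range = 4, step = 0.5)
  expect_lte(abs(as.numeric(est) - (96 - 1) / 2), 0.25)
  expect_error(find_center_entropy(s2, scan_geometry(96, ds$angles),
                                   half_range = 1, step = 0),
               "> 0")
})
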