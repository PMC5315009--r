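# Shared fixtures, all built in code.

deg <- function(x) x * pi / 180

# half-turn scan over an n x n grid in [-1, 1]^2
square_scan <- function(n, n_angles, center_shift = 0) {
  scan_geometry(n, build_angles(n_angles, 0, pi),
                center = (n - 1) / 2 + center_shift, det_width = 2 / n)
}

square_grid <- function(n) image_grid(n, n, pixel_size = 2 / n)

unit_disk <- function(r = 0.6, rho = 1) ellipse_phantom(0, 0, r, r, 0, rho)

# mask of pixels well inside a centred disk of radius r (grid units)
disk_interior <- function(n, r) {
  xs <- (seq_len(n) - 1 - (n - 1) / 2) * 2 / n
  sqrt(outer(xs^2, xs^2, `+`)) < r
}

# smooth radially-symmetric slice: Radon transform of a 2-D Gaussian is a
# 1-D Gaussian, so this sinogram is angle-constant and smooth at all
# detector scales
gaussian_sinogram <- function(n_angles, n_det, sd = 0.35, amp = 2) {
  tt <- (seq_len(n_det) - 1 - (n_det - 1) / 2) * (2 / n_det)
  matrix(rep(amp * exp(-tt^2 / (2 * sd^2)), each = n_angles),
         n_angles, n_det)
}

# the 16 x 16 / 24-angle system used for dense-matrix oracle tests,
# with a smooth consistent target
tiny_system <- function() {
  geom <- scan_geometry(23, build_angles(24, 0, pi), det_width = 2 / 16)
  grid <- image_grid(16, 16, pixel_size = 2 / 16)
  proj <- linear_projector(translate_geometry(geom), grid, "strip")
  xs <- (seq_len(16) - 1 - 15 / 2) * 2 / 16
  target <- 0.5 * exp(-outer(xs^2, xs^2, `+`) / (2 * 0.35^2))
  list(geom = geom, grid = grid, proj = proj, target = target,
       b = forward_project(target, proj))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

expect_no_plugin <- function(name) {
  if (name %in% list_algorithms()$plugins) unregister_plugin(name)
  invisible(NULL)
}
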