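test_that("strip and line kernels match the analytic ellipse sinogram", {
  n <- 256
  geom <- square_scan(n, 180)
  grid <- square_grid(n)
  ph <- unit_disk(0.6)
  ref <- analytic_sinogram(ph, geom)
  img <- rasterize_phantom(ph, grid, supersample = 4)
  for (spec in list(c("strip", 0.02), c("line", 0.05))) {
    proj <- linear_projector(translate_geometry(geom), grid, spec[1])
    fp <- forward_project(img, proj)
    expect_lte(sqrt(sum((fp - ref)^2) / sum(ref^2)), as.numeric(spec[2]))
  }
})

test_that("projection operators are linear and vanish on zero input", {
  geom <- square_scan(32, 24)
  grid <- square_grid(32)
  for (k in c("strip", "line")) {
    proj <- linear_projector(geom, grid, k)
    expect_identical(forward_project(matrix(0, 32, 32), proj),
                     matrix(0, 24, 32))
    expect_identical(back_project(matrix(0, 24, 32), proj),
                     matrix(0, 32, 32))
    set.seed(13)
    x <- matrix(rnorm(32 * 32), 32, 32)
    y <- matrix(rnorm(32 * 32), 32, 32)
    expect_equal(forward_project(2 * x - 3 * y, proj),
                 2 * forward_project(x, proj) - 3 * forward_project(y, proj),
                 tolerance = 1e-12)
  }
})

test_that("a single centre pixel projects into one dominant bin", {
  n <- 33
  geom <- scan_geometry(n, 0)   # theta = 0, unit pixels
  grid <- image_grid(n)
  img <- matrix(0, n, n)
  img[17, 17] <- 1
  for (k in c("strip", "line")) {
    s <- forward_project(img, linear_projector(geom, grid, k))
    expect_equal(s[1, 17], 1)              # pixel_size worth of path
    expect_equal(sum(s[1, -17]), 0)
  }
})

test_that("backprojection passes the adjoint dot test at 1e-10", {
  set.seed(42)
  for (k in c("strip", "line")) {
    for (off in c(0, 0.7, -2.3)) {
      pg <- projector_geometry(32, build_angles(48, 0, pi),
                               center_offset = off)
      proj <- linear_projector(pg, image_grid(32), k)
      x <- matrix(rnorm(32 * 32), 32, 32)
      y <- matrix(rnorm(48 * 32), 48, 32)
      ax <- forward_project(x, proj)
      aty <- back_project(y, proj)
      gap <- abs(sum(ax * y) - sum(x * aty)) /
        (sqrt(sum(ax^2)) * sqrt(sum(y^2)))
      expect_lte(gap, 1e-10)
    }
  }
})

test_that("rotationally symmetric images project angle-independently", {
  # a smooth radial profile, so rasterization error does not masquerade
  # as projector anisotropy
  n <- 128
  geom <- square_scan(n, 40)
  xs <- (seq_len(n) - 1 - (n - 1) / 2) * 2 / n
  img <- exp(-outer(xs^2, xs^2, `+`) / (2 * 0.25^2))
  s <- forward_project(img, linear_projector(geom, square_grid(n), "strip"))
  spread <- apply(s, 2, function(col) diff(range(col)))
  expect_lte(max(spread) / max(s), 0.005)
})

test_that("the sparse-matrix view reproduces the operators", {
  geom <- square_scan(16, 12)
  grid <- square_grid(16)
  for (k in c("strip", "line")) {
    proj <- linear_projector(geom, grid, k)
    A <- as_matrix(proj)
    expect_identical(dim(A), c(12L * 16L, 256L))
    set.seed(5)
    x <- matrix(rnorm(256), 16, 16)
    y <- matrix(rnorm(12 * 16), 12, 16)
    fp <- forward_project(x, proj)
    expect_equal(as.vector(A %*% as.vector(x)), as.vector(t(fp)),
                 tolerance = 1e-12)
    expect_equal(as.vector(Matrix::t(A) %*% as.vector(t(y))),
                 as.vector(back_project(y, proj)), tolerance = 1e-12)
  }
})

test_that("strip-kernel row sums equal the ray path length in the square", {
  n <- 24
  geom <- square_scan(n, 16)
  grid <- square_grid(n)
  A <- as_matrix(linear_projector(geom, grid, "strip"))
  rs <- Matrix::rowSums(A)
  px <- grid$pixel_size
  half <- n * px / 2
  k <- 0
  for (a in seq_along(geom$angles)) {
    th <- geom$angles[a]
    for (j in seq_len(n)) {
      k <- k + 1
      # brute force: average chord length of the square over the strip,
      # which is exactly what the exact-area weights sum to
      offs <- ((1:9) - 5) / 9 * geom$det_width
      ss <- seq(-2 * half, 2 * half, length.out = 4000)
      chords <- vapply(offs, function(o) {
        t0 <- (j - 1 - geom$center) * geom$det_width + o
        xs <- t0 * cos(th) - ss * sin(th)
        ys <- t0 * sin(th) + ss * cos(th)
        mean(abs(xs) <= half & abs(ys) <= half) * diff(range(ss))
      }, numeric(1))
      chord <- mean(chords)
      expect_lte(abs(rs[k] - chord), 0.03 * max(chord, px))
    }
  }
})

test_that("a one-hot sinogram backprojects onto a single ray's support", {
  geom <- square_scan(16, 8)
  grid <- square_grid(16)
  for (k in c("strip", "line")) {
    proj <- linear_projector(geom, grid, k)
    A <- as_matrix(proj)
    s <- matrix(0, 8, 16)
    s[3, 9] <- 1
    bp <- back_project(s, proj)
    col <- as.vector(A[(3 - 1) * 16 + 9, ])
    expect_equal(as.vector(bp), col, tolerance = 1e-12)
    expect_identical(which(as.vector(bp) != 0), which(col != 0))
  }
})

test_that("oversized explicit assembly and bad kernels are refused", {
  big <- scan_geometry(512, build_angles(360, 0, pi))
  expect_error(as_matrix(linear_projector(big, image_grid(512), "strip")),
               "refusing")
  g <- square_scan(8, 4)
  expect_error(linear_projector(g, square_grid(8), "cuda"),
               "unsupported backend")
  expect_error(linear_projector(g, square_grid(8), "voxel"),
               "unknown projection kernel")
})
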