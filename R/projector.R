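#' Matched forward/back-projection operator
#'
#' Bundles a [projector_geometry()] and an [image_grid()] with a
#' discretization kernel into a linear operator pair. Two CPU kernels are
#' available:
#' \describe{
#'   \item{`"strip"`}{exact pixel/strip intersection area divided by the
#'     detector bin width — the exact-area kernel;}
#'   \item{`"line"`}{Joseph's interpolating kernel: rays cast at detector
#'     bin centres, stepping along the dominant axis with linear
#'     interpolation transverse, scaled by the step length.}
#' }
#' Backprojection enumerates exactly the same (ray, pixel, weight) triples
#' as forward projection, so the adjoint identity
#' \eqn{\langle A x, y \rangle = \langle x, A^T y \rangle} holds to float
#' round-off by construction. The kernel name `"cuda"` is recognized as the
#' GPU kernel of other toolboxes and rejected: this is a CPU-only build.
#'
#' @param geom A [projector_geometry()] (or a [scan_geometry()], which is
#'   translated automatically).
#' @param grid An [image_grid()].
#' @param kernel `"strip"` or `"line"`.
#' @return An object of class `linear_projector`.
#' @export
linear_projector <- function(geom, grid, kernel = c("strip", "line")) {
  if (inherits(geom, "scan_geometry")) geom <- translate_geometry(geom)
  stopifnot(inherits(geom, "projector_geometry"), inherits(grid, "image_grid"))
  if (identical(kernel, "cuda"))
    stop("unsupported backend: 'cuda' projection kernels require a GPU ",
         "build; this package is CPU-only (kernels: strip, line)")
  if (length(kernel) == 1L && !kernel %in% c("strip", "line"))
    stop(sprintf("unknown projection kernel '%s' (valid: strip, line)",
                 kernel))
  kernel <- match.arg(kernel)
  structure(list(geom = geom, grid = grid, kernel = kernel),
            class = "linear_projector")
}

#' @export
print.linear_projector <- function(x, ...) {
  cat(sprintf(
    "<linear_projector> %s kernel: %d angles x %d bins <-> %d x %d image\n",
    x$kernel, length(x$geom$angles), x$geom$n_det, x$grid$n_y, x$grid$n_x))
  invisible(x)
}

proj_apply <- function(x, proj, forward) {
  g <- proj$geom
  gr <- proj$grid
  proj_apply_cpp(as.numeric(x), forward, proj$kernel == "strip",
                 length(g$angles), g$n_det, g$det_width, g$center_offset,
                 gr$n_x, gr$n_y, gr$pixel_size, cos(g$angles), sin(g$angles))
}

#' Forward projection (Radon transform) of an image
#'
#' @param image `n_y` x `n_x` matrix matching the projector's grid.
#' @param proj A [linear_projector()].
#' @return Sinogram matrix, rows = angles, columns = detector bins.
#' @export
forward_project <- function(image, proj) {
  stopifnot(inherits(proj, "linear_projector"))
  if (!is.matrix(image) ||
      nrow(image) != proj$grid$n_y || ncol(image) != proj$grid$n_x)
    stop(sprintf("image must be a %d x %d matrix",
                 proj$grid$n_y, proj$grid$n_x))
  out <- proj_apply(image, proj, forward = TRUE)
  # rays are enumerated ray = angle * n_det + bin: bin varies fastest
  matrix(out, length(proj$geom$angles), proj$geom$n_det, byrow = TRUE)
}

#' Backprojection of a sinogram
#'
#' The exact transpose of [forward_project()] for the same kernel.
#'
#' @param sino Sinogram matrix (angles x detector bins).
#' @param proj A [linear_projector()].
#' @return `n_y` x `n_x` image matrix.
#' @export
back_project <- function(sino, proj) {
  stopifnot(inherits(proj, "linear_projector"))
  if (!is.matrix(sino) || nrow(sino) != length(proj$geom$angles) ||
      ncol(sino) != proj$geom$n_det)
    stop(sprintf("sinogram must be a %d x %d matrix",
                 length(proj$geom$angles), proj$geom$n_det))
  out <- proj_apply(t(sino), proj, forward = FALSE)
  matrix(out, proj$grid$n_y, proj$grid$n_x)
}

#' Explicit sparse-matrix view of a projector
#'
#' Assembles the projector as a `dgCMatrix` with one row per ray (ray
#' index = angle * n_det + bin, bin fastest) and one column per pixel
#' (column-major pixel order, matching `as.vector(image)`). Applying the
#' matrix reproduces [forward_project()]; its transpose reproduces
#' [back_project()]. Intended for small systems — dense oracles, direct
#' solvers, teaching; refuses assembly when
#' `n_rays * n_pixels > 1e7` potential entries.
#'
#' @param proj A [linear_projector()].
#' @return A sparse matrix of class `dgCMatrix`.
#' @export
as_matrix <- function(proj) {
  stopifnot(inherits(proj, "linear_projector"))
  g <- proj$geom
  gr <- proj$grid
  n_rays <- length(g$angles) * g$n_det
  n_pix <- gr$n_x * gr$n_y
  if (as.numeric(n_rays) * n_pix > 1e7)
    stop(sprintf(
      "refusing explicit assembly: %d rays x %d pixels exceeds 1e7 potential entries; use forward_project/back_project operators instead",
      n_rays, n_pix))
  tr <- proj_triplets_cpp(proj$kernel == "strip", length(g$angles), g$n_det,
                          g$det_width, g$center_offset, gr$n_x, gr$n_y,
                          gr$pixel_size, cos(g$angles), sin(g$angles))
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$w,
                       dims = c(n_rays, n_pix))
}
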