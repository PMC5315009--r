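#' Reconstruction options
#'
#' The option record consumed by [recon()], mirroring the conventional
#' option vocabulary of slice-reconstruction toolboxes: algorithm name,
#' projection kernel, iteration count, analytic filter, optional bounds,
#' ordered-subset count, an open extra-options map handed to algorithms
#' and plugins untouched, and a GPU index list that this CPU-only build
#' accepts but ignores (with a single warning).
#'
#' @param algorithm Algorithm name: a built-in (`fbp`, `gridrec`, `sirt`,
#'   `cgls`, `em`) or a registered plugin name.
#' @param proj_type Projection kernel: `"strip"` or `"line"` (`"cuda"` is
#'   rejected as an unsupported backend).
#' @param num_iter Iterations for iterative algorithms (>= 1).
#' @param filter_name FBP/gridrec apodization window.
#' @param min_bound,max_bound Optional clamps (iterative algorithms).
#' @param n_subsets Ordered-subset count for `em` (>= 1).
#' @param extra Named list of extra options passed through untouched
#'   (plugins read their parameters here, e.g. `tv_reg`).
#' @param gpu_list Integer vector of GPU indices; accepted and inert.
#' @return List of class `recon_options`.
#' @export
recon_options <- function(algorithm = "gridrec", proj_type = "strip",
                          num_iter = 100L, filter_name = "ram-lak",
                          min_bound = NULL, max_bound = NULL,
                          n_subsets = 1L, extra = list(),
                          gpu_list = NULL) {
  stopifnot(num_iter >= 1, n_subsets >= 1, is.list(extra))
  structure(list(algorithm = algorithm, proj_type = proj_type,
                 num_iter = as.integer(num_iter), filter_name = filter_name,
                 min_bound = min_bound, max_bound = max_bound,
                 n_subsets = as.integer(n_subsets), extra = extra,
                 gpu_list = gpu_list),
            class = "recon_options")
}

builtin_algorithms <- function() c("fbp", "gridrec", "sirt", "cgls", "em")

# Table-1 methods deliberately outside this package's scope.
out_of_scope_algorithms <- function()
  c("art", "bart", "sart", "pml", "ospml")

#' Reconstruct slices with a named algorithm
#'
#' The single dispatch front-end: builds the scan geometry from the data
#' shape, the angle list and the rotation center, translates it to the
#' projector-level geometry, and hands each slice independently to the
#' named built-in algorithm or registered plugin. Switching algorithms is
#' a one-argument change; all resolved options are logged at INFO level.
#'
#' @param data A sinogram matrix (angles x detector) or an
#'   angles x slices x detector array.
#' @param angles Projection angles in radians (defaults to a uniform
#'   endpoint-excluded half turn).
#' @param center Rotation center in 0-based detector pixels (default:
#'   detector midpoint).
#' @param algorithm Algorithm name; see [recon_options()]. Overrides the
#'   name in `options`.
#' @param options A [recon_options()] record.
#' @param geom Alternatively, a ready-made [scan_geometry()] (overrides
#'   `angles`/`center`).
#' @param grid Target [image_grid()]; default square at detector size.
#' @param ... Convenience: fields of [recon_options()] given directly
#'   (e.g. `num_iter = 50`, `min_bound = 0`).
#' @return A slice matrix for matrix input, or an `n_y` x `n_x` x n_slices
#'   array for stack input.
#' @export
#' @examples
#' sl <- shepp_logan(64)
#' g <- scan_geometry(64, build_angles(90, 0, pi), det_width = 2 / 64)
#' sino <- analytic_sinogram(sl$phantom, g)
#' rec <- recon(sino, geom = g, algorithm = "fbp")
recon <- function(data, angles = NULL, center = NULL, algorithm = NULL,
                  options = NULL, geom = NULL, grid = NULL, ...) {
  if (is.null(options)) options <- recon_options(...)
  if (!inherits(options, "recon_options"))
    stop("`options` must come from recon_options()")
  dots <- list(...)
  for (nm in names(dots)) options[[nm]] <- dots[[nm]]
  if (!is.null(algorithm)) options$algorithm <- algorithm
  alg <- tolower(options$algorithm)

  stack <- if (is.matrix(data)) array(data, c(nrow(data), 1L, ncol(data)))
           else data
  if (length(dim(stack)) != 3L)
    stop("`data` must be a sinogram matrix or an angles x slices x detector array")
  n_ang <- dim(stack)[1]; n_slice <- dim(stack)[2]; n_det <- dim(stack)[3]

  if (is.null(geom)) {
    if (is.null(angles)) angles <- build_angles(n_ang, 0, pi)
    if (length(angles) != n_ang)
      stop(sprintf("%d angles for %d projections", length(angles), n_ang))
    if (is.null(center)) center <- (n_det - 1) / 2
    geom <- scan_geometry(n_det, angles, center = center)
  }
  stopifnot(inherits(geom, "scan_geometry"))
  pg <- translate_geometry(geom)
  grid <- resolve_grid(grid, pg)

  # bounds and filter may equivalently travel in the extra-options map
  # (the MinConstraint-style convention); explicit extra entries win
  for (k in c("min_bound", "max_bound", "filter_name", "n_subsets"))
    if (!is.null(options$extra[[k]])) options[[k]] <- options$extra[[k]]

  if (!is.null(options$gpu_list))
    warning("CPU-only build, gpu_list ignored")
  if (identical(options$proj_type, "cuda"))
    stop("unsupported backend: 'cuda' projection kernels require a GPU ",
         "build; this package is CPU-only (kernels: strip, line)")

  if (alg %in% out_of_scope_algorithms())
    stop(sprintf(
      "algorithm '%s' is not implemented: this package covers the %s subset by design",
      alg, paste(builtin_algorithms(), collapse = ", ")))

  plugin <- plugin_lookup(alg)
  if (!is.null(plugin)) {
    missing_opts <- setdiff(plugin$required_options, names(options$extra))
    if (length(missing_opts))
      stop(sprintf("plugin '%s' requires extra option(s): %s", alg,
                   paste(missing_opts, collapse = ", ")))
  }
  if (!alg %in% builtin_algorithms() && is.null(plugin))
    stop(sprintf("unknown algorithm '%s'; built-ins: %s; plugins: %s",
                 alg, paste(builtin_algorithms(), collapse = ", "),
                 if (length(list_algorithms()$plugins))
                   paste(list_algorithms()$plugins, collapse = ", ")
                 else "(none)"))

  log_msg("info", sprintf(
    "recon: algorithm=%s proj_type=%s num_iter=%d filter=%s n_subsets=%d slices=%d",
    alg, options$proj_type, options$num_iter, options$filter_name,
    options$n_subsets, n_slice))

  solve_one <- if (!is.null(plugin)) {
    projector <- linear_projector(pg, grid, options$proj_type)
    plugin$factory(projector, options)
  } else {
    switch(alg,
      fbp = function(s) fbp(s, pg, grid, options$filter_name,
                            options$proj_type),
      gridrec = function(s) gridrec(s, pg, grid, options$filter_name),
      sirt = function(s) sirt(s, pg, grid, options$num_iter,
                              options$min_bound, options$max_bound,
                              options$proj_type, x0 = options$extra$x0),
      cgls = function(s) cgls(s, pg, grid, options$num_iter,
                              options$proj_type),
      em = function(s) em_recon(s, pg, grid, options$num_iter,
                                options$n_subsets, options$proj_type))
  }

  out <- array(0, c(grid$n_y, grid$n_x, n_slice))
  for (s in seq_len(n_slice))
    out[, , s] <- solve_one(matrix(stack[, s, ], n_ang, n_det))
  if (is.matrix(data)) out[, , 1] else out
}
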