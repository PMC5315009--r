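# Registry of user-supplied reconstruction algorithms. Plugins dispatch
# through recon() exactly like built-ins: the registry maps a name to a
# factory that receives the already-translated projector and the resolved
# options, and returns a function(sinogram) -> slice.

.plugins <- new.env(parent = emptyenv())

#' Describe a reconstruction plugin
#'
#' @param name Dispatch name; nonempty, unique, must not shadow a built-in
#'   algorithm.
#' @param factory `function(projector, options)` returning a
#'   `function(sino)` that reconstructs one slice. `projector` is a
#'   [linear_projector()] over the translated geometry; `options` the
#'   resolved [recon_options()] (plugin parameters live in
#'   `options$extra`).
#' @param required_options Character vector of `extra` keys the plugin
#'   demands; [recon()] verifies their presence before calling the factory.
#' @return List of class `plugin_spec`.
#' @export
plugin_spec <- function(name, factory, required_options = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("plugin name must be a nonempty string")
  if (!is.function(factory)) stop("`factory` must be a function")
  structure(list(name = tolower(name), factory = factory,
                 required_options = required_options),
            class = "plugin_spec")
}

#' Register a reconstruction plugin
#'
#' After registration the plugin's name is immediately resolvable by
#' [recon()] and listed by [list_algorithms()].
#'
#' @param spec A [plugin_spec()].
#' @return The name, invisibly.
#' @export
register_plugin <- function(spec) {
  stopifnot(inherits(spec, "plugin_spec"))
  if (spec$name %in% builtin_algorithms())
    stop(sprintf("plugin name '%s' shadows a built-in algorithm", spec$name))
  if (!is.null(.plugins[[spec$name]]))
    stop(sprintf("a plugin named '%s' is already registered", spec$name))
  assign(spec$name, spec, envir = .plugins)
  invisible(spec$name)
}

#' @rdname register_plugin
#' @param name Plugin name to remove; removing an unknown name is an error.
#' @export
unregister_plugin <- function(name) {
  name <- tolower(name)
  if (is.null(.plugins[[name]]))
    stop(sprintf("no plugin named '%s' is registered", name))
  rm(list = name, envir = .plugins)
  invisible(name)
}

plugin_lookup <- function(name) {
  p <- .plugins[[tolower(name)]]
  if (is.null(p)) return(NULL)
  p
}

#' List available reconstruction algorithms
#'
#' @return List with `builtins` (fixed, stable order) and `plugins`
#'   (registered names, sorted).
#' @export
list_algorithms <- function() {
  list(builtins = builtin_algorithms(),
       plugins = sort(ls(envir = .plugins)))
}
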