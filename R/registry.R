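# Package-local registries mapping method names to callables, so the
# evaluation drivers and the CLI can address normalizers and DE methods by
# name, and external tools' gene lists can be plugged in.
.registries <- new.env(parent = emptyenv())
.registries$normalizers <- list()
.registries$de_methods <- list()

register_builtin_methods <- function() {
  if (!length(.registries$normalizers)) {
    .registries$normalizers <- list(
      two_step = function(matrix) two_step_normalize(matrix),
      quantile = function(matrix) quantile_normalize(matrix),
      lowess   = function(matrix) lowess_normalize(matrix)
    )
  }
  if (!length(.registries$de_methods)) {
    .registries$de_methods <- list(
      associative = function(control, experimental, restrictions) {
        associative_analysis(control, experimental, restrictions)
      },
      ttest_bh = function(control, experimental, restrictions) {
        ttest_bh_baseline(control, experimental,
                          alpha = restrictions$alpha_student,
                          fold_min = restrictions$Fa)
      }
    )
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_methods()
}

#' Register a normalization method by name
#'
#' Adds a `function(matrix) -> matrix` under a unique name, making it
#' addressable by the evaluation drivers and the CLI. Built-ins are
#' `two_step`, `quantile` and `lowess`. Registering an external method that
#' reads a pre-normalized matrix from file is the intended route for tools
#' not reimplemented here (e.g. VSN).
#'
#' @param name unique method name.
#' @param fn callable honouring the `matrix -> matrix` contract.
#' @return `name`, invisibly.
#' @export
register_normalizer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (name %in% names(.registries$normalizers)) {
    stop("a normalizer named '", name, "' is already registered", call. = FALSE)
  }
  .registries$normalizers[[name]] <- fn
  invisible(name)
}

#' @rdname register_normalizer
#' @export
list_normalizers <- function() sort(names(.registries$normalizers))

#' Register a differential-expression method by name
#'
#' Adds a `function(control, experimental, restrictions) -> DE result`
#' under a unique name. Built-ins are `associative` and `ttest_bh`. A
#' two-column (gene_id, selected) file from an external tool such as SAM or
#' Limma can be wrapped into a conforming callable and registered here.
#'
#' @param name unique method name.
#' @param fn callable honouring the DE contract.
#' @return `name`, invisibly.
#' @export
register_de_method <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (name %in% names(.registries$de_methods)) {
    stop("a DE method named '", name, "' is already registered", call. = FALSE)
  }
  .registries$de_methods[[name]] <- fn
  invisible(name)
}

#' @rdname register_de_method
#' @export
list_de_methods <- function() sort(names(.registries$de_methods))

get_normalizer <- function(name) {
  if (is.function(name)) return(name)
  fn <- .registries$normalizers[[name]]
  if (is.null(fn)) {
    stop("unknown normalizer '", name, "'; registered: ",
         paste(list_normalizers(), collapse = ", "), call. = FALSE)
  }
  fn
}

get_de_method <- function(name) {
  if (is.function(name)) return(name)
  fn <- .registries$de_methods[[name]]
  if (is.null(fn)) {
    stop("unknown DE method '", name, "'; registered: ",
         paste(list_de_methods(), collapse = ", "), call. = FALSE)
  }
  fn
}

# test hook: drop any extra registrations, keep built-ins
reset_registries <- function() {
  .registries$normalizers <- list()
  .registries$de_methods <- list()
  register_builtin_methods()
  invisible(NULL)
}
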