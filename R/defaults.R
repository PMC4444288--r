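# Fixed-parameter defaults table.
#
# The non-adjustable constants of the model (organ plasma flows, distribution
# volumes, free-antibody degradation, delay return, metabolite submodel rates)
# live in a versioned JSON config in inst/extdata with a source note per
# value. They are explicit stand-ins for reference tables that are external
# to this package, and every value can be overridden.

.pkg_env <- new.env(parent = emptyenv())

.load_fixed_table <- function() {
  if (is.null(.pkg_env$fixed_table)) {
    path <- system.file("extdata", "fixed_params.json", package = "cd66pbpk")
    if (!nzchar(path)) stop("fixed_params.json not found in package")
    .pkg_env$fixed_table <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  .pkg_env$fixed_table
}

#' Fixed physiological and kinetic constants
#'
#' Returns the versioned defaults table of all non-adjustable model constants
#' as a named list of values. See
#' `system.file("extdata", "fixed_params.json", package = "cd66pbpk")` for
#' units and source notes.
#'
#' @param overrides named list of values replacing individual defaults.
#' @return Named list of numeric constants with attribute `"version"`.
#' @export
fixed_defaults <- function(overrides = list()) {
  tab <- .load_fixed_table()
  vals <- lapply(tab$parameters, function(p) p$value)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(vals))
    if (length(unknown))
      stop("unknown fixed parameter(s): ", paste(unknown, collapse = ", "))
    vals[names(overrides)] <- overrides
  }
  vals <- lapply(vals, as.numeric)
  bad <- names(vals)[!vapply(vals, function(v) is.finite(v) && v >= 0,
                             logical(1))]
  if (length(bad))
    stop("fixed parameters must be finite and non-negative: ",
         paste(bad, collapse = ", "))
  attr(vals, "version") <- tab$version
  vals
}
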