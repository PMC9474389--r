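#' Read and write model-parameter files
#'
#' Model files are JSON objects with fields `family` (one of `"coxian"`,
#' `"ph_dec"`, `"ph_inc"`, `"exponential"`, `"weibull"`, `"crbd"`) and
#' `params` (named family parameters). `write_model` accepts a [wt_model],
#' a [coxian_ph] (stored as a general Coxian), or a [fit_model] result;
#' `read_model` round-trips them.
#'
#' @param model The object to serialise.
#' @param path File path.
#' @param provenance Optional named list (e.g. command line and seed) stored
#'   under a `provenance` field.
#' @return `read_model` returns a list with `family` and `params` (and, for
#'   fit files, the stored fit fields); `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path, provenance = NULL) {
  obj <- if (inherits(model, "coxian_ph")) {
    list(family = "coxian",
         params = list(lambdas = -diag(model$Q), ps = ph_continuation(model)))
  } else if (inherits(model, "wt_model")) {
    list(family = model$family, params = model$params)
  } else if (inherits(model, "ph_fit")) {
    list(family = model$family, params = model$params,
         n_phases = model$n_phases, logL = model$logL, npar = model$npar,
         aic = model$aic, n_trees = model$n_trees, k = model$k,
         ell = model$ell, tip_counts = model$tip_counts,
         sum_lfact = model$sum_lfact, perm_included = model$perm_included)
  } else stop("cannot serialise objects of class ", class(model)[1L])
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$family)) stop("model file lacks a 'family' field")
  obj
}

# rebuild a ph_fit (enough of one for gof/hazard/compare) from a fit JSON
fit_from_json <- function(path) {
  obj <- read_model(path)
  if (is.null(obj$logL)) stop("'", path, "' is not a fit file (no logL field)")
  nat <- as.list(obj$params)
  n_phases <- obj$n_phases %||% NA_integer_
  structure(
    list(family = obj$family, n_phases = n_phases, params = nat,
         dist = natural_to_dist(nat, obj$family),
         logL = obj$logL, npar = obj$npar, aic = obj$aic,
         perm_included = isTRUE(obj$perm_included),
         boundary = logical(0), convergence = NA_integer_,
         n_trees = obj$n_trees, k = obj$k, ell = obj$ell,
         tip_counts = as.integer(obj$tip_counts),
         sum_lfact = obj$sum_lfact, n_starts = NA_integer_, starts = NULL),
    class = "ph_fit"
  )
}
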