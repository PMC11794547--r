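#' @import methods
#' @importFrom stats approx coef cor lm median na.omit predict quantile
#'   rnorm runif sd setNames var plogis
#' @importFrom utils head read.csv write.csv
NULL

#' SpectralSet: sample-by-wavelength reflectance with metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `reflectance` assay (wavelengths as rows, samples as columns), the
#' wavelength grid in `rowData()$wavelength`, per-sample metadata (sample_id,
#' plot_id, stage, treatment) and optional trait columns in `colData()`.
#' A logical flag in `metadata()$derivative` marks derivative-transformed
#' spectra, for which the \[0, 1\] reflectance bound is not enforced.
#'
#' @slot derivative scalar logical, `TRUE` after derivative preprocessing.
#' @seealso [SpectralSet()], [spectra()], [wavelengths()]
#' @export
setClass("SpectralSet",
  contains = "SummarizedExperiment",
  representation(derivative = "logical"),
  prototype(derivative = FALSE)
)

setValidity("SpectralSet", function(object) {
  msg <- NULL
  wl <- SummarizedExperiment::rowData(object)$wavelength
  if (is.null(wl)) {
    msg <- c(msg, "rowData() must carry a 'wavelength' column")
  } else {
    if (anyDuplicated(wl)) msg <- c(msg, "duplicate wavelengths")
    if (is.unsorted(wl, strictly = TRUE)) {
      msg <- c(msg, "wavelength grid must be strictly increasing")
    }
  }
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'reflectance' is required")
  } else if (!isTRUE(object@derivative)) {
    a <- SummarizedExperiment::assay(object, "reflectance")
    if (length(a) && (min(a) < -1e-9 || max(a) > 1 + 1e-9)) {
      msg <- c(msg, "non-derivative reflectance must lie in [0, 1]")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' CorrelationMaps: synchronous and asynchronous 2D correlation maps
#'
#' Holds the synchronous map \eqn{\Phi(\nu_1,\nu_2)} (symmetric; positive
#' semidefinite for perturbation 2DCOS) and the asynchronous map
#' \eqn{\Psi(\nu_1,\nu_2)} (antisymmetric, zero diagonal) on a common
#' wavelength grid.
#'
#' @slot wavelengths numeric wavelength grid (nm).
#' @slot sync,async numeric matrices.
#' @slot kind `"perturbation_2dcos"` or `"two_trace"`.
#' @export
setClass("CorrelationMaps",
  representation(wavelengths = "numeric", sync = "matrix",
                 async = "matrix", kind = "character")
)

setValidity("CorrelationMaps", function(object) {
  msg <- NULL
  n <- length(object@wavelengths)
  if (!all(dim(object@sync) == n) || !all(dim(object@async) == n)) {
    msg <- c(msg, "map dimensions must match the wavelength grid")
  }
  if (max(abs(object@sync - t(object@sync))) > 1e-10 * max(1, max(abs(object@sync)))) {
    msg <- c(msg, "sync map must be symmetric")
  }
  if (max(abs(object@async + t(object@async))) > 1e-10 * max(1, max(abs(object@async)))) {
    msg <- c(msg, "async map must be antisymmetric")
  }
  if (!object@kind %in% c("perturbation_2dcos", "two_trace")) {
    msg <- c(msg, "kind must be 'perturbation_2dcos' or 'two_trace'")
  }
  if (is.null(msg)) TRUE else msg
})

#' BandSet: selected sensitive wavelengths with provenance
#'
#' @slot wavelengths numeric, selected wavelengths (nm).
#' @slot support integer, how many draws / paired samples selected each band.
#' @slot provenance list with the selection method and its parameters.
#' @export
setClass("BandSet",
  representation(wavelengths = "numeric", support = "integer",
                 provenance = "list")
)

setValidity("BandSet", function(object) {
  msg <- NULL
  if (length(object@support) != length(object@wavelengths)) {
    msg <- c(msg, "support and wavelengths lengths differ")
  }
  if (length(object@support) && any(object@support < 1L)) {
    msg <- c(msg, "support must be >= 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' SimulatedLUT: forward-simulated reflectance pool with responses
#'
#' Rows are parameter draws; `reflectance` holds the (optionally band-masked)
#' simulated canopy spectra and `response` the leaf biomass in t/ha computed
#' as `100 * LAI * Cm` (g/cm2 x m2/m2 to t/ha).
#'
#' @slot params data.frame of parameter draws.
#' @slot wavelengths numeric wavelength grid of the reflectance columns.
#' @slot reflectance numeric matrix, draws x wavelengths.
#' @slot response numeric vector, leaf biomass t/ha.
#' @slot manifest list (seed, sampler, ranges) for provenance.
#' @export
setClass("SimulatedLUT",
  representation(params = "data.frame", wavelengths = "numeric",
                 reflectance = "matrix", response = "numeric",
                 manifest = "list")
)

setValidity("SimulatedLUT", function(object) {
  msg <- NULL
  if (nrow(object@reflectance) != nrow(object@params) ||
      nrow(object@reflectance) != length(object@response)) {
    msg <- c(msg, "params, reflectance and response row counts differ")
  }
  if (ncol(object@reflectance) != length(object@wavelengths)) {
    msg <- c(msg, "reflectance columns must match the wavelength grid")
  }
  if (length(object@response) && min(object@response) < 0) {
    msg <- c(msg, "response (biomass) must be non-negative")
  }
  if (all(c("LAI", "Cm") %in% names(object@params)) &&
      length(object@response) &&
      max(abs(object@response - 100 * object@params$LAI * object@params$Cm)) > 1e-9) {
    msg <- c(msg, "response must equal 100 * LAI * Cm within 1e-9")
  }
  if (is.null(msg)) TRUE else msg
})

#' OptResult: outcome of a population metaheuristic run
#'
#' @slot best_x numeric parameter vector at the best objective value.
#' @slot best_f scalar best objective value.
#' @slot history numeric, best-so-far objective per iteration (non-increasing).
#' @slot archive data.frame of all evaluated points (empty unless requested).
#' @export
setClass("OptResult",
  representation(best_x = "numeric", best_f = "numeric",
                 history = "numeric", archive = "data.frame")
)

setValidity("OptResult", function(object) {
  msg <- NULL
  if (length(object@history) &&
      any(diff(object@history) > 1e-12)) {
    msg <- c(msg, "history must be non-increasing (best-so-far)")
  }
  if (length(object@history) &&
      abs(object@best_f - min(object@history)) > 1e-12) {
    msg <- c(msg, "best_f must equal min(history)")
  }
  if (is.null(msg)) TRUE else msg
})
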