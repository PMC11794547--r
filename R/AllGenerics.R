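#' @rdname SpectralSet-class
#' @param object,x A `SpectralSet`.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectralSet-class
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname SpectralSet-class
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname SpectralSet-class
#' @export
setGeneric("isDerivative", function(x) standardGeneric("isDerivative"))

#' @describeIn SpectralSet-class wavelength grid (nm)
#' @export
setMethod("wavelengths", "SpectralSet", function(x) {
  SummarizedExperiment::rowData(x)$wavelength
})

#' @describeIn SpectralSet-class sample x wavelength reflectance matrix
#' @export
setMethod("spectra", "SpectralSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "reflectance"))
  colnames(m) <- as.character(wavelengths(x))
  rownames(m) <- colnames(x)
  m
})

#' @describeIn SpectralSet-class per-sample metadata and traits (data.frame)
#' @export
setMethod("sampleMeta", "SpectralSet", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @describeIn SpectralSet-class TRUE for derivative-transformed spectra
#' @export
setMethod("isDerivative", "SpectralSet", function(x) x@derivative)

setMethod("show", "SpectralSet", function(object) {
  wl <- wavelengths(object)
  cat("SpectralSet:", ncol(object), "samples x", nrow(object), "bands",
      sprintf("(%g-%g nm)", min(wl), max(wl)),
      if (isDerivative(object)) "[derivative]" else "", "\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  meta/trait columns:", paste(colnames(cd), collapse = ", "), "\n")
  if ("stage" %in% colnames(cd)) {
    cat("  stages:", paste(names(table(cd$stage)), table(cd$stage),
                           sep = ":", collapse = " "), "\n")
  }
})

#' @rdname CorrelationMaps-class
#' @param x A `CorrelationMaps`.
#' @export
setGeneric("syncMap", function(x) standardGeneric("syncMap"))

#' @rdname CorrelationMaps-class
#' @export
setGeneric("asyncMap", function(x) standardGeneric("asyncMap"))

#' @describeIn CorrelationMaps-class synchronous map \eqn{\Phi}
#' @export
setMethod("syncMap", "CorrelationMaps", function(x) x@sync)

#' @describeIn CorrelationMaps-class asynchronous map \eqn{\Psi}
#' @export
setMethod("asyncMap", "CorrelationMaps", function(x) x@async)

setMethod("show", "CorrelationMaps", function(object) {
  cat("CorrelationMaps (", object@kind, "): ",
      length(object@wavelengths), " x ", length(object@wavelengths),
      " bands\n", sep = "")
  cat("  max |sync| = ", format(max(abs(object@sync)), digits = 4),
      ", max |async| = ", format(max(abs(object@async)), digits = 4),
      "\n", sep = "")
})

#' @rdname BandSet-class
#' @param x A `BandSet`.
#' @export
setGeneric("bandWavelengths", function(x) standardGeneric("bandWavelengths"))

#' @rdname BandSet-class
#' @export
setGeneric("bandSupport", function(x) standardGeneric("bandSupport"))

#' @describeIn BandSet-class selected wavelengths (nm)
#' @export
setMethod("bandWavelengths", "BandSet", function(x) x@wavelengths)

#' @describeIn BandSet-class per-band selection support
#' @export
setMethod("bandSupport", "BandSet", function(x) x@support)

setMethod("show", "BandSet", function(object) {
  cat("BandSet:", length(object@wavelengths), "bands",
      if (!is.null(object@provenance$method)) {
        paste0("[", object@provenance$method, "]")
      } else "", "\n")
  if (length(object@wavelengths)) {
    cat("  nm:", paste(utils::head(object@wavelengths, 20), collapse = ", "),
        if (length(object@wavelengths) > 20) "..." else "", "\n")
  }
})

#' @rdname SimulatedLUT-class
#' @param x A `SimulatedLUT`.
#' @export
setGeneric("lutParams", function(x) standardGeneric("lutParams"))

#' @rdname SimulatedLUT-class
#' @export
setGeneric("lutReflectance", function(x) standardGeneric("lutReflectance"))

#' @rdname SimulatedLUT-class
#' @export
setGeneric("lutResponse", function(x) standardGeneric("lutResponse"))

#' @describeIn SimulatedLUT-class parameter draws
#' @export
setMethod("lutParams", "SimulatedLUT", function(x) x@params)

#' @describeIn SimulatedLUT-class simulated reflectance matrix
#' @export
setMethod("lutReflectance", "SimulatedLUT", function(x) x@reflectance)

#' @describeIn SimulatedLUT-class leaf biomass responses (t/ha)
#' @export
setMethod("lutResponse", "SimulatedLUT", function(x) x@response)

setMethod("show", "SimulatedLUT", function(object) {
  cat("SimulatedLUT:", nrow(object@reflectance), "draws x",
      ncol(object@reflectance), "bands\n")
  cat("  leaf biomass t/ha: ",
      paste(format(range(object@response), digits = 3), collapse = " - "),
      "\n", sep = "")
})

setMethod("show", "OptResult", function(object) {
  cat("OptResult: best_f =", format(object@best_f, digits = 6),
      "after", length(object@history), "iterations\n")
})
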