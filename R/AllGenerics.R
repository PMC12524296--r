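#' @rdname Hypercube-class
#' @param x object
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectralDataset-class
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname SpectralDataset-class
#' @export
setGeneric("tga", function(x) standardGeneric("tga"))

#' @rdname SpectralDataset-class
#' @export
setGeneric("dayGroup", function(x) standardGeneric("dayGroup"))

#' @rdname SpectralDataset-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))
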