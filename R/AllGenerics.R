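#' @rdname intensityMatrix
#' @export
setGeneric("intensityMatrix", function(x, ...) standardGeneric("intensityMatrix"))

#' @rdname describeTruth
#' @export
setGeneric("describeTruth", function(truth, ...) standardGeneric("describeTruth"))

#' @rdname attributeModel
#' @export
setGeneric("attributeModel", function(model, background, samples, ...)
    standardGeneric("attributeModel"))
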