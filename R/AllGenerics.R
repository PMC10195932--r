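#' @rdname defaultRegistry
#' @param x Object with a feature dimension.
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname patientImage
#' @export
setGeneric("patientImage",
           function(x, patient) standardGeneric("patientImage"))

#' @rdname blurImages
#' @export
setGeneric("blurImages",
           function(x, half_window = 10L, decay = 10)
             standardGeneric("blurImages"))
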