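#' @rdname accessors
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))

#' @rdname accessors
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname accessors
#' @export
setGeneric("modalityCalls", function(x) standardGeneric("modalityCalls"))

#' @rdname accessors
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @rdname accessors
#' @export
setGeneric("trueModality", function(x) standardGeneric("trueModality"))

#' @rdname accessors
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("noiseMask", function(x) standardGeneric("noiseMask"))
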