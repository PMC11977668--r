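#' Count the parameters of a network spec or assembled model
#'
#' For a \code{MILNetworkSpec} the count stored at build time is returned;
#' for a \code{MILModel} every weight and bias array is measured, so the two
#' routes cross-check each other.
#'
#' @param object a \code{MILNetworkSpec} or \code{MILModel}.
#' @return integer-valued numeric scalar.
#' @examples
#' countParameters(buildSubnet1())  # 245792
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "MILNetworkSpec", function(object) as.integer(object@nParams))

#' @rdname countParameters
#' @export
setMethod("countParameters", "MILModel", function(object) {
  as.integer(sum(rapply(object@weights, length, how = "unlist")))
})

#' Accessors for MILBag
#'
#' \code{bagPatches} returns the pixel data as a double array in [0, 1];
#' \code{bagLength} the instance count; \code{bagLabel}, \code{bagPatientId}
#' and \code{bagGridShape} the remaining slots.
#'
#' @param x a \code{MILBag}.
#' @return see individual descriptions.
#' @export
setGeneric("bagPatches", function(x) standardGeneric("bagPatches"))

#' @rdname bagPatches
#' @export
setMethod("bagPatches", "MILBag", function(x) {
  d <- dim(x@patches)
  array(as.integer(x@patches) / 255, dim = d)
})

#' @rdname bagPatches
#' @export
setGeneric("bagLength", function(x) standardGeneric("bagLength"))

#' @rdname bagPatches
#' @export
setMethod("bagLength", "MILBag", function(x) dim(x@patches)[4])

#' @rdname bagPatches
#' @export
setGeneric("bagLabel", function(x) standardGeneric("bagLabel"))

#' @rdname bagPatches
#' @export
setMethod("bagLabel", "MILBag", function(x) x@label)

#' @rdname bagPatches
#' @export
setGeneric("bagPatientId", function(x) standardGeneric("bagPatientId"))

#' @rdname bagPatches
#' @export
setMethod("bagPatientId", "MILBag", function(x) x@patientId)

#' @rdname bagPatches
#' @export
setGeneric("bagGridShape", function(x) standardGeneric("bagGridShape"))

#' @rdname bagPatches
#' @export
setMethod("bagGridShape", "MILBag", function(x) x@gridShape)
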