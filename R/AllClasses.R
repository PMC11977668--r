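#' @import methods
#' @importFrom stats runif rnorm
#' @importFrom utils head read.csv write.csv tail
#' @useDynLib SparseMIL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Layer-list description of a network component
#'
#' A \code{MILNetworkSpec} records the ordered layer list of one network
#' component (the convolutional instance encoder, the dense scoring head, the
#' attention module, or a reference backbone) together with its input/output
#' contract and its exact parameter count. The count is computed from the
#' layer list alone, so architectures can be audited without instantiating
#' weights.
#'
#' @slot name single string identifying the component.
#' @slot layers list of layer descriptors as produced by the builders; each is
#'   a list with a \code{kind} field (\code{conv2d}, \code{maxpool2d},
#'   \code{global_avg_pool}, \code{dense}, \code{dropout}) plus
#'   kind-specific fields.
#' @slot inputDim integer vector describing the expected input (for the
#'   encoder: \code{c(NA, NA, 3)}, any spatial size with 3 channels; for dense
#'   stacks: the input length).
#' @slot outputDim integer output length.
#' @slot nParams numeric scalar, total number of trainable scalars (plus,
#'   where stated by the builder, non-trainable moving statistics).
#'
#' @seealso [buildSubnet1()], [buildSubnet2()], [buildAttentionModule()],
#'   [buildResNet50Spec()]
#' @export
setClass("MILNetworkSpec",
  representation(name = "character", layers = "list",
                 inputDim = "integer", outputDim = "integer",
                 nParams = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    if (object@nParams < 0) return("nParams must be nonnegative")
    TRUE
  })

#' A bag of image patches with its image-level label
#'
#' One microscopy image decomposed into L equal-sized, non-overlapping square
#' patches (the MIL instances). Pixels are stored as raw bytes (0--255) to
#' keep large bag collections memory-light; [bagPatches()] returns them as a
#' double array scaled to [0, 1].
#'
#' @slot patches raw array of dimension (ps, ps, 3, L).
#' @slot label integer, 0 = normal, 1 = abnormal, or NA when unknown.
#' @slot patientId single string.
#' @slot gridShape integer (rows, cols) of the patch grid; L = rows * cols,
#'   patches are ordered row-major from the top-left.
#' @export
setClass("MILBag",
  representation(patches = "array", label = "integer",
                 patientId = "character", gridShape = "integer"),
  validity = function(object) {
    d <- dim(object@patches)
    if (length(d) != 4L) return("patches must be a 4-d array (ps, ps, 3, L)")
    if (typeof(object@patches) != "raw") return("patches must be raw bytes")
    if (d[3] != 3L) return("patches must have 3 colour channels")
    if (d[1] != d[2]) return("patches must be square")
    if (d[4] < 1L) return("a bag needs at least one instance")
    if (length(object@gridShape) != 2L ||
        prod(object@gridShape) != d[4])
      return("gridShape must multiply to the instance count")
    TRUE
  })

#' An assembled MIL model
#'
#' Holds the variant identity (EMIL/IMIL x max/softmax/sparsemax pooling),
#' the patch side it expects, the regularizer configuration and all weight
#' arrays. Weights are plain R arrays grouped by component (\code{s1} encoder,
#' \code{s2} scoring head, \code{att} attention module when present).
#'
#' @slot variant one of \code{"EMIL_A"}, \code{"EMIL_M"}, \code{"IMIL_A"},
#'   \code{"IMIL_M"}, \code{"IMIL_SA"}.
#' @slot milMode \code{"embedding"} or \code{"instance"}.
#' @slot aggregator \code{"max"}, \code{"softmax_attention"} or
#'   \code{"sparsemax_attention"}.
#' @slot patchSide integer patch side in pixels.
#' @slot reg list with \code{lambdaL0}, \code{lambdaMer}, \code{merSign},
#'   \code{smoothL0}, \code{l0Sigma}.
#' @slot attentionSigmoid logical; pass attention logits through a sigmoid
#'   before the probability transform (the published design) or use them raw.
#' @slot weights list of weight arrays.
#' @export
setClass("MILModel",
  representation(variant = "character", milMode = "character",
                 aggregator = "character", patchSide = "integer",
                 reg = "list", attentionSigmoid = "logical",
                 weights = "list"),
  validity = function(object) {
    if (!object@variant %in% milVariants()) return("unknown variant")
    if (object@patchSide < 32L) return("patchSide must be at least 32")
    if (object@reg$lambdaL0 < 0) return("lambdaL0 must be nonnegative")
    TRUE
  })

#' Result of the sparsemax transform
#'
#' The Euclidean projection of a real vector onto the probability simplex,
#' together with the threshold subtracted from the retained coordinates and
#' the support size (number of nonzero probabilities).
#'
#' @slot probabilities numeric probability vector (exact zeros allowed).
#' @slot threshold numeric scalar subtracted from every retained coordinate.
#' @slot supportSize integer count of nonzero probabilities.
#' @export
setClass("SparsemaxResult",
  representation(probabilities = "numeric", threshold = "numeric",
                 supportSize = "integer"),
  validity = function(object) {
    if (abs(sum(object@probabilities) - 1) > 1e-9)
      return("probabilities must sum to 1")
    if (any(object@probabilities < 0)) return("probabilities must be nonnegative")
    if (object@supportSize != sum(object@probabilities > 0))
      return("supportSize must equal the number of nonzero probabilities")
    TRUE
  })

#' @describeIn MILNetworkSpec compact layer table
#' @param object a \code{MILNetworkSpec}
#' @export
setMethod("show", "MILNetworkSpec", function(object) {
  cat(sprintf("%s: %d layers, %s parameters\n", object@name,
              length(object@layers), format(object@nParams, big.mark = ",")))
  for (ly in object@layers) {
    extra <- switch(ly$kind,
      conv2d = sprintf("%d filters %dx%d %s", ly$filters, ly$window[1],
                       ly$window[2], ly$activation),
      maxpool2d = sprintf("%dx%d", ly$window[1], ly$window[2]),
      dense = sprintf("%d units %s", ly$units, ly$activation),
      dropout = sprintf("rate %.2f", ly$rate),
      "")
    cat(sprintf("  %-16s %s\n", ly$kind, extra))
  }
})

#' @describeIn MILBag one-line summary
#' @param object a \code{MILBag}
#' @export
setMethod("show", "MILBag", function(object) {
  d <- dim(object@patches)
  cat(sprintf("MILBag: %d instances of %dx%d px (grid %dx%d), label %s, patient %s\n",
              d[4], d[1], d[2], object@gridShape[1], object@gridShape[2],
              ifelse(is.na(object@label), "NA", object@label),
              object@patientId))
})

#' @describeIn MILModel one-line summary
#' @param object a \code{MILModel}
#' @export
setMethod("show", "MILModel", function(object) {
  cat(sprintf("MILModel %s: %s MIL, %s pooling, patch side %d, %s parameters\n",
              object@variant, object@milMode, object@aggregator,
              object@patchSide,
              format(countParameters(object), big.mark = ",")))
  if (object@reg$lambdaL0 > 0 || object@reg$lambdaMer != 0)
    cat(sprintf("  regularizers: lambdaL0 %g, lambdaMer %g (sign %+d)\n",
                object@reg$lambdaL0, object@reg$lambdaMer,
                object@reg$merSign))
})

#' @describeIn SparsemaxResult print probabilities with support
#' @param object a \code{SparsemaxResult}
#' @export
setMethod("show", "SparsemaxResult", function(object) {
  cat(sprintf("sparsemax: support %d of %d, threshold %.6g\n",
              object@supportSize, length(object@probabilities),
              object@threshold))
})

#' The five supported model variants
#' @return character vector of variant names.
#' @export
milVariants <- function() c("EMIL_A", "EMIL_M", "IMIL_A", "IMIL_M", "IMIL_SA")
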