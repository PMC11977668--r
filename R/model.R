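# Model assembly, the bag-level forward pass, and checkpoint I/O.
# The encoder weights are shared across instances; a bag of L patches is
# processed as a batch of L feature maps.

.glorot <- function(dims, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# He-uniform for the ReLU convolutions: keeps activation variance roughly
# constant through the five conv stages, where Glorot would shrink the
# embeddings by an order of magnitude and stall early training.
.heUniform <- function(dims, fanIn) {
  lim <- sqrt(6 / fanIn)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

.initSubnet1Weights <- function() {
  specs <- list(c(5L, 5L, 3L, 16L), c(3L, 3L, 16L, 32L), c(3L, 3L, 32L, 64L),
                c(3L, 3L, 64L, 128L), c(3L, 3L, 128L, 128L))
  W <- lapply(specs, function(d) .heUniform(d, prod(d[1:3])))
  b <- lapply(specs, function(d) numeric(d[4]))
  list(W = W, b = b)
}

.initDensePair <- function() {
  list(W1 = .glorot(c(128L, 256L), 128, 256), b1 = numeric(256),
       W2 = .glorot(c(256L, 1L), 256, 1), b2 = numeric(1))
}

#' Assemble a MIL model
#'
#' Builds one of the five variants. Embedding-based variants (EMIL) aggregate
#' the 128-d instance embeddings and score the aggregate once; instance-based
#' variants (IMIL) score every instance and aggregate the scores. The "_A"
#' variants pool with softmax attention, "_M" with max-pooling, and IMIL_SA
#' with sparsemax attention (identical topology and parameter count to
#' IMIL_A, only the probability transform differs). Weights are drawn from
#' the current R random-number state (He-uniform convolutions,
#' Glorot-uniform dense layers; the attention module starts as a copy of
#' the scoring head so the initial attention follows the initial score
#' ranking); call \code{set.seed()} first for reproducible initialization.
#'
#' @param variant one of \code{milVariants()}.
#' @param patchSide patch side in pixels (>= 32); the canonical sides for a
#'   3096 px field of view are 86, 129, 172, 258 and 344.
#' @param lambdaL0 weight of the L0 penalty on the attention distribution.
#' @param lambdaMer weight of the entropy penalty.
#' @param merSign +1 (penalty exactly as printed) or -1 (entropy-minimizing).
#' @param smoothL0 use the differentiable L0 surrogate in training.
#' @param l0Sigma width of the smooth surrogate.
#' @param attentionSigmoid pass attention logits through a sigmoid before the
#'   probability transform (default, the published design).
#' @return a [MILModel-class].
#' @examples
#' set.seed(1)
#' m <- assembleModel("IMIL_SA", patchSide = 86, lambdaL0 = 0.005,
#'                    lambdaMer = 0.005)
#' countParameters(m)  # 312354
#' @export
assembleModel <- function(variant, patchSide,
                          lambdaL0 = 0, lambdaMer = 0, merSign = 1,
                          smoothL0 = FALSE, l0Sigma = 0.01,
                          attentionSigmoid = TRUE) {
  variant <- match.arg(variant, milVariants())
  patchSide <- as.integer(patchSide)
  if (patchSide < 32L)
    stop("patchSide must be at least 32", call. = FALSE)
  .subnet1SpatialTrace(patchSide)
  milMode <- if (startsWith(variant, "EMIL")) "embedding" else "instance"
  aggregator <- switch(variant,
    EMIL_M = , IMIL_M = "max",
    EMIL_A = , IMIL_A = "softmax_attention",
    IMIL_SA = "sparsemax_attention")
  weights <- list(s1 = .initSubnet1Weights(), s2 = .initDensePair())
  if (aggregator != "max") {
    # The attention module is initialized as a copy of the scoring head,
    # so the initial attention ranks instances exactly the way the initial
    # scores do. This makes the attention-score feedback loop ignite in the
    # direction the data indicates for every seed: in positive bags the
    # attended (high-scoring) instances are pushed further up, and only the
    # truly positive instances receive that push consistently. With an
    # independent random attention head the sign of the initial preference
    # is arbitrary, and when it starts anti-aligned sparse attention can
    # permanently evict the truly positive instances (zero attention means
    # zero gradient) before the scorer has learned to rank them. The two
    # modules share only their starting point and train independently.
    weights$att <- list(W1 = weights$s2$W1, b1 = weights$s2$b1,
                        W2 = weights$s2$W2, b2 = numeric(1))
  }
  new("MILModel", variant = variant, milMode = milMode,
      aggregator = aggregator, patchSide = patchSide,
      reg = list(lambdaL0 = lambdaL0, lambdaMer = lambdaMer,
                 merSign = merSign, smoothL0 = smoothL0, l0Sigma = l0Sigma),
      attentionSigmoid = attentionSigmoid, weights = weights)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Encoder forward over a bag: x is (ps, ps, 3, L) in [0, 1]. Returns the
# L x 128 embedding matrix, plus (when training) an external pointer to the
# activation caches the backward pass needs.
.subnet1Forward <- function(x, w, cache = FALSE) {
  res <- cppEncoderForward(x, w$W, w$b, cache)
  list(E = res$E, cache = res$cache, finalSide = res$finalSide)
}

# Encoder backward for the active instances. dE is nAct x 128; active is the
# index vector of instances with a nonzero upstream gradient. Consumes the
# cache. Returns conv weight/bias gradients.
.subnet1Backward <- function(cache, w, dE, active) {
  cppEncoderBackward(cache, w$W, w$b, dE, as.integer(active))
}

# Dense scoring head forward (works on an L x 128 matrix or a single row).
# Dropout masks (inverted scaling) are supplied at training time.
.subnet2Forward <- function(E, w, masks = NULL) {
  X1 <- if (is.null(masks)) E else E * masks$D1
  Z1 <- sweep(X1 %*% w$W1, 2L, w$b1, "+")
  A1 <- pmax(Z1, 0)
  X2 <- if (is.null(masks)) A1 else A1 * masks$D2
  Z2 <- sweep(X2 %*% w$W2, 2L, w$b2, "+")
  s <- .sigmoid(Z2)
  list(s = as.vector(s), X1 = X1, Z1 = Z1, X2 = X2, sMat = s)
}

# Backward through the scoring head. ds: vector of dLoss/ds per row.
# Returns weight gradients and dE (same shape as E).
.subnet2Backward <- function(fw, E, w, ds, masks = NULL) {
  dZ2 <- matrix(ds * fw$s * (1 - fw$s), ncol = 1L)
  dW2 <- crossprod(fw$X2, dZ2)
  db2 <- sum(dZ2)
  dX2 <- dZ2 %*% t(w$W2)
  dA1 <- if (is.null(masks)) dX2 else dX2 * masks$D2
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$X1, dZ1)
  db1 <- colSums(dZ1)
  dX1 <- dZ1 %*% t(w$W1)
  dE <- if (is.null(masks)) dX1 else dX1 * masks$D1
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, dE = dE)
}

# Attention module forward: per-instance logit e in (0,1) (or raw when the
# sigmoid is bypassed), then softmax or sparsemax across instances.
.attentionForward <- function(E, w, aggregator, useSigmoid) {
  Tn <- tanh(sweep(E %*% w$W1, 2L, w$b1, "+"))
  eRaw <- as.vector(sweep(Tn %*% w$W2, 2L, w$b2, "+"))
  e <- if (useSigmoid) .sigmoid(eRaw) else eRaw
  if (aggregator == "softmax_attention") {
    a <- softmaxTransform(e)
    sm <- NULL
  } else {
    sm <- sparsemaxTransform(e)
    a <- sm@probabilities
  }
  list(a = a, e = e, eRaw = eRaw, Tn = Tn, sparsemax = sm)
}

# Backward through the probability transform, the logit sigmoid and the
# attention module. da: dLoss/da. Returns module gradients and dE.
.attentionBackward <- function(fw, E, w, da, aggregator, useSigmoid) {
  a <- fw$a
  if (aggregator == "softmax_attention") {
    de <- a * (da - sum(a * da))
  } else {
    supp <- a > 0
    de <- numeric(length(a))
    de[supp] <- da[supp] - mean(da[supp])
  }
  deRaw <- if (useSigmoid) de * fw$e * (1 - fw$e) else de
  dZ2 <- matrix(deRaw, ncol = 1L)
  dW2 <- crossprod(fw$Tn, dZ2)
  db2 <- sum(dZ2)
  dTn <- dZ2 %*% t(w$W2)
  dZt <- dTn * (1 - fw$Tn^2)
  dW1 <- crossprod(E, dZt)
  db1 <- colSums(dZt)
  dE <- dZt %*% t(w$W1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, dE = dE)
}

# Full forward pass. Returns the public BagForwardResult fields plus, when
# train = TRUE, the caches needed for backpropagation.
.forwardCore <- function(model, x, train = FALSE, masks = NULL) {
  w <- model@weights
  L <- dim(x)[4]
  s1 <- .subnet1Forward(x, w$s1, cache = train)
  E <- s1$E
  att <- NULL
  a <- NULL
  if (model@aggregator != "max") {
    att <- .attentionForward(E, w$att, model@aggregator,
                             model@attentionSigmoid)
    a <- att$a
  }
  if (model@milMode == "embedding") {
    g <- switch(model@aggregator,
      max = maxPoolEmbeddings(E),
      attentionAggregateEmbeddings(E, a))
    s2 <- .subnet2Forward(matrix(g, nrow = 1L), w$s2, masks)
    bagProb <- s2$s
    instanceScores <- NULL
  } else {
    s2 <- .subnet2Forward(E, w$s2, masks)
    instanceScores <- s2$s
    bagProb <- switch(model@aggregator,
      max = maxPoolPredictions(instanceScores),
      attentionAggregatePredictions(instanceScores, a))
  }
  list(bagProbability = bagProb, instanceScores = instanceScores,
       attention = a, embeddings = E,
       cache = if (train) list(s1 = s1, s2 = s2, att = att, x = x))
}

#' Run a bag through a model
#'
#' Computes the bag-level abnormality probability. Attention variants also
#' return the attention distribution over instances (sums to 1; sparsemax may
#' contain exact zeros); instance-based variants return the per-instance
#' scores. Inference is deterministic: dropout acts only during training.
#'
#' @param model a [MILModel-class].
#' @param bag a [MILBag-class] whose patch side matches the model.
#' @return a list with \code{bagProbability}, \code{instanceScores} (IMIL
#'   variants, else NULL), \code{attention} (attention variants, else NULL)
#'   and the L x 128 \code{embeddings} matrix.
#' @export
setGeneric("forwardBag", function(model, bag) standardGeneric("forwardBag"))

#' @rdname forwardBag
#' @export
setMethod("forwardBag", signature("MILModel", "MILBag"), function(model, bag) {
  d <- dim(bag@patches)
  if (d[1] != model@patchSide)
    stop("bag patch side ", d[1], " does not match model patch side ",
         model@patchSide, call. = FALSE)
  res <- .forwardCore(model, bagPatches(bag), train = FALSE)
  res["cache"] <- NULL
  res
})

#' Save / load a model checkpoint
#'
#' The weight arrays are serialized with \code{saveRDS}; a JSON sidecar
#' (same path with extension \code{.json}) records the variant, patch side,
#' regularizer settings and parameter count for auditability.
#'
#' @param model a [MILModel-class].
#' @param path checkpoint file path (conventionally \code{.rds}).
#' @return \code{saveModel} the path invisibly; \code{loadModel} the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(variant = model@variant, patchSide = model@patchSide,
               reg = model@reg, attentionSigmoid = model@attentionSigmoid,
               weights = model@weights), path)
  sidecar <- paste0(sub("\\.rds$", "", path), ".json")
  jsonlite::write_json(list(variant = model@variant,
                            patch_side = model@patchSide,
                            lambda_l0 = model@reg$lambdaL0,
                            lambda_mer = model@reg$lambdaMer,
                            mer_sign = model@reg$merSign,
                            n_parameters = countParameters(model)),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  st <- readRDS(path)
  m <- assembleModel(st$variant, st$patchSide,
                     lambdaL0 = st$reg$lambdaL0, lambdaMer = st$reg$lambdaMer,
                     merSign = st$reg$merSign, smoothL0 = st$reg$smoothL0,
                     l0Sigma = st$reg$l0Sigma,
                     attentionSigmoid = st$attentionSigmoid)
  m@weights <- st$weights
  m
}
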