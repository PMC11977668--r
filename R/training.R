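# The regularized training objective, the SGD training loop with flip
# augmentation and reverse class weighting, and the learning-rate sweep.

#' Reverse class weights for imbalanced bags
#'
#' w_c = (n_neg + n_pos) / (2 * n_c): each class weight is inversely
#' proportional to its bag count, so either class contributes half of the
#' expected loss and the bag-weighted mean of the weights is 1.
#'
#' @param nNeg,nPos bag counts per class, both >= 1.
#' @return named numeric vector \code{c(neg = ..., pos = ...)}.
#' @examples
#' reverseClassWeights(214, 632)  # 1.977, 0.669
#' @export
reverseClassWeights <- function(nNeg, nPos) {
  if (nNeg < 1 || nPos < 1)
    stop("both classes must be present to weight them", call. = FALSE)
  n <- nNeg + nPos
  c(neg = n / (2 * nNeg), pos = n / (2 * nPos))
}

#' The regularized bag loss
#'
#' Class-weighted binary cross-entropy on the bag probability plus the two
#' attention penalties: \code{lossReg = lossNoReg + rL0 + rMer}. The bag
#' probability is clipped to [1e-7, 1 - 1e-7] before the logarithm. The
#' penalties are evaluated on the attention probability vector and are zero
#' when no attention is used (max-pooling variants) or the weights are zero.
#'
#' @param bagProb predicted abnormality probability.
#' @param label 0/1 bag label.
#' @param classWeight multiplier for this bag's class (see
#'   [reverseClassWeights()]).
#' @param attention attention probability vector, or NULL.
#' @param lambdaL0,lambdaMer,merSign regularizer configuration.
#' @param smoothL0,l0Sigma L0 surrogate switch, see [l0Penalty()].
#' @return list with \code{lossNoReg}, \code{rL0}, \code{rMer},
#'   \code{lossReg}.
#' @export
bagLoss <- function(bagProb, label, classWeight = 1, attention = NULL,
                    lambdaL0 = 0, lambdaMer = 0, merSign = 1,
                    smoothL0 = FALSE, l0Sigma = 0.01) {
  q <- min(max(bagProb, 1e-7), 1 - 1e-7)
  lossNoReg <- -classWeight * (label * log(q) + (1 - label) * log(1 - q))
  rL0 <- 0
  rMer <- 0
  if (!is.null(attention)) {
    rL0 <- l0Penalty(attention, lambdaL0, smooth = smoothL0, sigma = l0Sigma)
    rMer <- merPenalty(attention, lambdaMer, merSign)
  }
  list(lossNoReg = lossNoReg, rL0 = rL0, rMer = rMer,
       lossReg = lossNoReg + rL0 + rMer)
}

#' Training configuration
#'
#' Plain stochastic gradient descent, one bag per step, online horizontal
#' and vertical flip augmentation, and best-validation-AUC model selection.
#' The learning-rate grid holds the eight canonical sweep values.
#'
#' @param epochs number of passes over the training bags.
#' @param learningRate SGD step size.
#' @param lrGrid grid for [sweepLearningRates()].
#' @param momentum SGD momentum (default 0.9; set 0 for plain SGD). With
#'   one bag per step the raw gradients are small and heavily attenuated by
#'   the attention distribution; momentum lets desk-scale runs converge in
#'   tens rather than hundreds of epochs.
#' @param weightDecay optional L2 weight decay (default off).
#' @param augment random horizontal/vertical patch flips, probability 0.5
#'   each, per step.
#' @param seed integer seed governing initialization, shuffling, flips and
#'   dropout.
#' @param modelSelection \code{"val_auc"} (weights of the best validation-AUC
#'   epoch) or \code{"final"}.
#' @return list of class \code{trainConfig}.
#' @export
trainConfig <- function(epochs = 50L, learningRate = 5e-3,
                        lrGrid = c(1e-3, 5e-3, 1e-4, 5e-4, 1e-5, 5e-5,
                                   1e-6, 5e-6),
                        momentum = 0.9, weightDecay = 0, augment = TRUE,
                        seed = 1L, modelSelection = c("val_auc", "final")) {
  if (epochs < 0) stop("epochs must be >= 0", call. = FALSE)
  if (learningRate <= 0) stop("learningRate must be positive", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                 lrGrid = lrGrid, momentum = momentum,
                 weightDecay = weightDecay, augment = augment,
                 seed = as.integer(seed),
                 modelSelection = match.arg(modelSelection)),
            class = "trainConfig")
}

.dropoutMask <- function(n, d, rate = 0.5) {
  matrix((runif(n * d) >= rate) / (1 - rate), n, d)
}

# One SGD step on a single bag. x: (ps, ps, 3, L) in [0, 1]. Returns the
# loss breakdown and the gradient list (same shape as model@weights).
.trainStep <- function(model, x, label, classWeight) {
  w <- model@weights
  reg <- model@reg
  L <- dim(x)[4]
  nMaskRows <- if (model@milMode == "embedding") 1L else L
  masks <- list(D1 = .dropoutMask(nMaskRows, 128L),
                D2 = .dropoutMask(nMaskRows, 256L))
  fw <- .forwardCore(model, x, train = TRUE, masks = masks)
  lb <- bagLoss(fw$bagProbability, label, classWeight, fw$attention,
                reg$lambdaL0, reg$lambdaMer, reg$merSign,
                reg$smoothL0, reg$l0Sigma)
  q <- min(max(fw$bagProbability, 1e-7), 1 - 1e-7)
  g <- classWeight * (q - label) / (q * (1 - q))

  cache <- fw$cache
  E <- cache$s1$E
  a <- fw$attention
  grads <- list(s1 = NULL, s2 = NULL)
  dE <- matrix(0, L, 128L)

  # gradient of the penalties w.r.t. the attention probabilities
  dPen <- NULL
  if (!is.null(a)) {
    dPen <- numeric(L)
    supp <- a > 0
    dPen[supp] <- reg$merSign * reg$lambdaMer * (1 + log(a[supp]))
    if (reg$smoothL0)
      dPen <- dPen + reg$lambdaL0 *
        exp(-a^2 / reg$l0Sigma^2) * 2 * a / reg$l0Sigma^2
  }

  if (model@milMode == "instance") {
    s <- fw$instanceScores
    ds <- numeric(L)
    if (model@aggregator == "max") {
      ds[which.max(s)] <- g
    } else {
      ds <- g * a
    }
    s2b <- .subnet2Backward(cache$s2, E, w$s2, ds, masks)
    grads$s2 <- s2b[c("W1", "b1", "W2", "b2")]
    dE <- dE + s2b$dE
    if (!is.null(a)) {
      da <- g * s + dPen
      ab <- .attentionBackward(cache$att, E, w$att, da, model@aggregator,
                               model@attentionSigmoid)
      grads$att <- ab[c("W1", "b1", "W2", "b2")]
      dE <- dE + ab$dE
    }
  } else {
    if (model@aggregator == "max") {
      gvec <- maxPoolEmbeddings(E)
      s2b <- .subnet2Backward(cache$s2, matrix(gvec, 1L), w$s2, g, masks)
      grads$s2 <- s2b[c("W1", "b1", "W2", "b2")]
      dg <- as.vector(s2b$dE)
      amax <- max.col(t(E), ties.method = "first")  # argmax instance per dim
      for (dcol in seq_len(128L)) dE[amax[dcol], dcol] <-
        dE[amax[dcol], dcol] + dg[dcol]
    } else {
      gvec <- attentionAggregateEmbeddings(E, a)
      s2b <- .subnet2Backward(cache$s2, matrix(gvec, 1L), w$s2, g, masks)
      grads$s2 <- s2b[c("W1", "b1", "W2", "b2")]
      dg <- as.vector(s2b$dE)
      dE <- dE + a %o% dg
      da <- as.vector(E %*% dg) + dPen
      ab <- .attentionBackward(cache$att, E, w$att, da, model@aggregator,
                               model@attentionSigmoid)
      grads$att <- ab[c("W1", "b1", "W2", "b2")]
      dE <- dE + ab$dE
    }
  }

  active <- which(rowSums(dE != 0) > 0)
  if (length(active)) {
    grads$s1 <- .subnet1Backward(cache$s1$cache, w$s1,
                                 dE[active, , drop = FALSE], active)
  }
  list(loss = lb, grads = grads)
}

# Classic SGD with optional momentum and weight decay. The gradient list
# mirrors the weight list's nesting; missing entries (e.g. no active
# instances reached the encoder) count as zero gradient.
.sgdUpdate <- function(w, v, g, lr, momentum, weightDecay) {
  if (is.list(w)) {
    keys <- if (is.null(names(w))) seq_along(w) else names(w)
    for (k in keys) {
      r <- .sgdUpdate(w[[k]], v[[k]], if (is.null(g)) NULL else g[[k]],
                      lr, momentum, weightDecay)
      w[[k]] <- r$w
      v[[k]] <- r$v
    }
    return(list(w = w, v = v))
  }
  gk <- if (is.null(g)) 0 else g
  gk <- gk + weightDecay * w
  if (momentum > 0) {
    v <- momentum * v + gk
    list(w = w - lr * v, v = v)
  } else {
    list(w = w - lr * gk, v = v)
  }
}

.zeroLike <- function(w) rapply(w, function(a) a * 0, how = "replace")

.flipPatches <- function(x, flipH, flipV) {
  ps <- dim(x)[1]
  if (flipV) x <- x[ps:1, , , , drop = FALSE]
  if (flipH) x <- x[, ps:1, , , drop = FALSE]
  x
}

#' Train a MIL model with stochastic gradient descent
#'
#' One bag per gradient step; training bags are reshuffled every epoch; each
#' bag is independently flipped horizontally and/or vertically with
#' probability 0.5 (flips permute the patch grid, and the poolers are
#' permutation invariant, so per-patch flips are equivalent to image-level
#' flips). Reverse class weighting balances the loss across the class
#' imbalance. After each epoch the model is scored on the validation bags;
#' with the default model selection the weights of the best validation-AUC
#' epoch are returned. Fully reproducible given \code{config$seed}.
#'
#' @param model a freshly assembled or previously trained [MILModel-class].
#' @param trainBags list of labeled [MILBag-class] objects (both classes
#'   required).
#' @param valBags optional list of validation bags.
#' @param config a [trainConfig()].
#' @return list with \code{model} (selected weights), \code{steps} (one row
#'   per gradient step: epoch, step, lossNoReg, rL0, rMer, lossReg),
#'   \code{epochs} (per-epoch mean loss and validation AUC) and
#'   \code{bestEpoch}.
#' @export
trainModel <- function(model, trainBags, valBags = NULL,
                       config = trainConfig()) {
  labels <- vapply(trainBags, bagLabel, integer(1))
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  set.seed(config$seed)
  cw <- reverseClassWeights(sum(labels == 0L), sum(labels == 1L))
  n <- length(trainBags)
  stepRows <- vector("list", config$epochs * n)
  epochRows <- vector("list", config$epochs)
  best <- list(auc = -Inf, weights = model@weights, epoch = 0L)
  velocity <- .zeroLike(model@weights)
  k <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (b in ord) {
      bag <- trainBags[[b]]
      x <- bagPatches(bag)
      if (config$augment)
        x <- .flipPatches(x, runif(1) < 0.5, runif(1) < 0.5)
      st <- .trainStep(model, x, bagLabel(bag), cw[[bagLabel(bag) + 1L]])
      upd <- .sgdUpdate(model@weights, velocity, st$grads,
                        config$learningRate, config$momentum,
                        config$weightDecay)
      model@weights <- upd$w
      velocity <- upd$v
      k <- k + 1L
      stepRows[[k]] <- data.frame(epoch = ep, step = k,
                                  lossNoReg = st$loss$lossNoReg,
                                  rL0 = st$loss$rL0, rMer = st$loss$rMer,
                                  lossReg = st$loss$lossReg)
    }
    valAuc <- NA_real_
    if (!is.null(valBags) && length(valBags)) {
      vs <- vapply(valBags, function(bg)
        forwardBag(model, bg)$bagProbability, numeric(1))
      vl <- vapply(valBags, bagLabel, integer(1))
      valAuc <- aucTrapezoid(vl, vs)
      if (!is.na(valAuc) && valAuc >= best$auc) {  # ties -> later epoch
        best <- list(auc = valAuc, weights = model@weights, epoch = ep)
      }
    }
    meanLoss <- mean(vapply(stepRows[(k - n + 1L):k],
                            function(r) r$lossReg, numeric(1)))
    epochRows[[ep]] <- data.frame(epoch = ep, meanLossReg = meanLoss,
                                  valAuc = valAuc)
  }
  if (config$modelSelection == "val_auc" && best$epoch > 0L)
    model@weights <- best$weights
  list(model = model,
       steps = if (k) do.call(rbind, stepRows[seq_len(k)]) else
         data.frame(epoch = integer(), step = integer(),
                    lossNoReg = numeric(), rL0 = numeric(),
                    rMer = numeric(), lossReg = numeric()),
       epochs = if (config$epochs) do.call(rbind, epochRows) else
         data.frame(epoch = integer(), meanLossReg = numeric(),
                    valAuc = numeric()),
       bestEpoch = if (best$epoch > 0L) best$epoch else config$epochs)
}

#' Learning-rate sweep
#'
#' Trains one model per grid value from the same seed (identical
#' initialization and data order) and returns the model with the best
#' validation AUC together with the full table, mirroring the protocol under
#' which the best-performing configuration can differ per patch size.
#'
#' @param variant,patchSide model identity, see [assembleModel()].
#' @param trainBags,valBags labeled bag lists.
#' @param lrGrid learning rates to try (default from [trainConfig()]).
#' @param config base [trainConfig()]; its learningRate is overridden.
#' @param ... further arguments to [assembleModel()] (regularizers etc.).
#' @return list with \code{table} (data.frame lr, valAuc, bestEpoch),
#'   \code{model} (winner) and \code{bestLr}.
#' @export
sweepLearningRates <- function(variant, patchSide, trainBags, valBags,
                               lrGrid = trainConfig()$lrGrid,
                               config = trainConfig(), ...) {
  if (!length(lrGrid)) stop("learning-rate grid is empty", call. = FALSE)
  rows <- vector("list", length(lrGrid))
  bestModel <- NULL
  bestAuc <- -Inf
  bestLr <- NA_real_
  for (i in seq_along(lrGrid)) {
    cfg <- config
    cfg$learningRate <- lrGrid[i]
    set.seed(cfg$seed)
    model <- assembleModel(variant, patchSide, ...)
    fit <- trainModel(model, trainBags, valBags, cfg)
    auc <- max(c(fit$epochs$valAuc, -Inf), na.rm = TRUE)
    rows[[i]] <- data.frame(lr = lrGrid[i], valAuc = auc,
                            bestEpoch = fit$bestEpoch)
    if (auc > bestAuc) {
      bestAuc <- auc
      bestModel <- fit$model
      bestLr <- lrGrid[i]
    }
  }
  list(table = do.call(rbind, rows), model = bestModel, bestLr = bestLr)
}

#' Multi-restart training with validation burn-in selection
#'
#' Sparse-attention MIL training is a race between the instance scorer and
#' the attention module: if sparse attention locks onto uninformative
#' instances before the scorer can rank the informative ones, the run
#' settles in a self-consistent but wrong optimum that is plainly visible as
#' a depressed validation AUC within the first couple of epochs. The
#' standard remedy for such non-convex multi-basin optimization is restart
#' selection: \code{restarts} models are assembled from derived seeds and
#' trained for \code{burninEpochs} epochs each; the candidate with the best
#' validation AUC (ties broken by lower validation cross-entropy) is trained
#' for the remaining epochs, so the selected lineage trains for
#' \code{config$epochs} epochs in total.
#'
#' @param variant,patchSide model identity, see [assembleModel()].
#' @param trainBags,valBags labeled bag lists (validation required).
#' @param config a [trainConfig()]; \code{config$epochs} is the total budget
#'   of the selected lineage.
#' @param restarts number of independent initializations.
#' @param burninEpochs burn-in epochs per candidate.
#' @param ... further arguments to [assembleModel()].
#' @return as [trainModel()], plus \code{burnin} (the candidate table) and
#'   \code{chosen} (index of the selected restart).
#' @export
trainModelRestarts <- function(variant, patchSide, trainBags, valBags,
                               config = trainConfig(), restarts = 5L,
                               burninEpochs = 2L, ...) {
  if (restarts < 1L) stop("need at least one restart", call. = FALSE)
  if (!length(valBags)) stop("restart selection needs validation bags",
                             call. = FALSE)
  if (burninEpochs > config$epochs)
    stop("burninEpochs exceeds the epoch budget", call. = FALSE)
  labs <- vapply(valBags, bagLabel, integer(1))
  cand <- vector("list", restarts)
  rows <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    sr <- config$seed + 1009L * (r - 1L)
    cfg <- config
    cfg$seed <- sr
    cfg$epochs <- burninEpochs
    cfg$modelSelection <- "final"
    set.seed(sr)
    m <- assembleModel(variant, patchSide, ...)
    fit <- trainModel(m, trainBags, valBags, cfg)
    scores <- vapply(valBags, function(b)
      forwardBag(fit$model, b)$bagProbability, numeric(1))
    q <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
    rows[[r]] <- data.frame(restart = r, seed = sr,
                            valAuc = aucTrapezoid(labs, scores),
                            valBce = mean(-(labs * log(q) +
                                            (1 - labs) * log(1 - q))))
    cand[[r]] <- fit$model
  }
  burnin <- do.call(rbind, rows)
  chosen <- order(-burnin$valAuc, burnin$valBce)[1L]
  cfg <- config
  cfg$seed <- burnin$seed[chosen] + 1L
  cfg$epochs <- config$epochs - burninEpochs
  fit <- trainModel(cand[[chosen]], trainBags, valBags, cfg)
  fit$burnin <- burnin
  fit$chosen <- chosen
  fit
}
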