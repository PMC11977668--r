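# Layer-list builders for the network components and exact parameter
# counting. The counts are derived from the layer lists alone so that the
# assembled models can be cross-checked against them.

.convLayer <- function(filters, window, activation = "relu")
  list(kind = "conv2d", filters = as.integer(filters),
       window = as.integer(rep(window, length.out = 2L)),
       activation = activation)
.poolLayer <- function(window)
  list(kind = "maxpool2d", window = as.integer(rep(window, length.out = 2L)))
.gapLayer <- function() list(kind = "global_avg_pool")
.denseLayer <- function(units, activation)
  list(kind = "dense", units = as.integer(units), activation = activation)
.dropoutLayer <- function(rate) list(kind = "dropout", rate = rate)

# Walk a layer list tracking the channel/unit count; convolutions and dense
# layers carry biases.
.countLayerList <- function(layers, inChannels) {
  total <- 0
  ch <- inChannels
  for (ly in layers) {
    if (ly$kind == "conv2d") {
      total <- total + prod(ly$window) * ch * ly$filters + ly$filters
      ch <- ly$filters
    } else if (ly$kind == "dense") {
      total <- total + ch * ly$units + ly$units
      ch <- ly$units
    }
  }
  total
}

#' Build the convolutional instance encoder (Subnet 1)
#'
#' Five same-padded convolution blocks
#' conv(16, 5x5, ReLU) - pool 3x3 - conv(32, 3x3, ReLU) - pool 2x2 -
#' conv(64, 3x3, ReLU) - pool 2x2 - conv(128, 3x3, ReLU) - pool 2x2 -
#' conv(128, 3x3, ReLU) - global average pooling, taking an RGB patch of any
#' supported side to a 128-vector embedding. Pooling is non-overlapping with
#' floor division, so the smallest supported patch side (86 px) traces
#' 86 -> 28 -> 14 -> 7 -> 3 and still reaches the last convolution with a
#' nonzero spatial extent. 245,792 parameters.
#'
#' @return a [MILNetworkSpec-class].
#' @export
buildSubnet1 <- function() {
  layers <- list(
    .convLayer(16, 5), .poolLayer(3),
    .convLayer(32, 3), .poolLayer(2),
    .convLayer(64, 3), .poolLayer(2),
    .convLayer(128, 3), .poolLayer(2),
    .convLayer(128, 3), .gapLayer())
  new("MILNetworkSpec", name = "subnet1", layers = layers,
      inputDim = c(NA_integer_, NA_integer_, 3L), outputDim = 128L,
      nParams = .countLayerList(layers, 3L))
}

#' Build the dense scoring head (Subnet 2)
#'
#' dropout(0.5) - dense(256, ReLU) - dropout(0.5) - dense(1, sigmoid) on a
#' 128-vector embedding, producing one probability. The final layer has a
#' single sigmoid unit: that is the only width under which the published
#' whole-model parameter counts (279,073 / 312,354) reconcile. 33,281
#' parameters.
#'
#' @return a [MILNetworkSpec-class].
#' @export
buildSubnet2 <- function() {
  layers <- list(.dropoutLayer(0.5), .denseLayer(256, "relu"),
                 .dropoutLayer(0.5), .denseLayer(1, "sigmoid"))
  new("MILNetworkSpec", name = "subnet2", layers = layers,
      inputDim = 128L, outputDim = 1L,
      nParams = .countLayerList(layers, 128L))
}

#' Build the attention module
#'
#' dense(256, tanh) - dense(1, sigmoid) applied to each instance embedding,
#' producing one attention logit per instance; the logit vector is then
#' turned into a probability distribution by softmax or sparsemax. The
#' sigmoid confines logits to (0, 1) (the published design); the model
#' assembler can bypass it for ablation. 33,281 parameters.
#'
#' @return a [MILNetworkSpec-class].
#' @export
buildAttentionModule <- function() {
  layers <- list(.denseLayer(256, "tanh"), .denseLayer(1, "sigmoid"))
  new("MILNetworkSpec", name = "attention", layers = layers,
      inputDim = 128L, outputDim = 1L,
      nParams = .countLayerList(layers, 128L))
}

#' Parameter count of the ResNet-50 reference backbone
#'
#' Counting-only description of the single-image classification baseline the
#' MIL variants are compared against: a ResNet-50 v1 backbone whose
#' convolutions carry bias terms, followed by global average pooling and one
#' sigmoid output unit. Batch-normalization layers are counted with all four
#' per-channel arrays (scale, shift, moving mean, moving variance), matching
#' how deep-learning toolkits report model size. 23,589,761 parameters.
#' No forward pass is provided; the baseline is outside the MIL core.
#'
#' @return a [MILNetworkSpec-class] with a summary layer list.
#' @export
buildResNet50Spec <- function() {
  convP <- function(k, cin, cout) k * k * cin * cout + cout   # with bias
  bnP <- function(c) 4 * c                                    # gamma, beta, mu, var
  total <- convP(7, 3, 64) + bnP(64)                          # stem
  stages <- list(c(64, 3), c(128, 4), c(256, 6), c(512, 3))   # (width, blocks)
  cin <- 64
  for (st in stages) {
    w <- st[1]; blocks <- st[2]
    for (b in seq_len(blocks)) {
      total <- total + convP(1, cin, w) + bnP(w) +
        convP(3, w, w) + bnP(w) +
        convP(1, w, 4 * w) + bnP(4 * w)
      if (b == 1L)                                            # projection shortcut
        total <- total + convP(1, cin, 4 * w) + bnP(4 * w)
      cin <- 4 * w
    }
  }
  total <- total + (2048 + 1)                                 # GAP + sigmoid unit
  new("MILNetworkSpec", name = "resnet50_baseline",
      layers = list(list(kind = "conv2d", filters = 64L, window = c(7L, 7L),
                         activation = "relu"),
                    list(kind = "global_avg_pool"),
                    .denseLayer(1, "sigmoid")),
      inputDim = c(NA_integer_, NA_integer_, 3L), outputDim = 1L,
      nParams = total)
}

# Spatial side after each encoder stage for a given input side; used to
# validate patch sides and size gradient buffers.
.subnet1SpatialTrace <- function(side) {
  pools <- c(3L, 2L, 2L, 2L)
  out <- integer(5)
  cur <- as.integer(side)
  for (i in 1:4) {
    cur <- cur %/% pools[i]
    out[i] <- cur
  }
  out[5] <- cur      # last conv keeps the spatial size (same padding)
  if (any(out < 1L))
    stop("patch side ", side, " collapses to zero spatial size in the encoder",
         call. = FALSE)
  out
}
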