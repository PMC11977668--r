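# Probability transforms, sparsity penalties and permutation-invariant
# pooling operators. These are pure functions shared by every MIL variant.

.checkWeightVector <- function(v) {
  if (!is.numeric(v) || length(v) < 1L)
    stop("weight vector must be a nonempty numeric vector", call. = FALSE)
  if (!all(is.finite(v)))
    stop("weight vector must be finite", call. = FALSE)
  invisible(v)
}

#' Softmax probability transform
#'
#' Maps a real attention-logit vector v to exp(v_i) / sum_j exp(v_j), a
#' strictly positive probability vector. Computed with max subtraction so
#' large logits cannot overflow. Softmax never produces exact zeros, which is
#' exactly the limitation sparse attention addresses: every instance keeps a
#' nonzero pooling weight.
#'
#' @param v numeric vector of attention logits (any finite values).
#' @return numeric probability vector of the same length (sums to 1).
#' @examples
#' softmaxTransform(c(0, 0))            # 0.5 0.5
#' softmaxTransform(log(c(1, 3)))       # 0.25 0.75
#' @seealso [sparsemaxTransform()]
#' @export
softmaxTransform <- function(v) {
  .checkWeightVector(v)
  e <- exp(v - max(v))
  e / sum(e)
}

#' Sparsemax probability transform
#'
#' The Euclidean projection of a real vector onto the probability simplex.
#' With sorted coordinates v_(1) >= ... >= v_(L), the support size is the
#' largest l with 1 + l * v_(l) > sum_{j<=l} v_(j); the threshold is
#' Th(v) = (sum_{j<=l(v)} v_(j) - 1) / l(v) and every output coordinate is
#' max(v_i - Th(v), 0). Unlike softmax, coordinates sufficiently below the
#' leaders are mapped to exact zeros, so the corresponding instances drop out
#' of the aggregation entirely.
#'
#' @param v numeric vector of attention logits.
#' @return a [SparsemaxResult-class]: probabilities, threshold, support size.
#' @examples
#' sparsemaxTransform(c(2, 0))          # probabilities (1, 0), threshold 1
#' sparsemaxTransform(c(0.5, 0.3, 0.2)) # a simplex point is its own projection
#' @export
sparsemaxTransform <- function(v) {
  .checkWeightVector(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  k <- seq_along(u)
  supp <- max(k[1 + k * u > css])
  th <- (css[supp] - 1) / supp
  p <- pmax(v - th, 0)
  new("SparsemaxResult", probabilities = p, threshold = th,
      supportSize = sum(p > 0))
}

#' Brute-force simplex projection (test oracle)
#'
#' Independent reference for [sparsemaxTransform()]: enumerates every
#' candidate support set S, solves the equality-constrained projection on S
#' (subtract (sum(v_S) - 1)/|S| from the coordinates in S, zero elsewhere),
#' keeps the feasible candidates (no negative coordinate) and returns the one
#' closest to v in Euclidean distance. Exponential in the vector length, so
#' restricted to short vectors.
#'
#' @param v numeric vector, length at most 20.
#' @return numeric probability vector: the projection of v onto the simplex.
#' @export
simplexProjectionOracle <- function(v) {
  .checkWeightVector(v)
  L <- length(v)
  if (L > 20L) stop("oracle is exponential; use length <= 20", call. = FALSE)
  nS <- bitwShiftL(1L, L) - 1L
  memb <- vapply(seq_len(L), function(i) {
    bitwAnd(bitwShiftR(seq_len(nS), i - 1L), 1L) == 1L
  }, logical(nS))                          # nS x L membership matrix
  sizes <- rowSums(memb)
  th <- (as.vector(memb %*% v) - 1) / sizes
  # feasibility: min over S of (v_i - th_S) must be >= 0
  A <- sweep(memb * rep(v, each = nS), 1, th)
  A[!memb] <- Inf
  feasMin <- do.call(pmin, lapply(seq_len(L), function(j) A[, j]))
  # squared distance to v: |S| * th^2 on S, v_i^2 off S
  off <- as.vector((!memb) %*% (v^2))
  d2 <- sizes * th^2 + off
  d2[feasMin < -1e-12] <- Inf
  best <- which.min(d2)
  p <- numeric(L)
  p[memb[best, ]] <- v[memb[best, ]] - th[best]
  p
}

#' L0 sparsity penalty
#'
#' lambda times the number of entries whose magnitude exceeds \code{zeroTol}
#' (default: exact nonzeros, appropriate after sparsemax where exact zeros
#' occur). The indicator is piecewise constant, so this penalty contributes
#' no gradient; \code{smooth = TRUE} substitutes the differentiable surrogate
#' lambda * sum(1 - exp(-p^2 / sigma^2)).
#'
#' @param p numeric vector (typically an attention probability vector).
#' @param lambdaL0 nonnegative penalty weight.
#' @param zeroTol entries with |p_i| <= zeroTol count as zero.
#' @param smooth use the smooth surrogate instead of the exact count.
#' @param sigma width of the surrogate bump.
#' @return numeric penalty value.
#' @export
l0Penalty <- function(p, lambdaL0, zeroTol = 0, smooth = FALSE, sigma = 0.01) {
  if (!is.numeric(lambdaL0) || length(lambdaL0) != 1L || lambdaL0 < 0)
    stop("lambdaL0 must be a single nonnegative number", call. = FALSE)
  if (!all(is.finite(p))) stop("p must be finite", call. = FALSE)
  if (smooth) lambdaL0 * sum(1 - exp(-p^2 / sigma^2))
  else lambdaL0 * sum(abs(p) > zeroTol)
}

#' Entropy (MER) penalty
#'
#' lambda * sum(p_i * log p_i) with the convention 0 * log 0 = 0, applied to
#' a probability vector and multiplied by \code{merSign}. As printed (sign
#' +1) the term is the negative entropy, so adding it to a minimized loss
#' rewards high entropy; sign -1 selects the entropy-minimizing variant that
#' concentrates the attention distribution. Both are exposed because the two
#' conventions appear in the sparse-attention literature.
#'
#' @param p probability vector (checked to sum to 1 within 1e-6).
#' @param lambdaMer penalty weight.
#' @param merSign +1 or -1.
#' @return numeric penalty value.
#' @export
merPenalty <- function(p, lambdaMer, merSign = 1) {
  if (!merSign %in% c(-1, 1)) stop("merSign must be +1 or -1", call. = FALSE)
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6)
    stop("p must lie on the probability simplex", call. = FALSE)
  pos <- p > 0
  merSign * lambdaMer * sum(p[pos] * log(p[pos]))
}

#' Permutation-invariant pooling operators
#'
#' \code{maxPoolEmbeddings} takes the coordinate-wise maximum over the rows of
#' an L x D embedding matrix; \code{maxPoolPredictions} the maximum of L
#' instance scores; \code{attentionAggregateEmbeddings} the attention-weighted
#' sum of embedding rows; \code{attentionAggregatePredictions} the
#' attention-weighted sum of instance scores (a convex combination, so the
#' result stays within the score range).
#'
#' @param H numeric matrix, instances in rows.
#' @param p numeric vector of instance scores in [0, 1].
#' @param a probability vector of attention weights, same length as the
#'   instance dimension.
#' @return a length-D vector, or a scalar for the prediction poolers.
#' @name pooling
NULL

#' @rdname pooling
#' @export
maxPoolEmbeddings <- function(H) {
  if (!is.matrix(H) || nrow(H) < 1L) stop("H must be a nonempty matrix", call. = FALSE)
  apply(H, 2L, max)
}

#' @rdname pooling
#' @export
maxPoolPredictions <- function(p) {
  if (length(p) < 1L) stop("empty score vector", call. = FALSE)
  max(p)
}

#' @rdname pooling
#' @export
attentionAggregateEmbeddings <- function(H, a) {
  if (!is.matrix(H) || nrow(H) != length(a))
    stop("attention length must match the number of instances", call. = FALSE)
  as.vector(crossprod(H, a))
}

#' @rdname pooling
#' @export
attentionAggregatePredictions <- function(p, a) {
  if (length(p) != length(a))
    stop("attention length must match the number of scores", call. = FALSE)
  sum(a * p)
}
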