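test_that("softmax matches the closed form and its invariances", {
  expect_equal(softmaxTransform(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmaxTransform(log(c(1, 3))), c(0.25, 0.75))
  set.seed(41)
  for (i in 1:25) {
    v <- rnorm(sample(2:12, 1), sd = 3)
    p <- softmaxTransform(v)
    expect_true(all(p > 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(softmaxTransform(v + rnorm(1)), p, tolerance = 1e-9)
    # overflow safety
    expect_equal(softmaxTransform(v + 800), p, tolerance = 1e-9)
  }
  expect_error(softmaxTransform(numeric(0)), "nonempty")
  expect_error(softmaxTransform(c(1, Inf)), "finite")
})

test_that("sparsemax hand cases: saturation, fixed points, symmetry", {
  r <- sparsemaxTransform(c(2, 0))
  expect_identical(r@probabilities, c(1, 0))
  expect_identical(r@threshold, 1)
  expect_identical(r@supportSize, 1L)
  # a point already on the simplex is its own projection, threshold 0
  r <- sparsemaxTransform(c(0.5, 0.3, 0.2))
  expect_equal(r@probabilities, c(0.5, 0.3, 0.2), tolerance = 1e-12)
  expect_equal(r@threshold, 0, tolerance = 1e-12)
  # constant vectors project to the uniform distribution
  for (L in c(1L, 3L, 7L)) {
    r <- sparsemaxTransform(rep(2.3, L))
    expect_equal(r@probabilities, rep(1 / L, L))
    expect_identical(r@supportSize, L)
  }
  # a gap of at least 1 to every other coordinate gives a one-hot output,
  # while softmax of the same logits never reaches 1
  for (t in c(1, 1.5, 4, 20)) {
    r <- sparsemaxTransform(c(t, 0))
    expect_identical(r@probabilities, c(1, 0))
    expect_lt(max(softmaxTransform(c(t, 0))), 1)
  }
  v <- c(2.2, runif(11))
  expect_identical(sparsemaxTransform(v)@supportSize, 1L)
  expect_error(sparsemaxTransform(numeric(0)), "nonempty")
})

test_that("sparsemax agrees with the brute-force simplex projection", {
  set.seed(99)
  for (i in 1:200) {
    L <- sample(2:12, 1)
    v <- rnorm(L, sd = runif(1, 0.1, 5))
    r <- sparsemaxTransform(v)
    p <- simplexProjectionOracle(v)
    expect_lt(max(abs(r@probabilities - p)), 1e-9)
    expect_identical(r@supportSize, sum(p > 1e-12))
    # nonzero outputs all equal v_i - threshold
    nz <- r@probabilities > 0
    expect_equal(r@probabilities[nz], v[nz] - r@threshold, tolerance = 1e-12)
  }
})

test_that("L0 penalty counts nonzeros and rejects bad weights", {
  expect_identical(l0Penalty(c(0, 0, 0), 5), 0)
  expect_equal(l0Penalty(c(0.7, 0.3, 0, 0), 0.01), 0.02)
  expect_identical(l0Penalty(runif(10), 0), 0)
  expect_error(l0Penalty(c(1, 0), -0.1), "nonnegative")
  # smooth surrogate: 0 at 0, approaches lambda per clearly nonzero entry
  expect_equal(l0Penalty(c(0, 0), 1, smooth = TRUE), 0)
  expect_equal(l0Penalty(c(0.5, 0), 1, smooth = TRUE), 1, tolerance = 1e-6)
  # zeroTol masks small entries
  expect_equal(l0Penalty(c(1e-4, 0.5), 1, zeroTol = 1e-3), 1)
})

test_that("entropy penalty: conventions, bounds, sign switch", {
  expect_identical(merPenalty(c(1, 0, 0), 1), 0)
  expect_equal(merPenalty(c(0.5, 0.5), 1), log(0.5), tolerance = 1e-12)
  expect_identical(merPenalty(c(0.3, 0.7), 0), 0)
  expect_equal(merPenalty(c(0.5, 0.5), 1, merSign = -1), -log(0.5))
  expect_error(merPenalty(c(0.5, 0.6), 1), "simplex")
  expect_error(merPenalty(c(0.5, 0.5), 1, merSign = 2), "merSign")
  set.seed(5)
  for (i in 1:30) {
    L <- sample(2:10, 1)
    p <- as.vector(sparsemaxTransform(rnorm(L))@probabilities)
    val <- merPenalty(p, 1)
    expect_lte(abs(val), log(L) + 1e-12)
    oneHot <- sum(p > 0) == 1L
    if (oneHot) expect_identical(val, 0) else expect_lt(val, 0)
  }
})

test_that("pooling operators: definitions and permutation invariance", {
  H <- rbind(c(1, 0), c(0, 2))
  expect_equal(maxPoolEmbeddings(H), c(1, 2))
  expect_equal(maxPoolEmbeddings(H[1, , drop = FALSE]), c(1, 0))
  expect_equal(maxPoolPredictions(c(0.2, 0.9, 0.1)), 0.9)
  expect_equal(attentionAggregateEmbeddings(rbind(c(0, 0), c(2, 4)),
                                            c(0.5, 0.5)), c(1, 2))
  expect_equal(attentionAggregateEmbeddings(H, c(0, 1)), c(0, 2))
  expect_equal(attentionAggregatePredictions(c(0.2, 0.8), c(0.5, 0.5)), 0.5)
  expect_equal(attentionAggregatePredictions(c(0.2, 0.8), c(1, 0)), 0.2)
  set.seed(8)
  for (i in 1:20) {
    L <- sample(2:15, 1)
    H <- matrix(rnorm(L * 6), L)
    a <- softmaxTransform(rnorm(L))
    p <- runif(L)
    perm <- sample(L)
    expect_lt(max(abs(maxPoolEmbeddings(H) - maxPoolEmbeddings(H[perm, ]))),
              1e-6)
    expect_lt(abs(maxPoolPredictions(p) - maxPoolPredictions(p[perm])), 1e-6)
    expect_lt(max(abs(attentionAggregateEmbeddings(H, a) -
                      attentionAggregateEmbeddings(H[perm, ], a[perm]))),
              1e-6)
    agg <- attentionAggregatePredictions(p, a)
    expect_lt(abs(agg - attentionAggregatePredictions(p[perm], a[perm])),
              1e-6)
    expect_gte(agg, min(p))
    expect_lte(agg, max(p))
    # zero-weight instances cannot influence the attention aggregate
    sp <- as.vector(sparsemaxTransform(rnorm(L) * 3)@probabilities)
    if (any(sp == 0)) {
      H2 <- H
      H2[sp == 0, ] <- 1e6
      expect_equal(attentionAggregateEmbeddings(H, sp),
                   attentionAggregateEmbeddings(H2, sp))
    }
  }
  expect_error(attentionAggregateEmbeddings(H, c(1, 0, 0)), "match")
  expect_error(attentionAggregatePredictions(c(0.1), c(0.5, 0.5)), "match")
  expect_error(maxPoolPredictions(numeric(0)), "empty")
})
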