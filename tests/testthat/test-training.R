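test_that("reverse class weights follow the inverse-frequency formula", {
  w <- reverseClassWeights(214, 632)
  expect_equal(w[["neg"]], 846 / (2 * 214), tolerance = 1e-12)
  expect_equal(w[["pos"]], 846 / (2 * 632), tolerance = 1e-12)
  expect_equal(w[["neg"]], 1.9766, tolerance = 1e-4)
  expect_equal(w[["pos"]], 0.6693, tolerance = 1e-4)
  # expected weight over bags is 1: each class contributes half the loss
  expect_equal((214 * w[["neg"]] + 632 * w[["pos"]]) / 846, 1)
  expect_identical(reverseClassWeights(10, 10), c(neg = 1, pos = 1))
  expect_error(reverseClassWeights(1, 0), "both classes")
})

test_that("bag loss decomposes additively into its three terms", {
  lb <- bagLoss(0.5, 1, 1)
  expect_equal(lb$lossNoReg, -log(0.5), tolerance = 1e-12)
  expect_identical(lb$rL0 + lb$rMer, 0)
  expect_identical(lb$lossReg, lb$lossNoReg)
  lb <- bagLoss(0.9, 1, 1, attention = c(1, 0), lambdaL0 = 0.01)
  expect_identical(lb$rL0, 0.01)
  set.seed(40)
  for (i in 1:30) {
    a <- as.vector(sparsemaxTransform(rnorm(sample(2:10, 1)))@probabilities)
    lb <- bagLoss(runif(1), rbinom(1, 1, 0.5), runif(1, 0.5, 2),
                  attention = a, lambdaL0 = 0.005, lambdaMer = 0.005,
                  merSign = sample(c(-1, 1), 1))
    expect_lt(abs(lb$lossReg - (lb$lossNoReg + lb$rL0 + lb$rMer)), 1e-9)
  }
  # extreme probabilities are clipped, loss stays finite
  expect_true(is.finite(bagLoss(0, 1, 1)$lossReg))
  expect_true(is.finite(bagLoss(1, 0, 1)$lossReg))
})

test_that("zero-epoch training returns the initial weights untouched", {
  bags <- toyBagSet()
  set.seed(50)
  m <- assembleModel("IMIL_A", 32L)
  w0 <- m@weights
  fit <- trainModel(m, bags, config = trainConfig(epochs = 0, seed = 50))
  expect_identical(fit$model@weights, w0)
  expect_identical(nrow(fit$steps), 0L)
})

test_that("training is deterministic given the seed", {
  bags <- toyBagSet()
  cfg <- trainConfig(epochs = 2, learningRate = 1e-3, seed = 123)
  set.seed(123)
  f1 <- trainModel(assembleModel("IMIL_SA", 32L, lambdaL0 = 0.005,
                                 lambdaMer = 0.005), bags, bags, cfg)
  set.seed(123)
  f2 <- trainModel(assembleModel("IMIL_SA", 32L, lambdaL0 = 0.005,
                                 lambdaMer = 0.005), bags, bags, cfg)
  expect_identical(f1$steps, f2$steps)
  expect_identical(f1$model@weights, f2$model@weights)
})

test_that("a two-bag toy problem is memorised (capacity smoke test)", {
  bags <- toyBagSet(n = 2, seed = 7)
  expect_identical(vapply(bags, bagLabel, integer(1)), c(0L, 1L))
  set.seed(7)
  m <- assembleModel("IMIL_A", 32L)
  fit <- trainModel(m, bags, config = trainConfig(epochs = 50,
                                                  learningRate = 0.01,
                                                  seed = 7))
  ev <- evaluateBags(fit$model, bags)
  expect_identical(ev$accuracy, 1)
})

test_that("training refuses a single-class bag set", {
  bags <- toyBagSet()[c(2, 4, 6)]
  set.seed(51)
  m <- assembleModel("IMIL_M", 32L)
  expect_error(trainModel(m, bags), "both classes")
})

test_that("every trainable array receives gradient on a generic bag", {
  set.seed(52)
  m <- assembleModel("IMIL_SA", 32L, lambdaL0 = 0.005, lambdaMer = 0.005)
  x <- bagPatches(randomBag(32L, 5L))
  st <- SparseMIL:::.trainStep(m, x, 1L, 1)
  leaf <- rapply(st$grads, function(a) sum(abs(a)), how = "unlist")
  expect_true(all(leaf > 0))
  # the exact L0 term contributes value but no gradient: same step with a
  # much larger lambdaL0 yields identical gradients
  set.seed(52)
  m2 <- assembleModel("IMIL_SA", 32L, lambdaL0 = 50, lambdaMer = 0.005)
  set.seed(99); st1 <- SparseMIL:::.trainStep(m, x, 1L, 1)
  set.seed(99); st2 <- SparseMIL:::.trainStep(m2, x, 1L, 1)
  expect_identical(st1$grads, st2$grads)
  expect_gt(st2$loss$rL0, st1$loss$rL0)
})

test_that("flip augmentation is an involution on the patch array", {
  x <- bagPatches(randomBag(32L, 3L))
  expect_identical(SparseMIL:::.flipPatches(
    SparseMIL:::.flipPatches(x, TRUE, TRUE), TRUE, TRUE), x)
  expect_false(identical(SparseMIL:::.flipPatches(x, TRUE, FALSE), x))
})

test_that("learning-rate sweep returns the validation winner", {
  bags <- toyBagSet(n = 6, seed = 9)
  cfg <- trainConfig(epochs = 2, seed = 9)
  sw <- sweepLearningRates("IMIL_M", 32L, bags, bags,
                           lrGrid = c(1e-3, 1e-4), config = cfg)
  expect_identical(nrow(sw$table), 2L)
  expect_identical(max(sw$table$valAuc), max(sw$table$valAuc[
    sw$table$lr == sw$bestLr]))
  # a one-point grid returns that model
  sw1 <- sweepLearningRates("IMIL_M", 32L, bags, bags, lrGrid = 1e-3,
                            config = cfg)
  expect_identical(sw1$bestLr, 1e-3)
  # rerun equality
  sw2 <- sweepLearningRates("IMIL_M", 32L, bags, bags,
                            lrGrid = c(1e-3, 1e-4), config = cfg)
  expect_identical(sw$table, sw2$table)
  expect_error(sweepLearningRates("IMIL_M", 32L, bags, bags,
                                  lrGrid = numeric(0), config = cfg),
               "empty")
})
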