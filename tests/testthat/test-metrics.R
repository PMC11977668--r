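test_that("threshold metrics and AUC on hand-checkable score sets", {
  m <- evaluateScores(c(1, 1, 0), c(0.9, 0.8, 0.1))
  expect_identical(m$auc, 1)
  expect_identical(m$accuracy, 1)
  expect_identical(m$recall, 1)
  expect_identical(m$precision, 1)
  expect_identical(m$f1, 1)
  expect_identical(sum(m$confusion), 3L)
  # scores anti-ordered to the labels
  expect_identical(evaluateScores(c(1, 1, 0), c(0.1, 0.2, 0.9))$auc, 0)
  # all-tied scores: diagonal ROC, half credit
  expect_identical(evaluateScores(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
})

test_that("AUC equals the Mann-Whitney rank statistic", {
  set.seed(70)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    scores <- if (i %% 3 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE)
              else runif(n)
    expect_equal(aucTrapezoid(labels, scores),
                 mannWhitneyAUC(labels, scores), tolerance = 1e-12)
  }
})

test_that("confusion matrix counts and F1 identity hold", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- runif(n)
    m <- evaluateScores(labels, scores)
    expect_identical(sum(m$confusion), as.integer(n))
    if (!is.na(m$f1))
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall), tolerance = 1e-12)
    expect_identical(m$confusion["abnormal", "abnormal"] +
                     m$confusion["abnormal", "normal"],
                     as.integer(sum(labels == 1)))
  }
})

test_that("single-class sets yield NA AUC but defined threshold metrics", {
  m <- evaluateScores(c(1, 1, 1), c(0.9, 0.2, 0.7))
  expect_true(is.na(m$auc))
  expect_identical(m$accuracy, 2 / 3)
  expect_identical(m$recall, 2 / 3)
  expect_null(m$roc)
})

test_that("evaluateBags wires model scores into the metrics", {
  set.seed(72)
  m <- assembleModel("IMIL_M", 32L)
  bags <- list(randomBag(32L, 3L, label = 1L),
               randomBag(32L, 3L, label = 0L),
               randomBag(32L, 3L, label = 1L))
  ev <- evaluateBags(m, bags)
  expect_length(ev$scores, 3L)
  expect_identical(ev$labels, c(1L, 0L, 1L))
  expect_identical(ev$scores[1],
                   forwardBag(m, bags[[1]])$bagProbability)
})
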