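test_that("forward pass honours each variant's aggregation contract", {
  set.seed(10)
  bag <- randomBag(32L, 6L)
  for (v in milVariants()) {
    m <- assembleModel(v, 32L)
    r <- forwardBag(m, bag)
    expect_gte(r$bagProbability, 0)
    expect_lte(r$bagProbability, 1)
    expect_identical(dim(r$embeddings), c(6L, 128L))
    if (m@milMode == "instance") {
      expect_length(r$instanceScores, 6L)
      expect_true(all(r$instanceScores >= 0 & r$instanceScores <= 1))
    } else {
      expect_null(r$instanceScores)
    }
    if (m@aggregator == "max") {
      expect_null(r$attention)
    } else {
      expect_equal(sum(r$attention), 1, tolerance = 1e-9)
      expect_true(all(r$attention >= 0))
    }
  }
})

test_that("IMIL_M bag probability equals the maximum instance score", {
  set.seed(11)
  m <- assembleModel("IMIL_M", 32L)
  for (i in 1:5) {
    bag <- randomBag(32L, sample(2:8, 1))
    r <- forwardBag(m, bag)
    expect_identical(r$bagProbability, max(r$instanceScores))
  }
})

test_that("bag probability is invariant to instance order", {
  set.seed(12)
  for (v in milVariants()) {
    m <- assembleModel(v, 32L)
    for (i in 1:5) {
      L <- sample(3:8, 1)
      x <- array(round(runif(32 * 32 * 3 * L) * 255), c(32L, 32L, 3L, L))
      perm <- sample(L)
      b1 <- new("MILBag", patches = array(as.raw(x), dim(x)), label = 1L,
                patientId = "P", gridShape = c(1L, L))
      xp <- x[, , , perm, drop = FALSE]
      b2 <- new("MILBag", patches = array(as.raw(xp), dim(xp)), label = 1L,
                patientId = "P", gridShape = c(1L, L))
      expect_lt(abs(forwardBag(m, b1)$bagProbability -
                    forwardBag(m, b2)$bagProbability), 1e-6)
    }
  }
})

test_that("patch side mismatch is rejected", {
  set.seed(13)
  m <- assembleModel("IMIL_A", 43L)
  expect_error(forwardBag(m, randomBag(32L, 3L)), "patch side")
})

test_that("checkpoints round-trip through save/load with a JSON sidecar", {
  set.seed(14)
  m <- assembleModel("IMIL_SA", 32L, lambdaL0 = 0.005, lambdaMer = 0.005,
                     merSign = -1)
  bag <- randomBag(32L, 4L)
  p1 <- forwardBag(m, bag)$bagProbability
  path <- file.path(tempdir(), "ck.rds")
  saveModel(m, path)
  side <- jsonlite::read_json(file.path(tempdir(), "ck.json"))
  expect_identical(side$variant, "IMIL_SA")
  expect_identical(side$n_parameters, 312354L)
  m2 <- loadModel(path)
  expect_identical(m2@reg$merSign, -1)
  expect_identical(forwardBag(m2, bag)$bagProbability, p1)
})
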