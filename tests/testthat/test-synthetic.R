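test_that("generated bags satisfy the MIL labelling axiom", {
  cfg <- syntheticConfig(imageSide = 258L, patchSide = 86L)
  set.seed(60)
  for (i in 1:6) {
    neg <- generateBag(0L, cfg)
    expect_identical(sum(neg$truth), 0L)
    pos <- generateBag(1L, cfg)
    expect_gte(sum(pos$truth), 1L)
    expect_lte(sum(pos$truth), 4L)
    expect_identical(dim(pos$image), c(258L, 258L, 3L))
    expect_true(all(pos$image >= 0 & pos$image <= 255))
  }
})

test_that("generation is a pure function of the RNG state", {
  cfg <- syntheticConfig(imageSide = 172L, patchSide = 86L)
  set.seed(61)
  a <- generateBag(1L, cfg)
  set.seed(61)
  b <- generateBag(1L, cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("field-of-view mask is idempotent and has the disc's area", {
  img <- array(200, dim = c(512L, 512L, 3L))
  masked <- renderFieldOfView(img, 0.4)
  expect_identical(renderFieldOfView(masked, 0.4), masked)
  kept <- sum(masked[, , 1] == 200)
  r <- 0.4 * 512
  expect_lt(abs(kept - pi * r^2) / (pi * r^2), 0.01)
  expect_true(all(masked[, , 1] %in% c(2, 200)))
  expect_error(renderFieldOfView(img, 0.9), "0.71")
})

test_that("dataset generation hits the configured class balance and splits", {
  dir <- file.path(tempdir(), "synthsmall")
  unlink(dir, recursive = TRUE)
  cfg <- syntheticConfig(imageSide = 172L, patchSide = 86L, nImages = 100L,
                         nPatients = 30L, positiveFraction = 0.75,
                         seed = 11L)
  res <- generateDataset(cfg, dir)
  mf <- res$manifest
  expect_identical(nrow(mf), 100L)
  expect_identical(sum(mf$label), 75L)
  expect_true(all(file.exists(file.path(dir, mf$path))))
  # patient-disjoint splits
  tab <- unique(mf[, c("patient_id", "split")])
  expect_identical(anyDuplicated(tab$patient_id), 0L)
  expect_setequal(unique(mf$split), c("train", "val", "test"))
  # truth table agrees with the manifest labels (MIL axiom on disk)
  truth <- readTruth(res$truthPath)
  nAb <- vapply(mf$path, function(p) sum(truth[[p]]), integer(1))
  expect_identical(unname(nAb > 0), mf$label == 1L)
  # images round-trip losslessly through PNG and the manifest reloads
  bags <- loadBags(mf[1:2, ], 86L, crop = FALSE, dir = dir)
  expect_identical(bagLength(bags[[1]]), 4L)
  mf2 <- readManifest(res$manifestPath)
  expect_identical(mf2$label, mf$label)
})

test_that("planted abnormal patches are linearly separable by mean colour", {
  cfg <- syntheticConfig()   # full desk-scale defaults (774 px, 86 px)
  set.seed(62)
  feats <- NULL
  ys <- NULL
  for (i in 1:10) {
    g <- generateBag(1L, cfg)
    bag <- tilePatches(g$image, cfg$patchSide)
    x <- bagPatches(bag)
    mc <- t(apply(x, 4, function(p) c(mean(p[, , 1]), mean(p[, , 2]),
                                      mean(p[, , 3]))))
    feats <- rbind(feats, mc)
    ys <- c(ys, as.integer(as.vector(t(g$truth))))
  }
  fit <- suppressWarnings(glm(ys ~ feats, family = binomial))
  acc <- mean((fitted(fit) >= 0.5) == (ys == 1))
  expect_gte(acc, 0.95)
})

test_that("heavier pixel noise degrades the colour separability", {
  sepIndex <- function(noiseSd) {
    cfg <- syntheticConfig(imageSide = 258L, patchSide = 86L,
                           noiseSd = noiseSd)
    set.seed(63)
    dAb <- NULL; dNo <- NULL
    for (i in 1:8) {
      g <- generateBag(1L, cfg)
      x <- bagPatches(tilePatches(g$image, 86L))
      mc <- t(apply(x, 4, function(p) c(mean(p[, , 1]), mean(p[, , 2]),
                                        mean(p[, , 3]))))
      tv <- as.vector(t(g$truth))
      dAb <- rbind(dAb, mc[tv, , drop = FALSE])
      dNo <- rbind(dNo, mc[!tv, , drop = FALSE])
    }
    # between-class distance over within-class spread
    sqrt(sum((colMeans(dAb) - colMeans(dNo))^2)) /
      (mean(apply(dNo, 2, sd)) + mean(apply(dAb, 2, sd)))
  }
  s <- vapply(c(8, 120, 400), sepIndex, numeric(1))
  expect_true(all(diff(s) < 0))
})
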