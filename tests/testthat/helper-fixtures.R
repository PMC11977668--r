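# Shared fixtures: all test data is generated in code at run time.

# A bag of L random patches of side ps (pixels uniform in [0, 1]).
randomBag <- function(ps, L, label = 1L, patient = "P1") {
  x <- array(round(runif(ps * ps * 3 * L) * 255), dim = c(ps, ps, 3, L))
  g <- c(1L, L)
  new("MILBag",
      patches = array(as.raw(x), dim = dim(x)),
      label = as.integer(label), patientId = patient, gridShape = g)
}

# A tiny learnable bag set: negative bags are mid-gray, positive bags carry
# one bright patch. side/ps chosen so each bag has 4 instances.
toyBagSet <- function(n = 6, ps = 32L, seed = 1) {
  set.seed(seed)
  bags <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- as.integer(i %% 2 == 0)
    img <- array(51 + round(rnorm(ps * 2 * ps * 2 * 3, 0, 8)),
                 dim = c(2L * ps, 2L * ps, 3L))
    if (lab == 1L) img[1:ps, 1:ps, ] <- 230 + round(rnorm(ps * ps * 3, 0, 8))
    img <- pmin(pmax(img, 0), 255)
    bags[[i]] <- tilePatches(img, ps, label = lab,
                             patientId = sprintf("P%02d", i))
  }
  bags
}

# In-memory synthetic bags at reduced image side (fast, keeps 9 instances).
smallSyntheticBags <- function(n = 20, seed = 1, imageSide = 258L,
                               patchSide = 86L) {
  cfg <- syntheticConfig(imageSide = imageSide, patchSide = patchSide,
                         nImages = n, seed = seed)
  set.seed(seed)
  nPos <- round(n * cfg$positiveFraction)
  labs <- sample(c(rep(1L, nPos), rep(0L, n - nPos)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generateBag(labs[i], cfg)
    out[[i]] <- list(bag = tilePatches(g$image, patchSide, label = labs[i],
                                       patientId = sprintf("P%02d",
                                                           (i - 1) %/% 2)),
                     truth = g$truth)
  }
  out
}

# Independent AUC oracle: normalized Mann-Whitney rank statistic with
# half-credit for ties.
mannWhitneyAUC <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
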