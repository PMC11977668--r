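# Seeded generator of histopathology-like bags. The images emulate the
# acquisition geometry of smartphone-on-microscope H&E photographs: a bright
# pink tissue texture inside a circular field of view on a near-black
# surround, magnification variability as a spatial-frequency jitter, and (in
# abnormal images) a few patch-sized clusters of dark purple blobs standing
# in for hyperchromatic nuclei. A bag is labeled abnormal iff at least one
# patch contains a planted cluster (the standard MIL assumption), and the
# per-patch ground truth is recorded so attention maps can be scored.

#' Synthetic dataset configuration
#'
#' Defaults describe the desk-scale scenario: 774 px images (one quarter of
#' the 3096 px cropped field of view) tiled into 9 x 9 = 81 patches of 86 px
#' -- the same bag size as the largest patch setting on full-size images --
#' with the training-set class balance of roughly 3 abnormal bags per normal
#' bag (positive fraction 632/846 = 0.747).
#'
#' @param imageSide image side in pixels.
#' @param patchSide patch side (must divide imageSide in default use).
#' @param nImages total images to generate.
#' @param nPatients number of patients images are grouped under.
#' @param imagesPerPatient integer range (min, max) of images per patient.
#' @param positiveFraction fraction of abnormal images; the generated count
#'   is round(nImages * positiveFraction).
#' @param abnormalPatchesPerPositive integer range of planted abnormal
#'   patches per positive image.
#' @param magnificationJitter multiplicative range applied to the texture
#'   spatial frequency per image.
#' @param fovRadiusFraction field-of-view radius as a fraction of the image
#'   side (<= 0.71; at 0.5 the disc inscribes the image exactly).
#' @param noiseSd Gaussian pixel noise standard deviation (0--255 scale).
#' @param blobContrast 0--1; how far abnormal blobs are pulled from the pink
#'   tissue colour towards dark purple.
#' @param splitFractions train/val/test image fractions.
#' @param seed integer seed for [generateDataset()].
#' @return list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(imageSide = 774L, patchSide = 86L,
                            nImages = 120L, nPatients = 40L,
                            imagesPerPatient = c(1L, 5L),
                            positiveFraction = 0.747,
                            abnormalPatchesPerPositive = c(1L, 4L),
                            magnificationJitter = c(0.8, 1.2),
                            fovRadiusFraction = 0.7,
                            noiseSd = 8, blobContrast = 1,
                            splitFractions = c(0.6, 0.1, 0.3),
                            seed = 1L) {
  if (positiveFraction <= 0 || positiveFraction >= 1)
    stop("positiveFraction must be in (0, 1)", call. = FALSE)
  if (fovRadiusFraction <= 0 || fovRadiusFraction > 0.71)
    stop("fovRadiusFraction must be in (0, 0.71]", call. = FALSE)
  structure(list(imageSide = as.integer(imageSide),
                 patchSide = as.integer(patchSide),
                 nImages = as.integer(nImages),
                 nPatients = as.integer(nPatients),
                 imagesPerPatient = as.integer(imagesPerPatient),
                 positiveFraction = positiveFraction,
                 abnormalPatchesPerPositive =
                   as.integer(abnormalPatchesPerPositive),
                 magnificationJitter = magnificationJitter,
                 fovRadiusFraction = fovRadiusFraction,
                 noiseSd = noiseSd, blobContrast = blobContrast,
                 splitFractions = splitFractions,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

.tissuePink <- c(228, 170, 200)
.nucleusPurple <- c(88, 42, 112)

#' Apply a circular field-of-view mask
#'
#' Sets every pixel outside the centered disc of radius
#' \code{radiusFraction * min(H, W)} to near-black (intensity 2), emulating
#' the dark surround outside the microscope optics. Idempotent.
#'
#' @param image numeric array (H, W, 3), values 0--255.
#' @param radiusFraction disc radius as a fraction of the shorter side.
#' @return the masked image.
#' @export
renderFieldOfView <- function(image, radiusFraction) {
  if (radiusFraction <= 0 || radiusFraction > 0.71)
    stop("radiusFraction must be in (0, 0.71]", call. = FALSE)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  r <- radiusFraction * min(H, W)
  dy <- seq_len(H) - (H + 1) / 2
  dx <- seq_len(W) - (W + 1) / 2
  outside <- outer(dy^2, dx^2, "+") > r^2
  for (k in 1:3) {
    ch <- image[, , k]
    ch[outside] <- 2
    image[, , k] <- ch
  }
  image
}

# Paint one abnormal cluster: dense dark-purple blobs filling most of the
# patch cell whose top-left corner is (r0, c0).
.paintAbnormalCell <- function(image, r0, c0, ps, contrast) {
  nBlob <- round(runif(1, 0.004, 0.007) * ps^2)
  for (i in seq_len(nBlob)) {
    rad <- runif(1, ps * 0.035, ps * 0.07)
    cy <- r0 + runif(1, rad, ps - rad)
    cx <- c0 + runif(1, rad, ps - rad)
    rows <- max(1, floor(cy - rad)):min(dim(image)[1], ceiling(cy + rad))
    cols <- max(1, floor(cx - rad)):min(dim(image)[2], ceiling(cx + rad))
    disc <- outer((rows - cy)^2, (cols - cx)^2, "+") <= rad^2
    col <- .nucleusPurple + rnorm(3, 0, 6)
    for (k in 1:3) {
      ch <- image[rows, cols, k]
      ch[disc] <- (1 - contrast) * ch[disc] + contrast * col[k]
      image[rows, cols, k] <- ch
    }
  }
  image
}

#' Generate one synthetic bag image with ground truth
#'
#' Draws from the current R random-number state (seed it for
#' reproducibility). The image is a pink tissue texture whose spatial
#' frequency is scaled by a per-image magnification factor, plus Gaussian
#' noise, inside a circular field of view. For label 1, between
#' \code{abnormalPatchesPerPositive[1]} and \code{[2]} patch cells lying
#' inside the field of view receive a blob cluster; the per-patch truth
#' matrix marks exactly those cells.
#'
#' @param label 0 (normal) or 1 (abnormal).
#' @param config a [syntheticConfig()].
#' @return list with \code{image} (side x side x 3, 0--255), \code{truth}
#'   (grid logical matrix) and \code{label}.
#' @export
generateBag <- function(label, config) {
  side <- config$imageSide
  ps <- config$patchSide
  n <- side %/% ps
  mag <- runif(1, config$magnificationJitter[1], config$magnificationJitter[2])
  freq <- 2 * pi * mag / 37          # texture wavelength ~37 px at mag 1
  xs <- seq_len(side)
  tex <- 0.6 * outer(sin(freq * xs + runif(1, 0, 2 * pi)),
                     sin(0.83 * freq * xs + runif(1, 0, 2 * pi))) +
    0.4 * outer(cos(0.61 * freq * xs + runif(1, 0, 2 * pi)),
                cos(1.27 * freq * xs + runif(1, 0, 2 * pi)))
  image <- array(0, dim = c(side, side, 3L))
  for (k in 1:3)
    image[, , k] <- .tissuePink[k] + 14 * tex +
      matrix(rnorm(side^2, 0, config$noiseSd), side, side)
  truth <- matrix(FALSE, n, n)
  if (label == 1L) {
    rng <- config$abnormalPatchesPerPositive
    kAb <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    centers <- (seq_len(n) - 0.5) * ps
    rFov <- config$fovRadiusFraction * side
    cellDist <- sqrt(outer((centers - side / 2)^2, (centers - side / 2)^2, "+"))
    eligible <- which(cellDist < rFov - ps / 2)
    if (kAb > length(eligible))
      stop("abnormal patch count exceeds the cells inside the field of view",
           call. = FALSE)
    cells <- if (length(eligible) == 1L) eligible else
      sample(eligible, kAb)
    for (cell in cells) {
      rc <- arrayInd(cell, c(n, n))
      image <- .paintAbnormalCell(image, (rc[1] - 1L) * ps + 1L,
                                  (rc[2] - 1L) * ps + 1L, ps,
                                  config$blobContrast)
      truth[rc[1], rc[2]] <- TRUE
    }
  }
  image <- renderFieldOfView(image, config$fovRadiusFraction)
  image <- round(pmin(pmax(image, 0), 255))
  list(image = image, truth = truth, label = as.integer(label))
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG images, a manifest CSV (\code{path,label,patient_id,split})
#' with patient-wise stratified splits, and a per-patch truth CSV
#' (\code{path,patch_row,patch_col,truth}). Label assignment is by count
#' rounding, so the empirical positive fraction matches the configured one
#' to within 1/(2 nImages). Deterministic given \code{config$seed}.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed); images go to
#'   \code{dir/images}.
#' @return invisibly, a list with \code{manifest} (data.frame),
#'   \code{truth} (data.frame) and the two CSV paths.
#' @export
generateDataset <- function(config, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  nImages <- config$nImages
  nPos <- round(nImages * config$positiveFraction)
  labels <- sample(c(rep(1L, nPos), rep(0L, nImages - nPos)))
  # group images under patients with random loads in the configured range
  loads <- integer(0)
  while (sum(loads) < nImages) {
    loads <- c(loads, sample(config$imagesPerPatient[1]:
                             config$imagesPerPatient[2], 1L))
    if (length(loads) == config$nPatients) break
  }
  loads[length(loads)] <- loads[length(loads)] + nImages - sum(loads)
  while (sum(loads) < nImages) loads <- c(loads, 1L)  # more patients if needed
  patientOf <- rep(sprintf("P%03d", seq_along(loads)), loads)[seq_len(nImages)]
  paths <- file.path("images", sprintf("img%04d.png", seq_len(nImages)))
  truthRows <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    bagOut <- generateBag(labels[i], config)
    png::writePNG(bagOut$image / 255, file.path(dir, paths[i]))
    g <- dim(bagOut$truth)
    truthRows[[i]] <- data.frame(path = paths[i],
                                 patch_row = rep(seq_len(g[1]), g[2]),
                                 patch_col = rep(seq_len(g[2]),
                                                 each = g[1]),
                                 truth = as.integer(bagOut$truth))
  }
  records <- data.frame(path = paths, label = labels,
                        patient_id = patientOf,
                        split = NA_character_,
                        stringsAsFactors = FALSE)
  records <- patientStratifiedSplit(records, config$splitFractions,
                                    seed = config$seed)
  manifestPath <- file.path(dir, "manifest.csv")
  writeManifest(records, manifestPath)
  truth <- do.call(rbind, truthRows)
  truthPath <- file.path(dir, "truth.csv")
  write.csv(truth, truthPath, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = records, truth = truth,
                 manifestPath = manifestPath, truthPath = truthPath))
}

#' Read a per-patch truth table as matrices
#'
#' @param path truth CSV written by [generateDataset()].
#' @return named list (by image path) of logical grid matrices.
#' @export
readTruth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$path), function(d) {
    g <- matrix(FALSE, max(d$patch_row), max(d$patch_col))
    g[cbind(d$patch_row, d$patch_col)] <- d$truth == 1
    g
  })
  out
}
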