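# Raw images to bags: field-of-view cropping, patch tiling, manifest I/O,
# patient-wise stratified splitting.

#' Read an 8-bit RGB image
#'
#' Reads PNG (always) or TIFF (when the \pkg{tiff} package is installed) into
#' an H x W x 3 numeric array with values 0--255. Grayscale input is
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path image file path.
#' @return numeric array (H, W, 3), values in 0--255.
#' @export
readRawImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Crop a microscope image to its field of view
#'
#' Microscope-adapter images show a bright circular tissue field on a dark
#' surround. The crop takes the square of side min(H, W) centered on the
#' centroid of the above-threshold pixels (grayscale intensity above
#' \code{threshold} times the image maximum), clamped to the image bounds.
#' A 4128 x 3096 image with a centered field of view therefore becomes
#' 3096 x 3096. The operation is idempotent: a square image is returned
#' unchanged up to re-centering, and re-cropping a crop is the identity.
#'
#' @param image numeric array (H, W, 3), values 0--255.
#' @param threshold fraction of the maximum intensity separating tissue from
#'   the dark surround.
#' @return square numeric array (side, side, 3) with side = min(H, W).
#' @export
cropFieldOfView <- function(image, threshold = 0.1) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  mask <- gray > threshold * max(gray)
  if (!any(mask))
    stop("no pixel above threshold: no tissue found", call. = FALSE)
  rw <- rowSums(mask); cw <- colSums(mask)
  cy <- sum(seq_len(H) * rw) / sum(rw)
  cx <- sum(seq_len(W) * cw) / sum(cw)
  side <- min(H, W)
  r0 <- min(max(round(cy) - side %/% 2L, 1L), H - side + 1L)
  c0 <- min(max(round(cx) - side %/% 2L, 1L), W - side + 1L)
  image[r0:(r0 + side - 1L), c0:(c0 + side - 1L), , drop = FALSE]
}

#' Tile a square image into a bag of patches
#'
#' Cuts the image into all possible equal-sized non-overlapping square
#' patches of side \code{patchSide}, read row-major from the top-left. When
#' the side is not a multiple of \code{patchSide} the right/bottom remainder
#' strip is discarded (the canonical patch sides 86, 129, 172, 258 and 344
#' all divide the 3096 px field of view exactly, giving 1296, 576, 324, 144
#' and 81 instances).
#'
#' @param image square numeric array (side, side, 3), values 0--255.
#' @param patchSide patch side in pixels.
#' @param label optional image-level label (0/1).
#' @param patientId optional patient identifier.
#' @return a [MILBag-class].
#' @export
tilePatches <- function(image, patchSide, label = NA_integer_,
                        patientId = NA_character_) {
  d <- dim(image)
  if (d[1] != d[2]) stop("tilePatches expects a square image", call. = FALSE)
  patchSide <- as.integer(patchSide)
  if (patchSide > d[1])
    stop("patchSide exceeds the image side", call. = FALSE)
  n <- d[1] %/% patchSide
  L <- n * n
  patches <- array(as.raw(0L), dim = c(patchSide, patchSide, 3L, L))
  vals <- as.raw(pmin(pmax(round(image), 0), 255))
  dim(vals) <- d
  k <- 0L
  for (r in seq_len(n)) {
    rows <- ((r - 1L) * patchSide + 1L):(r * patchSide)
    for (cc in seq_len(n)) {
      k <- k + 1L
      cols <- ((cc - 1L) * patchSide + 1L):(cc * patchSide)
      patches[, , , k] <- vals[rows, cols, ]
    }
  }
  new("MILBag", patches = patches, label = as.integer(label),
      patientId = as.character(patientId), gridShape = c(n, n))
}

#' Reassemble a bag into its image region
#'
#' Inverse of [tilePatches()] on the tiled region: places the patches back on
#' their grid, returning a (rows*ps, cols*ps, 3) array with values 0--255.
#' Useful for checking that tiling is lossless.
#'
#' @param bag a [MILBag-class].
#' @return numeric array of the reassembled region.
#' @export
untilePatches <- function(bag) {
  d <- dim(bag@patches)
  ps <- d[1]
  g <- bag@gridShape
  out <- array(0, dim = c(g[1] * ps, g[2] * ps, 3L))
  vals <- array(as.integer(bag@patches), dim = d)
  k <- 0L
  for (r in seq_len(g[1])) {
    for (cc in seq_len(g[2])) {
      k <- k + 1L
      out[((r - 1L) * ps + 1L):(r * ps),
          ((cc - 1L) * ps + 1L):(cc * ps), ] <- vals[, , , k]
    }
  }
  out
}

.normalizeLabels <- function(label, where = "manifest") {
  lab <- tolower(trimws(as.character(label)))
  out <- ifelse(lab %in% c("1", "abnormal"), 1L,
                ifelse(lab %in% c("0", "normal"), 0L, NA_integer_))
  bad <- which(is.na(out))
  if (length(bad))
    stop(where, " rows ", paste(bad, collapse = ", "),
         ": unknown label token(s) ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  out
}

.validateManifest <- function(df) {
  need <- c("path", "label", "patient_id", "split")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$label <- .normalizeLabels(df$label)
  dup <- which(duplicated(df$path))
  if (length(dup))
    stop("manifest rows ", paste(dup, collapse = ", "),
         ": duplicate path(s) ", paste(unique(df$path[dup]), collapse = ", "),
         call. = FALSE)
  bad <- !df$split %in% c("train", "val", "test")
  if (any(bad))
    stop("manifest rows ", paste(which(bad), collapse = ", "),
         ": split must be train/val/test", call. = FALSE)
  tab <- unique(df[, c("patient_id", "split")])
  multi <- unique(tab$patient_id[duplicated(tab$patient_id)])
  if (length(multi))
    stop("patient(s) ", paste(multi, collapse = ", "),
         " appear in more than one split", call. = FALSE)
  df
}

#' Read / write a bag manifest
#'
#' The manifest is a UTF-8 CSV with header \code{path,label,patient_id,split}.
#' Labels may be 0/1 or normal/abnormal (case-insensitive) and are normalized
#' to 0/1 on read. Reading validates the file: unknown label tokens,
#' duplicate paths and patients straddling two splits are errors that name
#' the offending rows.
#'
#' @param path CSV file path.
#' @param records data.frame with columns path, label, patient_id, split.
#' @return \code{readManifest} a validated data.frame;
#'   \code{writeManifest} the path, invisibly.
#' @export
readManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .validateManifest(df)
}

#' @rdname readManifest
#' @export
writeManifest <- function(records, path) {
  need <- c("path", "label", "patient_id", "split")
  write.csv(records[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Patient-wise stratified split
#'
#' Partitions patients (never individual images) into train/val/test so that
#' each split's abnormal fraction stays close to the global fraction and the
#' split sizes approach the requested image fractions. Patients are visited
#' in a seeded random order, largest first, and greedily assigned to the
#' split whose size deficit and class-balance deviation the assignment
#' improves most. Deterministic given \code{seed}.
#'
#' @param records data.frame with at least path, label, patient_id.
#' @param fractions numeric length 3 (train, val, test), all positive,
#'   summing to 1.
#' @param seed integer seed for the visiting order.
#' @return the records with a \code{split} column assigned.
#' @export
patientStratifiedSplit <- function(records, fractions = c(0.6, 0.1, 0.3),
                                   seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three values summing to 1", call. = FALSE)
  if (any(fractions <= 0))
    stop("all three splits must receive a positive fraction", call. = FALSE)
  records$label <- .normalizeLabels(records$label, "records")
  pats <- unique(records$patient_id)
  if (length(pats) < 3L)
    stop("need at least 3 patients to form 3 splits", call. = FALSE)
  nImg <- vapply(pats, function(p) sum(records$patient_id == p), numeric(1))
  nPos <- vapply(pats, function(p)
    sum(records$label[records$patient_id == p]), numeric(1))
  globalPos <- sum(nPos) / sum(nImg)
  target <- fractions * sum(nImg)
  splits <- c("train", "val", "test")
  # visiting order drawn from a local RNG so the caller's stream is untouched
  ord <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    order(-nImg, sample.int(length(pats)))
  })
  cnt <- c(0, 0, 0); pos <- c(0, 0, 0)
  assign_ <- character(length(pats))
  for (i in ord) {
    score <- vapply(1:3, function(s) {
      newCnt <- cnt[s] + nImg[i]
      newFrac <- (pos[s] + nPos[i]) / newCnt
      sizePenalty <- max(0, newCnt - target[s]) / target[s]
      abs(newFrac - globalPos) + 2 * sizePenalty +
        (cnt[s] / max(target[s], 1)) * 0.5
    }, numeric(1))
    s <- which.min(score)
    assign_[i] <- splits[s]
    cnt[s] <- cnt[s] + nImg[i]
    pos[s] <- pos[s] + nPos[i]
  }
  if (any(cnt == 0))
    stop("a split would be empty; adjust fractions or add patients",
         call. = FALSE)
  records$split <- assign_[match(records$patient_id, pats)]
  records
}

#' Load bags listed in a manifest
#'
#' Reads each image, optionally crops it to the field of view, and tiles it
#' into a [MILBag-class] carrying the manifest label and patient.
#'
#' @param manifest validated manifest data.frame (see [readManifest()]).
#' @param patchSide patch side in pixels.
#' @param crop apply [cropFieldOfView()] before tiling.
#' @param dir directory that relative manifest paths are resolved against.
#' @return named list of bags (names = manifest paths).
#' @export
loadBags <- function(manifest, patchSide, crop = TRUE, dir = NULL) {
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$path
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!is.null(dir) && !file.exists(p)) p <- file.path(dir, p)
    img <- readRawImage(p)
    if (crop) img <- cropFieldOfView(img)
    out[[i]] <- tilePatches(img, patchSide, label = manifest$label[i],
                            patientId = manifest$patient_id[i])
  }
  out
}
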