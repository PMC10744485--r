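#' @include AllClasses.R utils-interp.R
NULL

#' Preprocess a synthetic X-ray image
#'
#' Applies, in order: (1) grayscale conversion (luminance average over
#' channels); (2) an intensity threshold keeping the brighter pixels (Otsu by
#' default, parameter-free and robust for bimodal DRRs; a fixed-quantile
#' threshold is available); (3) morphological opening (3x3 box) then closing
#' (5x5 box) to remove specks and fill gaps; (4) location of the largest
#' 8-connected foreground component (ties broken by topmost-leftmost bounding
#' box); (5) cropping of the original grayscale to that component's bounding
#' box; (6) min-max normalization to [0, 1] (an all-constant crop collapses
#' to zeros); (7) symmetric zero padding of the shorter dimension to a square
#' (odd remainders put the extra row/column at bottom/right); (8) bilinear
#' resampling to `outSize` x `outSize`.
#'
#' @param img numeric matrix, 3-channel array, [XRayImage-class], or path to
#'   a PNG file.
#' @param outSize output edge length in pixels (default 128).
#' @param threshold `"otsu"` or `"quantile"`.
#' @param quantile foreground quantile when `threshold = "quantile"`.
#' @return An [XRayImage-class] of size `outSize` x `outSize` in [0, 1].
#' @export
preprocessXray <- function(img, outSize = 128L,
                           threshold = c("otsu", "quantile"),
                           quantile = 0.5) {
  threshold <- match.arg(threshold)
  if (is.character(img)) img <- readXRay(img)
  ang <- 0
  if (is(img, "XRayImage")) { ang <- img@viewAngleDeg; img <- img@pixels }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)  # luminance
  if (!is.matrix(img) || length(img) == 0L) stop("img must be a 2D image")

  g <- img
  gn <- rescale01(g)
  if (all(gn == 0)) {
    # constant image: no threshold exists; treat the whole frame as bright
    bin <- matrix(TRUE, nrow(g), ncol(g))
  } else {
    thr <- if (threshold == "otsu") EBImage::otsu(gn, range = c(0, 1))
           else stats::quantile(gn, quantile)
    bin <- gn > thr
  }
  binI <- EBImage::closing(EBImage::opening(bin * 1, EBImage::makeBrush(3, "box")),
                           EBImage::makeBrush(5, "box"))
  lab <- EBImage::bwlabel(binI)
  nlab <- max(lab)
  if (nlab < 1L) stop("empty X-ray: no foreground pixels after thresholding")
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: topmost, then leftmost bounding box
    corners <- t(vapply(best, function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      c(min(w[, 1]), min(w[, 2]))
    }, numeric(2)))
    best <- best[order(corners[, 1], corners[, 2])][1]
  }
  w <- which(lab == best, arr.ind = TRUE)
  r0 <- min(w[, 1]); r1 <- max(w[, 1]); c0 <- min(w[, 2]); c1 <- max(w[, 2])
  crop <- g[r0:r1, c0:c1, drop = FALSE]
  crop <- rescale01(crop)
  nr <- nrow(crop); nc <- ncol(crop)
  side <- max(nr, nc)
  sq <- matrix(0, side, side)
  offR <- (side - nr) %/% 2L
  offC <- (side - nc) %/% 2L
  sq[offR + seq_len(nr), offC + seq_len(nc)] <- crop
  out <- resizeBilinear(sq, outSize, outSize)
  xrayImage(pmin(pmax(out, 0), 1), ang)
}

#' Package a paired sample as a single case file
#'
#' One file per case containing exactly the three named elements `"ct"`
#' (normalized to [0, 1] by `intensityScale`), `"xray1"` and `"xray2"`, with
#' an exact round trip. The container is an RDS serialization (the package's
#' native case format).
#'
#' @param ct a [CTVolume-class] (raw intensity scale) or a normalized 3D
#'   array in [0, 1].
#' @param xray1,xray2 preprocessed anterior/lateral [XRayImage-class] objects
#'   or matrices in [0, 1].
#' @param path output file path (conventionally `.rds`); errors before any
#'   file is created if inputs are missing or invalid.
#' @param intensityScale normalization divisor applied when `ct` carries raw
#'   intensities (default 2500).
#' @return `packageCase` invisibly returns `path`; `readCase` returns a list
#'   with elements `ct`, `xray1`, `xray2`.
#' @export
packageCase <- function(ct, xray1, xray2, path, intensityScale = 2500) {
  if (missing(xray2) || is.null(xray2))
    stop("xray2 is required; no file was created")
  if (missing(xray1) || is.null(xray1))
    stop("xray1 is required; no file was created")
  if (is(ct, "CTVolume")) ct <- ct@data / intensityScale
  ct <- pmin(pmax(ct, 0), 1)
  if (is(xray1, "XRayImage")) xray1 <- xray1@pixels
  if (is(xray2, "XRayImage")) xray2 <- xray2@pixels
  stopifnot(is.matrix(xray1), is.matrix(xray2), length(dim(ct)) == 3L)
  saveRDS(list(ct = ct, xray1 = xray1, xray2 = xray2), path)
  invisible(path)
}

#' @rdname packageCase
#' @export
readCase <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", sQuote(path))
  x <- readRDS(path)
  if (!identical(sort(names(x)), c("ct", "xray1", "xray2")))
    stop("case file must contain exactly the elements ct, xray1, xray2")
  x[c("ct", "xray1", "xray2")]
}

# round-half-up; R's round() is round-half-even
roundHalfUp <- function(x) floor(x + 0.5)

#' Split case identifiers into train and test partitions
#'
#' Seeded uniform shuffle; the first `roundHalfUp(trainFrac * n)` ids form
#' the training set and the rest the test set, so 440 cases at the default
#' 80/20 split yield exactly 352 train and 88 test cases. Deterministic under
#' `seed`.
#'
#' @param ids character (or coercible) case identifiers, n >= 2.
#' @param trainFrac training fraction, within (0, 1).
#' @param seed integer seed.
#' @return A [DatasetSplit-class].
#' @export
splitCases <- function(ids, trainFrac = 0.8, seed = 1L) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 2L) stop("need at least two cases to split")
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("trainFrac must lie strictly between 0 and 1")
  set.seed(as.integer(seed))
  perm <- sample(ids)
  nTrain <- roundHalfUp(trainFrac * n)
  nTrain <- min(max(nTrain, 1L), n - 1L)
  new("DatasetSplit", trainIds = perm[seq_len(nTrain)],
      testIds = perm[(nTrain + 1L):n])
}

#' Write / read a split manifest CSV
#'
#' Two columns: `case_id`, `partition` ("train"/"test").
#' @param split a [DatasetSplit-class].
#' @param path CSV path.
#' @return `writeSplit` invisibly returns `path`; `readSplit` a
#'   [DatasetSplit-class].
#' @export
writeSplit <- function(split, path) {
  df <- data.frame(
    case_id = c(split@trainIds, split@testIds),
    partition = rep(c("train", "test"),
                    c(length(split@trainIds), length(split@testIds))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("DatasetSplit", trainIds = df$case_id[df$partition == "train"],
      testIds = df$case_id[df$partition == "test"])
}

#' Training-time augmentation of a paired sample
#'
#' Each X-ray is resized to `resizeTo` x `resizeTo` (150 by default), a
#' random crop back to the original size is taken with the same offset for
#' both views, and the crops are standardized by the provided mean and
#' standard deviation (conventionally dataset-level statistics of the
#' training split; the defaults leave values unchanged). The CT passes
#' through untouched. Deterministic given `seed`.
#'
#' @param sample a [PairedSample-class] with square X-rays.
#' @param seed integer seed for the crop offset.
#' @param resizeTo intermediate resize edge (default 150).
#' @param mean,sd standardization statistics (defaults 0 and 1 = identity).
#' @param offset optional forced (row, col) 0-based crop offset, mainly for
#'   testing; `c(0, 0)` selects the top-left crop.
#' @return A list with `ct` (unchanged array), `xray1`, `xray2` (standardized
#'   crop matrices) and `caseId`. Standardized values are no longer confined
#'   to [0, 1], so plain matrices rather than XRayImage objects are returned.
#' @export
augmentSample <- function(sample, seed = 1L, resizeTo = 150L, mean = 0,
                          sd = 1, offset = NULL) {
  stopifnot(is(sample, "PairedSample"))
  sz <- nrow(sample@xray1@pixels)
  if (resizeTo <= sz) stop("resizeTo must exceed the input size")
  r1 <- resizeBilinear(sample@xray1@pixels, resizeTo, resizeTo)
  r2 <- resizeBilinear(sample@xray2@pixels, resizeTo, resizeTo)
  maxOff <- resizeTo - sz
  if (is.null(offset)) {
    set.seed(as.integer(seed))
    offset <- c(sample.int(maxOff + 1L, 1L) - 1L,
                sample.int(maxOff + 1L, 1L) - 1L)
  }
  ri <- offset[1] + seq_len(sz); ci <- offset[2] + seq_len(sz)
  std <- function(m) (m - mean) / sd
  list(ct = sample@ct, xray1 = std(r1[ri, ci]), xray2 = std(r2[ri, ci]),
       caseId = sample@caseId)
}
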