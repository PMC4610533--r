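#' Segment the white blood cells of one smear image
#'
#' Runs the full four-phase pipeline: area-average resize to the working
#' scale, nucleus-seed extraction (Phase I), whole-cell region extraction
#' with the total inside-seed area anchoring the adaptive thresholds
#' (Phase II), nucleus-marked watershed separation of adhesive cells
#' (Phase III) and post-processing (Phase IV). Labels are mapped back to the
#' original resolution by nearest-neighbour upsampling. The run is
#' deterministic for a fixed input and parameter set.
#'
#' @param image integer RGB array (0-255), or a
#'   \linkS4class{SyntheticSmear}.
#' @param params \linkS4class{SegmentationParams}; remember
#'   \code{resizeFactor = 1} for images already at working scale.
#' @return a \linkS4class{SegmentationResult} at the input resolution.
#' @examples
#' sc <- makeSmear(imageSize = c(160, 200), nWbc = 2, nRbc = 15, seed = 42)
#' res <- segmentImage(sc, segmentationParams("peripheral", resizeFactor = 1))
#' max(wbcLabels(res))
#' @export
segmentImage <- function(image, params = segmentationParams()) {
  if (is(image, "SyntheticSmear")) image <- smearImage(image)
  image <- checkRGB(image)
  work <- resizeArea(image, params@resizeFactor)
  if (any(dim(work)[1:2] < 16))
    stop("segmentImage: image smaller than 16x16 after resizing")
  seeds <- buildInsideSeeds(work, params)
  inside <- insideSeeds(seeds)
  nucleusArea <- sum(inside)
  outside <- buildOutsideSeeds(work, nucleusArea, params)
  rects <- ((inside > 0) & (nucleusMask(seeds) == 0)) * 1L
  labs <- separateWbcs(outside, inside, params, connectedSeeds = rects)
  prov <- attr(labs, "provenance")
  res <- postprocessSegmentation(labsWithProv(labs, prov),
                                 nucleusMask(seeds), params)
  if (params@resizeFactor < 1) {
    d <- dim(image)[1:2]
    wl <- upsampleNearest(wbcLabels(res), d)
    nl <- upsampleNearest(nucleusLabels(res), d)
    res <- new("SegmentationResult", wbcLabels = wl, nucleusLabels = nl,
               props = regionProps(wl), provenance = res@provenance,
               params = params)
  }
  res
}

labsWithProv <- function(labs, prov) {
  attr(labs, "provenance") <- prov
  labs
}

#' Segment a batch of images
#'
#' Applies \code{\link{segmentImage}} to each image; when ground truth is
#' supplied the per-image reports are aggregated by summing the outcome
#' counts (so the aggregate TP is the sum of per-image TPs).
#'
#' @param images list of RGB arrays or \linkS4class{SyntheticSmear}s, or a
#'   directory containing images.
#' @param truths optional list of truth label matrices (taken from the
#'   scenes automatically when \code{images} are \code{SyntheticSmear}s).
#' @param params \linkS4class{SegmentationParams}.
#' @param iouThreshold IoU for a correct segmentation.
#' @return list with \code{results} (per-image
#'   \linkS4class{SegmentationResult}s), \code{reports} (per-image
#'   \linkS4class{EvalReport}s or \code{NULL}) and \code{aggregate}
#'   (pooled \linkS4class{EvalReport} or \code{NULL}).
#' @export
runBatch <- function(images, truths = NULL, params = segmentationParams(),
                     iouThreshold = params@iouMatch) {
  if (is.character(images) && length(images) == 1 && dir.exists(images)) {
    files <- sort(list.files(images, "\\.(png|tif|tiff|jpg|jpeg)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) warning("runBatch: no images found")
    images <- lapply(files, readSmear)
  }
  if (is.null(truths) && length(images) &&
      all(vapply(images, is, logical(1), "SyntheticSmear")))
    truths <- lapply(images, wbcLabels)
  results <- lapply(images, segmentImage, params = params)
  reports <- NULL
  aggregate <- NULL
  if (!is.null(truths)) {
    stopifnot(length(truths) == length(results))
    reports <- Map(function(r, t)
      evaluateSegmentation(r, t, iouThreshold), results, truths)
    cnt <- vapply(reports, function(r)
      c(r@tp, r@fp, r@fn, r@overseg, r@underseg), numeric(5))
    if (length(reports)) {
      s <- rowSums(cnt)
      aggregate <- evalReport(s[1], s[2], s[3], s[4], s[5])
    }
  }
  list(results = results, reports = reports, aggregate = aggregate)
}

# area-averaging downscale; the mapping floor((i-1)*h2/h)+1 partitions the
# source rows/cols into h2/w2 contiguous bins
resizeArea <- function(image, factor) {
  if (factor >= 1) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  h2 <- max(1L, as.integer(round(h * factor)))
  w2 <- max(1L, as.integer(round(w * factor)))
  rmap <- pmin(h2, floor((seq_len(h) - 1) * h2 / h) + 1L)
  cmap <- pmin(w2, floor((seq_len(w) - 1) * w2 / w) + 1L)
  cnt <- outer(tabulate(rmap, h2), tabulate(cmap, w2))
  out <- array(0L, c(h2, w2, 3))
  for (c3 in 1:3) {
    m <- rowsum(image[, , c3], rmap)
    m <- t(rowsum(t(m), cmap))
    out[, , c3] <- as.integer(pmin(255, pmax(0, round(m / cnt))))
  }
  out
}

upsampleNearest <- function(labels, targetDim) {
  h <- targetDim[1]; w <- targetDim[2]
  h2 <- nrow(labels); w2 <- ncol(labels)
  rmap <- pmin(h2, floor((seq_len(h) - 1) * h2 / h) + 1L)
  cmap <- pmin(w2, floor((seq_len(w) - 1) * w2 / w) + 1L)
  storageInt(labels[rmap, cmap])
}
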