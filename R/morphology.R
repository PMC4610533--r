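#' Connected components of a binary mask
#'
#' Labels maximal connected foreground regions 1..K in raster-scan order of
#' their first pixel.
#'
#' @param mask integer/logical matrix, foreground non-zero.
#' @param connectivity 4 (default, the pipeline convention) or 8.
#' @return integer label matrix, 0 = background.
#' @export
connectedComponents <- function(mask, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  .cpp_label(binMat(mask), as.integer(connectivity))
}

#' Remove small components (morphological denoising)
#'
#' Deletes every 4-connected component whose area is strictly below
#' \code{minArea}; components of exactly \code{minArea} pixels are kept.
#'
#' @param mask binary matrix.
#' @param minArea area threshold in pixels (S1 = 100 for the nucleus mask,
#'   S2 = 350 for the cell mask at working scale).
#' @return binary integer matrix.
#' @export
denoiseSmall <- function(mask, minArea) {
  stopifnot(minArea >= 0)
  m <- binMat(mask)
  if (minArea == 0 || !any(m > 0)) return(m)
  lab <- .cpp_label(m, 4L)
  if (max(lab) == 0) return(m)
  areas <- tabulate(lab[lab > 0], max(lab))
  drop <- which(areas < minArea)
  if (length(drop)) m[lab %in% drop] <- 0L
  m
}

#' Binary morphological reconstruction
#'
#' Returns the union of the 4-connected components of \code{mask} that
#' intersect \code{marker} (equivalently, conditional dilation of the marker
#' inside the mask iterated to stability). A marker poking outside the mask
#' is clipped first, so a nucleus seed overhanging a watershed-trimmed cell
#' boundary by a pixel still selects its component.
#'
#' @param marker,mask binary matrices of identical shape.
#' @return binary integer matrix, a subset of \code{mask}.
#' @export
reconstructMask <- function(marker, mask) {
  marker <- binMat(marker); mask <- binMat(mask)
  if (!identical(dim(marker), dim(mask)))
    stop("reconstructMask: marker and mask must share one shape")
  marker <- marker * mask  # clip
  if (!any(marker > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- .cpp_label(mask, 4L)
  keep <- unique(lab[marker > 0])
  keep <- keep[keep > 0]
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab %in% keep] <- 1L
  out
}

#' Region features by chain-code boundary tracing
#'
#' One record per label: pixel area, chain-code perimeter (8-directional
#' boundary tracing, diagonal steps weighted sqrt(2); an isolated pixel
#' counts 1), bounding-box height and width, the roundness (compactness)
#' perimeter^2 / (4 pi area) which is ~1 for a disk and grows with shape
#' irregularity, and the area-weighted centroid (cx = column, cy = row,
#' 1-based pixel centers). Labels that are not 4-connected (watershed
#' output) have the perimeters of their pieces summed.
#'
#' @param labels integer label matrix.
#' @return \code{data.frame} with columns label, area, perimeter, height,
#'   width, roundness, cx, cy.
#' @export
regionProps <- function(labels) {
  labels <- storageInt(labels)
  k <- max(0L, labels)
  if (k == 0L)
    return(data.frame(label = integer(), area = integer(),
                      perimeter = numeric(), height = integer(),
                      width = integer(), roundness = numeric(),
                      cx = numeric(), cy = numeric()))
  idx <- which(labels > 0)
  lb <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  area <- tabulate(lb, k)
  present <- which(area > 0)
  per <- .cpp_chain_perimeter(labels, k)
  cy <- rowsum(as.numeric(rows), lb)[, 1] / area[present]
  cx <- rowsum(as.numeric(cols), lb)[, 1] / area[present]
  hh <- tapply(rows, lb, function(x) diff(range(x)) + 1L)
  ww <- tapply(cols, lb, function(x) diff(range(x)) + 1L)
  data.frame(label = present, area = area[present],
             perimeter = per[present],
             height = as.integer(hh), width = as.integer(ww),
             roundness = per[present]^2 / (4 * pi * area[present]),
             cx = cx, cy = cy, row.names = NULL)
}

#' Binary erosion and dilation by a disk
#'
#' Disk structuring element of the given radius (a radius-1 disk is the
#' 4-neighbourhood cross).
#'
#' @param mask binary matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return binary integer matrix.
#' @export
binaryErode <- function(mask, radius = 3) {
  stopifnot(radius >= 1)
  m <- binMat(mask)
  storageInt(EBImage::erode(m, EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")))
}

#' @rdname binaryErode
#' @export
binaryDilate <- function(mask, radius = 3) {
  stopifnot(radius >= 1)
  m <- binMat(mask)
  storageInt(EBImage::dilate(m, EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")))
}

#' @rdname binaryErode
#' @export
binaryOpen <- function(mask, radius = 3) {
  binaryDilate(binaryErode(mask, radius), radius)
}

#' @rdname binaryErode
#' @export
binaryClose <- function(mask, radius = 3) {
  binaryErode(binaryDilate(mask, radius), radius)
}

# open-and-close boundary repair: thresholded masks carry pixel-noise
# jaggedness that inflates chain-code perimeters (and therefore roundness)
# and sheds specks under corrosion; closing fills boundary dents, opening
# shaves spikes
morphSmooth <- function(mask, radius) {
  if (!any(mask > 0)) return(binMat(mask))
  binaryOpen(binaryClose(mask, radius), radius)
}

#' Fill enclosed background holes
#'
#' Sets to foreground every background region not connected to the image
#' border. Used after the two whole-cell masks are unioned, where a nucleus
#' darker than its cytoplasm can leave a hole.
#'
#' @param mask binary matrix.
#' @return binary integer matrix.
#' @export
fillHoles <- function(mask) {
  storageInt(EBImage::fillHull(binMat(mask)))
}

#' Euclidean distance transform
#'
#' Distance from every foreground pixel to the nearest background pixel
#' (thin wrapper over \code{EBImage::distmap}).
#'
#' @param mask binary matrix.
#' @return numeric matrix of distances, 0 on the background.
#' @export
distanceTransform <- function(mask) {
  m <- binMat(mask)
  if (!any(m > 0)) return(matrix(0, nrow(m), ncol(m)))
  if (!any(m == 0)) { # distmap needs at least one background pixel
    out <- matrix(Inf, nrow(m), ncol(m))
    return(out)
  }
  unclass(EBImage::distmap(m, "euclidean"))
}

binMat <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask)) stop("expected a matrix mask")
  m <- storageInt((mask != 0) * 1L)
  m
}

storageInt <- function(m) {
  storage.mode(m) <- "integer"
  m
}
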