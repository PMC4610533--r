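#' Read and write smear images and label masks
#'
#' \code{readSmear} loads an 8-bit RGB PNG/TIFF/JPEG as an integer
#' H x W x 3 array with values 0-255 (row = y, column = x).
#' \code{writeSmear} writes such an array back. Label masks travel as
#' single-channel images via \code{writeLabelMask} / \code{readLabelMask}:
#' 16-bit TIFF, or 8-bit PNG when there are fewer than 256 labels.
#'
#' @param path image file path.
#' @param image integer RGB array (0-255).
#' @param labels integer label matrix (values below 65536).
#' @return \code{readSmear}: integer array; \code{readLabelMask}: integer
#'   matrix; the writers invisibly return \code{path}.
#' @export
readSmear <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2)
    stop("readSmear: expected a 3-channel RGB image")
  if (d[3] > 3) img <- img[, , 1:3]  # drop alpha
  if (d[3] < 3)
    stop("readSmear: expected a 3-channel RGB image")
  # EBImage stores (x, y, c); transpose to (row = y, col = x)
  out <- aperm(EBImage::imageData(img), c(2, 1, 3))
  out <- round(out * 255)
  storage.mode(out) <- "integer"
  checkRGB(out)
}

#' @rdname readSmear
#' @export
writeSmear <- function(image, path) {
  image <- checkRGB(image)
  img <- EBImage::Image(aperm(image / 255, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @rdname readSmear
#' @export
writeLabelMask <- function(labels, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stopifnot(max(labels) < 65536)
    EBImage::writeImage(EBImage::Image(t(labels) / 65535), path,
                        bits.per.sample = 16L)
  } else {
    # the PNG writer emits 8 bits per sample
    stopifnot(max(labels) < 256)
    EBImage::writeImage(EBImage::Image(t(labels) / 255), path)
  }
  invisible(path)
}

#' @rdname readSmear
#' @export
readLabelMask <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3) img <- img[, , 1]
  scale <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) 65535 else 255
  storageInt(round(t(img) * scale))
}

#' Draw segmentation contours on an image
#'
#' Marks the boundary pixels of every labeled region in red, mirroring the
#' usual presentation of smear segmentations.
#'
#' @param image integer RGB array (0-255).
#' @param labels integer label matrix of the same height/width.
#' @param color RGB triple for the contour.
#' @return integer RGB array with contours burned in.
#' @export
overlayContours <- function(image, labels, color = c(255, 0, 0)) {
  image <- checkRGB(image)
  stopifnot(identical(dim(image)[1:2], dim(labels)))
  h <- nrow(labels); w <- ncol(labels)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- labels
  ctr <- pad[2:(h + 1), 2:(w + 1)]
  edge <- ctr > 0 & (
    pad[1:h, 2:(w + 1)] != ctr | pad[3:(h + 2), 2:(w + 1)] != ctr |
    pad[2:(h + 1), 1:w] != ctr | pad[2:(h + 1), 3:(w + 2)] != ctr)
  out <- image
  for (c3 in 1:3) {
    pl <- out[, , c3]
    pl[edge] <- color[c3]
    out[, , c3] <- pl
  }
  storage.mode(out) <- "integer"
  out
}

#' Write a synthetic scene to disk
#'
#' Writes the rendered image, both ground-truth label masks and a JSON-free
#' YAML sidecar of the scene description, so batches can be regenerated and
#' consumed by the command-line tools.
#'
#' @param scene a \linkS4class{SyntheticSmear}.
#' @param dir output directory.
#' @param stem file name stem.
#' @return invisibly, the paths written.
#' @export
writeScene <- function(scene, dir, stem = "scene") {
  stopifnot(is(scene, "SyntheticSmear"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, paste0(stem, ".png"))
  p2 <- file.path(dir, paste0(stem, "_wbc_truth.tif"))
  p3 <- file.path(dir, paste0(stem, "_nucleus_truth.tif"))
  p4 <- file.path(dir, paste0(stem, "_scene.yaml"))
  writeSmear(smearImage(scene), p1)
  writeLabelMask(wbcLabels(scene), p2)
  writeLabelMask(nucleusLabels(scene), p3)
  yaml::write_yaml(scene@spec, p4)
  invisible(c(p1, p2, p3, p4))
}
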