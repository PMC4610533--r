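#' Color-space conversions and ratio enhancement
#'
#' The stain signal of a blood smear is carried by channel ratios rather
#' than absolute intensities, which makes these planes robust to the
#' multiplicative illumination differences between microscopes.
#' \code{rgbToChroma} maps an RGB image to the rg chromaticity space
#' (r = R/(R+G+B), g = G/(R+G+B), b = 1 - r - g); \code{rgbSaturation}
#' extracts the HSI saturation S = 1 - 3 min(R,G,B)/(R+G+B); and
#' \code{rgbCyanChannel} the cyan fraction of the CMYK decomposition, which
#' is high on the purple-blue stained cell regions and essentially zero on
#' the pale background and the reddish red cells.
#'
#' Pixels with R+G+B = 0 are achromatic: their chromaticity is set to
#' (1/3, 1/3, 1/3) and their saturation to 0.
#'
#' @param image integer-valued H x W x 3 array with values in [0, 255].
#' @param naive if \code{TRUE}, use the naive cyan C = 1 - R/255 instead of
#'   the key-extraction form C = (1 - R' - K)/(1 - K), K = 1 - max(R',G',B').
#' @return \code{rgbToChroma}: an H x W x 3 array of chromaticities in
#'   [0, 1] summing to 1 per pixel; the others: an H x W matrix in [0, 1].
#' @examples
#' px <- array(c(100, 50, 50), c(1, 1, 3))
#' rgbSaturation(px)          # 1 - 3*50/200 = 0.25
#' rgbToChroma(px)[1, 1, ]    # (0.5, 0.25, 0.25)
#' @export
rgbToChroma <- function(image) {
  image <- checkRGB(image)
  s <- image[, , 1] + image[, , 2] + image[, , 3]
  zero <- s <= 0
  s[zero] <- 1
  r <- image[, , 1] / s
  g <- image[, , 2] / s
  b <- image[, , 3] / s
  r[zero] <- 1 / 3
  g[zero] <- 1 / 3
  b[zero] <- 1 / 3
  out <- array(0, c(dim(image)[1:2], 3),
               dimnames = list(NULL, NULL, c("r", "g", "b")))
  out[, , 1] <- r
  out[, , 2] <- g
  out[, , 3] <- b
  out
}

#' @rdname rgbToChroma
#' @export
rgbSaturation <- function(image) {
  image <- checkRGB(image)
  s <- image[, , 1] + image[, , 2] + image[, , 3]
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  out <- ifelse(s > 0, 1 - 3 * mn / pmax(s, 1), 0)
  matrix(out, dim(image)[1], dim(image)[2])
}

#' @rdname rgbToChroma
#' @export
rgbCyanChannel <- function(image, naive = FALSE) {
  image <- checkRGB(image)
  rp <- image[, , 1] / 255
  if (naive)
    return(matrix(1 - rp, dim(image)[1], dim(image)[2]))
  mx <- pmax(rp, image[, , 2] / 255, image[, , 3] / 255)
  k <- 1 - mx
  out <- ifelse(k < 1, (1 - rp - k) / (1 - k), 0)
  matrix(out, dim(image)[1], dim(image)[2])
}

#' Rescale a plane to the 0-255 byte range
#'
#' Affine min-max normalization \code{(x - min) * 255 / (max - min)}. A
#' constant plane maps to all zeros (degenerate range).
#'
#' @param plane numeric matrix.
#' @return numeric matrix spanning [0, 255] (or all zeros).
#' @examples
#' normalizePlane(matrix(c(0.2, 0.3, 0.4), 1))  # 0, 127.5, 255
#' @export
normalizePlane <- function(plane) {
  stopifnot(is.matrix(plane), length(plane) > 0)
  rg <- range(plane)
  if (rg[1] == rg[2]) return(matrix(0, nrow(plane), ncol(plane)))
  (plane - rg[1]) * 255 / (rg[2] - rg[1])
}

#' Pixelwise ratio enhancement of two planes
#'
#' Computes \code{numerator / denominator} where the denominator is
#' positive and 0 elsewhere. Applied to normalized saturation over
#' normalized g-chromaticity it amplifies the nucleus; applied to b over g
#' chromaticity it amplifies the whole cell.
#'
#' @param numerator,denominator numeric matrices of identical shape.
#' @return non-negative numeric matrix on a ratio scale.
#' @export
ratioEnhance <- function(numerator, denominator) {
  if (!identical(dim(numerator), dim(denominator)))
    stop("ratioEnhance: planes must share one shape")
  out <- matrix(0, nrow(numerator), ncol(numerator))
  ok <- denominator > 0
  out[ok] <- numerator[ok] / denominator[ok]
  out
}

# Winsorise the upper tail of a ratio plane: values above the given quantile
# of the positive values are clipped to it. Rank-preserving below the clip
# point, so rank-based thresholds are unaffected; protects min-max rescaling
# from near-zero denominators.
clipRatioTail <- function(plane, quantile = 0.995) {
  pos <- plane[plane > 0]
  if (!length(pos) || quantile >= 1) return(plane)
  q <- stats::quantile(pos, quantile, names = FALSE)
  pmin(plane, q)
}

# Validate an RGB array: numeric H x W x 3, values in [0, 255].
checkRGB <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("expected an H x W x 3 RGB array")
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop("RGB values must lie in [0, 255]")
  image
}
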