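#' Stain palettes for synthetic smears
#'
#' RGB triples emulating a Wright-stained smear: pale background, reddish
#' anucleate red cells, lilac cytoplasm and a dark purple nucleus. The
#' marrow palette moves the cytoplasm tint closer to the nucleus, mimicking
#' the weaker nucleus/cytoplasm contrast of leukemic marrow cells. The
#' colors satisfy the orderings the segmentation method relies on: the
#' nucleus has the highest saturation and the lowest g chromaticity, cyan
#' decreases from nucleus over cytoplasm to (zero on) red cells and
#' background, and cell pixels have a higher b/g chromaticity ratio than
#' red cells and background.
#'
#' @param smearType \code{"peripheral"} or \code{"marrow"}.
#' @return named list of RGB triples
#'   (\code{background}, \code{rbc}, \code{cytoplasm}, \code{nucleus}).
#' @export
smearPalette <- function(smearType = c("peripheral", "marrow")) {
  smearType <- match.arg(smearType)
  list(background = c(232, 228, 224),
       rbc        = c(217, 136, 128),
       cytoplasm  = if (smearType == "peripheral") c(180, 160, 200)
                    else c(150, 120, 180),
       nucleus    = c(91, 44, 111))
}

#' Generate a synthetic stained-smear scene with ground truth
#'
#' Renders white blood cells (elliptical cytoplasm containing one or more
#' nucleus lobes), anucleate red cell disks and a pale background, then
#' applies a global multiplicative illumination factor and additive
#' Gaussian noise. Cell geometry is drawn at the 0.2x working scale of 100x
#' micrographs: isolated cell radii default to 14-30 px (areas roughly
#' 600-2800 px) and cells placed in adhesive clusters to 24-32 px
#' (monocyte/blast-sized, so a two-cell cluster exceeds the adhesion area
#' threshold). Nucleus area is cell area divided by the smear-type ratio N.
#' Ground-truth labels are pixel-exact; contested overlap pixels belong to
#' the cell drawn later except that every nucleus pixel belongs to its own
#' cell.
#'
#' @param imageSize \code{c(height, width)} in pixels.
#' @param nWbc,nRbc cell counts.
#' @param overlapFraction share of WBCs placed in touching/overlapping
#'   clusters (clusters of 2-3 cells are formed until the share is used up).
#' @param lobesRange integer range of nucleus lobes per cell; lobes are only
#'   used when each lobe's area stays in the single-core pairing range.
#' @param illumination global multiplicative factor in (0, 1].
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; scenes are bit-reproducible for a fixed seed.
#' @param smearType \code{"peripheral"} or \code{"marrow"}; sets the
#'   nucleus size ratio and the default palette.
#' @param palette stain palette, see \code{\link{smearPalette}}.
#' @param wbcRadiusRange,clusterRadiusRange radius ranges (px) for isolated
#'   and clustered cells.
#' @param rbcRadiusRange radius range for red cells.
#' @param cellClearance minimum boundary-to-boundary distance (px) between
#'   cells that are not cluster mates (default 55). Smear fields suitable
#'   for differential counting are sparse, and the lobe-pairing geometry of
#'   the method assumes that nuclei of distinct cells sit farther apart
#'   than the core-gap threshold.
#' @param mergedNuclei if \code{TRUE}, the nuclei of one adjacent pair in
#'   each cluster are pushed together until they touch, producing a merged
#'   nucleus seed that forces the second watershed pass.
#' @param maxTries placement retries before declaring the packing
#'   infeasible.
#' @return a \linkS4class{SyntheticSmear}.
#' @examples
#' sc <- makeSmear(imageSize = c(128, 160), nWbc = 1, nRbc = 10, seed = 1)
#' max(wbcLabels(sc))  # 1
#' @export
makeSmear <- function(imageSize = c(300, 400), nWbc = 4, nRbc = 60,
                      overlapFraction = 0, lobesRange = c(1, 1),
                      illumination = 1, noiseSd = 4, seed = 1,
                      smearType = c("peripheral", "marrow"),
                      palette = smearPalette(smearType),
                      wbcRadiusRange = c(14, 30),
                      clusterRadiusRange = c(24, 32),
                      rbcRadiusRange = c(8, 12), cellClearance = 55,
                      mergedNuclei = FALSE, maxTries = 60) {
  smearType <- match.arg(smearType)
  stopifnot(nWbc >= 0, nRbc >= 0, overlapFraction >= 0, overlapFraction <= 1,
            illumination > 0, illumination <= 1, noiseSd >= 0)
  h <- imageSize[1]; w <- imageSize[2]
  oldSeed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv()),
    add = TRUE)
  set.seed(seed)
  nratio <- if (smearType == "peripheral") 3 else 1.5

  cells <- NULL
  for (attempt in seq_len(maxTries)) {
    cells <- try(placeCells(h, w, nWbc, overlapFraction,
                            wbcRadiusRange, clusterRadiusRange,
                            cellClearance), silent = TRUE)
    if (!inherits(cells, "try-error")) break
  }
  if (inherits(cells, "try-error") || is.null(cells))
    stop("makeSmear: infeasible packing for the requested scene")

  # nucleus geometry
  cells$nucleusRadius <- cells$radius / sqrt(nratio)
  cells$lobes <- rep(1L, nrow(cells))
  nucGeom <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- if (lobesRange[2] > 1) sample(lobesRange[1]:lobesRange[2], 1) else 1L
    rn <- cells$nucleusRadius[i]
    if (k > 1) {
      lobeArea <- pi * rn^2 / k
      if (lobeArea < 130 || lobeArea > 900) k <- 1L
    }
    cells$lobes[i] <- k
    nucGeom[[i]] <- placeLobes(cells$cx[i], cells$cy[i], cells$radius[i], rn, k)
  }
  # keep nuclei of cluster mates from touching: a cell's nucleus may sit
  # anywhere inside its cytoplasm, so conflicting single-lobe nuclei are
  # pushed apart along the line joining them
  for (cl in setdiff(unique(cells$cluster), 0L)) {
    idx <- which(cells$cluster == cl)
    if (length(idx) < 2) next
    for (rep in 1:4) {
      moved <- FALSE
      pr <- utils::combn(idx, 2)
      for (q in seq_len(ncol(pr))) {
        i1 <- pr[1, q]; i2 <- pr[2, q]
        g1 <- nucGeom[[i1]]; g2 <- nucGeom[[i2]]
        if (nrow(g1) > 1 || nrow(g2) > 1) next
        need <- g1$r + g2$r + 3
        dx <- g2$x - g1$x; dy <- g2$y - g1$y
        d <- sqrt(dx^2 + dy^2)
        if (d >= need) next
        if (d == 0) { dx <- 1; dy <- 0; d <- 1 }
        ux <- dx / d; uy <- dy / d
        for (s in c(-1, 1)) {
          ii <- if (s < 0) i1 else i2
          gi <- nucGeom[[ii]]
          maxOff <- 0.92 * cells$radius[ii] - gi$r
          shift <- (need - d) / 2
          nx <- gi$x + s * ux * shift; ny <- gi$y + s * uy * shift
          off <- sqrt((nx - cells$cx[ii])^2 + (ny - cells$cy[ii])^2)
          if (off > maxOff && off > 0) {
            nx <- cells$cx[ii] + (nx - cells$cx[ii]) * maxOff / off
            ny <- cells$cy[ii] + (ny - cells$cy[ii]) * maxOff / off
          }
          nucGeom[[ii]]$x <- nx; nucGeom[[ii]]$y <- ny
        }
        moved <- TRUE
      }
      if (!moved) break
    }
  }
  if (mergedNuclei) {
    for (cl in setdiff(unique(cells$cluster), 0L)) {
      idx <- which(cells$cluster == cl)
      if (length(idx) < 2) next
      # pick the closest pair and slide their (single-lobe) nuclei together
      pr <- utils::combn(idx, 2)
      dd <- apply(pr, 2, function(p)
        sqrt((cells$cx[p[1]] - cells$cx[p[2]])^2 +
             (cells$cy[p[1]] - cells$cy[p[2]])^2))
      p <- pr[, which.min(dd)]
      mx <- mean(cells$cx[p]); my <- mean(cells$cy[p])
      for (q in p) {
        rn <- cells$nucleusRadius[q]
        ux <- cells$cx[q] - mx; uy <- cells$cy[q] - my
        nrm <- sqrt(ux^2 + uy^2); if (nrm == 0) { ux <- 1; uy <- 0; nrm <- 1 }
        nucGeom[[q]] <- data.frame(x = mx + ux / nrm * (rn - 2),
                                   y = my + uy / nrm * (rn - 2), r = rn)
        cells$lobes[q] <- 1L
      }
    }
  }

  # render ---------------------------------------------------------------
  jit <- function(col) pmin(255, pmax(0, col + round(stats::rnorm(3, 0, 3))))
  chan <- lapply(palette$background, function(v) matrix(as.numeric(v), h, w))
  wbcLab <- matrix(0L, h, w)
  nucLab <- matrix(0L, h, w)

  if (nRbc > 0) {
    rr <- stats::runif(nRbc, rbcRadiusRange[1], rbcRadiusRange[2])
    placedR <- 0
    for (i in seq_len(nRbc)) {
      ok <- FALSE
      for (t in seq_len(80)) {
        x <- stats::runif(1, rr[i] + 1, w - rr[i])
        y <- stats::runif(1, rr[i] + 1, h - rr[i])
        if (nrow(cells) == 0 ||
            all(sqrt((cells$cx - x)^2 + (cells$cy - y)^2) >
                cells$radius + rr[i] + 1)) { ok <- TRUE; break }
      }
      if (!ok) next
      px <- diskPixels(h, w, x, y, rr[i])
      col <- jit(palette$rbc)
      for (c3 in 1:3) chan[[c3]][px] <- col[c3]
      placedR <- placedR + 1
    }
  }

  for (i in seq_len(nrow(cells))) {
    px <- ellipsePixels(h, w, cells$cx[i], cells$cy[i],
                        cells$a[i], cells$b[i], cells$angle[i])
    col <- jit(palette$cytoplasm)
    for (c3 in 1:3) chan[[c3]][px] <- col[c3]
    wbcLab[px] <- i
  }
  for (i in seq_len(nrow(cells))) {
    g <- nucGeom[[i]]
    col <- jit(palette$nucleus)
    for (j in seq_len(nrow(g))) {
      px <- diskPixels(h, w, g$x[j], g$y[j], g$r[j])
      for (c3 in 1:3) chan[[c3]][px] <- col[c3]
      nucLab[px] <- i
      wbcLab[px] <- i  # a nucleus always belongs to its own cell
    }
  }

  img <- array(0, c(h, w, 3))
  for (c3 in 1:3) {
    v <- chan[[c3]] * illumination
    if (noiseSd > 0) v <- v + stats::rnorm(h * w, 0, noiseSd)
    img[, , c3] <- pmin(255, pmax(0, round(v)))
  }
  storage.mode(img) <- "integer"

  cells$nucleusRadius <- round(cells$nucleusRadius, 2)
  spec <- list(imageSize = imageSize, nWbc = nWbc, nRbc = nRbc,
               overlapFraction = overlapFraction, lobesRange = lobesRange,
               illumination = illumination, noiseSd = noiseSd, seed = seed,
               smearType = smearType, mergedNuclei = mergedNuclei)
  new("SyntheticSmear", image = img, wbcLabels = wbcLab,
      nucleusLabels = nucLab, cells = cells, spec = spec)
}

#' Apply a global multiplicative illumination change
#'
#' Scales every channel by \code{factor} and rounds; factors are restricted
#' to (0, 1] so no clipping can occur. The rg chromaticity of the result
#' matches the original within the 2/(R+G+B) quantization bound per channel.
#'
#' @param image RGB array (0-255).
#' @param factor multiplicative factor in (0, 1].
#' @return integer RGB array.
#' @export
applyIllumination <- function(image, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop("applyIllumination: factor must be a scalar in (0, 1]")
  image <- checkRGB(image)
  out <- round(image * factor)
  storage.mode(out) <- "integer"
  out
}

# placement -----------------------------------------------------------------

placeCells <- function(h, w, nWbc, overlapFraction,
                       wbcRadiusRange, clusterRadiusRange,
                       cellClearance = 55) {
  cells <- data.frame(cell = integer(), cx = numeric(), cy = numeric(),
                      radius = numeric(), a = numeric(), b = numeric(),
                      angle = numeric(), cluster = integer())
  if (nWbc == 0) return(cells)
  nOver <- round(overlapFraction * nWbc)
  sizes <- integer()
  left <- nOver
  while (left >= 2) {
    s <- sample(2:min(3, left), 1)
    if (left - s == 1) s <- s + 1  # avoid a leftover singleton
    s <- min(s, left)
    sizes <- c(sizes, s)
    left <- left - s
  }
  nSingle <- nWbc - sum(sizes)

  addCell <- function(cells, x, y, r, cl) {
    ratio <- stats::runif(1, 0.85, 1)
    rbind(cells, data.frame(cell = nrow(cells) + 1L, cx = x, cy = y,
                            radius = r, a = r / sqrt(ratio),
                            b = r * sqrt(ratio),
                            angle = stats::runif(1, 0, pi),
                            cluster = cl))
  }
  clearOf <- function(cells, x, y, r, exceptCluster) {
    if (nrow(cells) == 0) return(TRUE)
    other <- cells$cluster != exceptCluster | cells$cluster == 0 |
      exceptCluster == 0
    if (!any(other)) return(TRUE)
    all(sqrt((cells$cx[other] - x)^2 + (cells$cy[other] - y)^2) >
          cells$radius[other] + r + cellClearance)
  }

  clId <- 0L
  for (s in sizes) {
    clId <- clId + 1L
    placedCluster <- FALSE
    for (t in seq_len(80)) {
      trial <- cells
      r1 <- stats::runif(1, clusterRadiusRange[1], clusterRadiusRange[2])
      m <- r1 + 2.2 * s * clusterRadiusRange[2] / 2
      m <- min(m, (min(h, w) - 2) / 2)
      x1 <- stats::runif(1, m, w - m); y1 <- stats::runif(1, m, h - m)
      if (!clearOf(trial, x1, y1, r1, clId)) next
      trial <- addCell(trial, x1, y1, r1, clId)
      okAll <- TRUE
      for (j in seq_len(s - 1)) {
        rj <- stats::runif(1, clusterRadiusRange[1], clusterRadiusRange[2])
        okOne <- FALSE
        for (u in seq_len(60)) {
          anchor <- which(trial$cluster == clId)
          anchor <- anchor[sample.int(length(anchor), 1)]
          d <- stats::runif(1, 0.8, 1.4) * 0.6 *
            (trial$radius[anchor] + rj)
          ang <- stats::runif(1, 0, 2 * pi)
          x <- trial$cx[anchor] + d * cos(ang)
          y <- trial$cy[anchor] + d * sin(ang)
          if (x < rj + 2 || x > w - rj - 2 || y < rj + 2 || y > h - rj - 2)
            next
          mates <- which(trial$cluster == clId)
          dm <- sqrt((trial$cx[mates] - x)^2 + (trial$cy[mates] - y)^2)
          if (any(dm < 0.5 * (trial$radius[mates] + rj))) next
          if (!clearOf(trial, x, y, rj, clId)) next
          trial <- addCell(trial, x, y, rj, clId)
          okOne <- TRUE
          break
        }
        if (!okOne) { okAll <- FALSE; break }
      }
      if (okAll) { cells <- trial; placedCluster <- TRUE; break }
    }
    if (!placedCluster) stop("cluster placement failed")
  }
  for (i in seq_len(nSingle)) {
    r <- stats::runif(1, wbcRadiusRange[1], wbcRadiusRange[2])
    ok <- FALSE
    for (t in seq_len(200)) {
      x <- stats::runif(1, r + 2, w - r - 2)
      y <- stats::runif(1, r + 2, h - r - 2)
      if (clearOf(cells, x, y, r, 0L)) { ok <- TRUE; break }
    }
    if (!ok) stop("isolated-cell placement failed")
    cells <- addCell(cells, x, y, r, 0L)
  }
  cells
}

placeLobes <- function(cx, cy, rCell, rNucleus, k) {
  if (k == 1) {
    jx <- stats::runif(1, -0.15, 0.15) * rCell
    jy <- stats::runif(1, -0.15, 0.15) * rCell
    return(data.frame(x = cx + jx, y = cy + jy, r = rNucleus))
  }
  rl <- rNucleus / sqrt(k)
  for (t in seq_len(60)) {
    g <- data.frame(x = cx + stats::runif(1, -0.2, 0.2) * rCell,
                    y = cy + stats::runif(1, -0.2, 0.2) * rCell, r = rl)
    ok <- TRUE
    for (j in seq_len(k - 1)) {
      placed <- FALSE
      for (u in seq_len(40)) {
        a <- g[sample.int(nrow(g), 1), ]
        gap <- stats::runif(1, 1, 6)
        d <- 2 * rl + gap
        ang <- stats::runif(1, 0, 2 * pi)
        x <- a$x + d * cos(ang); y <- a$y + d * sin(ang)
        if (sqrt((x - cx)^2 + (y - cy)^2) + rl > 0.92 * rCell) next
        if (any(sqrt((g$x - x)^2 + (g$y - y)^2) < 2 * rl + 0.5)) next
        g <- rbind(g, data.frame(x = x, y = y, r = rl))
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(g)
  }
  # fall back to one round nucleus
  data.frame(x = cx, y = cy, r = rNucleus)
}

# rasterization helpers ------------------------------------------------------

diskPixels <- function(h, w, cx, cy, r) {
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  inside <- outer(dy^2, dx^2, "+") <= r^2
  cbind(rep(rows, length(cols))[as.vector(inside)],
        rep(cols, each = length(rows))[as.vector(inside)])
}

ellipsePixels <- function(h, w, cx, cy, a, b, angle) {
  r <- max(a, b)
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(rep(rows, length(cols))[as.vector(inside)],
        rep(cols, each = length(rows))[as.vector(inside)])
}
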