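#' Flag adhesive (overlapping) cell clusters
#'
#' A component is adhesive when its area exceeds \code{adhesionMinArea}
#' (larger than any single cell) or its roundness passes the
#' \code{adhesionRoundness} bound, two complementary signatures of merged
#' cells. With \code{adhesionRule = "both"} both conditions are required;
#' \code{adhesionComparator} selects the direction of the roundness
#' comparison. False positives are harmless downstream: a convex component
#' with a single marker survives both watershed passes intact.
#'
#' @param props one or more rows of a \code{\link{regionProps}} table.
#' @param params \linkS4class{SegmentationParams}.
#' @return logical vector, one flag per row of \code{props}.
#' @export
detectAdhesion <- function(props, params = segmentationParams()) {
  byArea <- props$area > params@adhesionMinArea
  byRound <- if (params@adhesionComparator == "greater")
    props$roundness > params@adhesionRoundness
  else
    props$roundness < params@adhesionRoundness
  if (params@adhesionRule == "both") byArea & byRound else byArea | byRound
}

#' Marker-controlled watershed
#'
#' Floods a topographic surface inside the \code{outside} mask from the
#' marker labels: by default the negated Euclidean distance to the
#' background, so basins sit at the thick centers of cells;
#' \code{surface = "dist_to_seed"} floods the distance to the nearest
#' marker instead. Every reachable mask pixel receives the label of exactly
#' one marker; ridge ties are resolved deterministically by flood order.
#'
#' @param outside binary mask of the region to partition.
#' @param markers integer label matrix of seeds (clipped to \code{outside}).
#' @param surface \code{"dist_to_bg"} or \code{"dist_to_seed"}.
#' @return integer label matrix; mask pixels in components containing no
#'   marker remain 0.
#' @export
markedWatershed <- function(outside, markers, surface = "dist_to_bg") {
  outside <- binMat(outside)
  markers <- storageInt(markers) * outside
  if (!any(markers > 0))
    stop("markedWatershed: no marker inside the mask")
  surf <- if (surface == "dist_to_seed") {
    distanceTransform(markers == 0)
  } else {
    -distanceTransform(outside)
  }
  .cpp_marked_watershed(surf, markers, outside > 0)
}

#' Split one adhesive region in the second pass
#'
#' Used when the first watershed pass could not separate a cluster. When the
#' cluster's merged nucleus group is supplied as \code{seedMask} it is
#' corroded first (distance-map superlevel sets until it falls into at
#' least two cores): merged nuclei overlap only slightly, so their waist is
#' deep and the cores it yields are reliable watershed seeds for the cell
#' region. Without a usable seed the region's own shape is used:
#' local-extremum regions are
#' the connected components of \{distance-to-background >= extremumRadius\};
#' if at least two exist they seed a watershed of the region. A marker in
#' any path must be core-like (at least 25 px and a tenth of the largest
#' core), which keeps boundary-noise fragments from seeding spurious
#' basins. Otherwise the
#' region is eroded by a disk of growing integer radius -- realized exactly
#' as the superlevel sets of the Euclidean distance map, so the narrow
#' depth window between the waist saddle and the lobe peaks cannot be
#' skipped by a metric approximation -- until its component count
#' increases (the eroded components become the seeds) or the next step
#' would empty it, in which case the region is returned unsplit.
#'
#' @param region binary mask of a single 4-connected component.
#' @param params \linkS4class{SegmentationParams}.
#' @param seedMask optional binary mask of the (merged) nucleus group
#'   inside the region.
#' @return integer label matrix covering \code{region}; the attribute
#'   \code{"how"} records the path taken (\code{"seed"},
#'   \code{"extremum"}, \code{"erosion"} or \code{"unsplit"}).
#' @export
adaptiveSplit <- function(region, params = segmentationParams(),
                          seedMask = NULL) {
  region <- binMat(region)
  if (!is.null(seedMask)) {
    seedMask <- binMat(seedMask) * region
    if (any(seedMask > 0)) {
      mk <- corrodeIntoCores(seedMask)
      if (!is.null(mk)) {
        out <- markedWatershed(region, mk, params@watershedSurface)
        attr(out, "how") <- "seed"
        return(out)
      }
    }
  }
  d <- distanceTransform(region)
  ext <- (d >= params@extremumRadius) * 1L
  markers <- dropNonCores(connectedComponents(ext, 4))
  how <- "extremum"
  if (countLabels(markers) < 2) {
    how <- "erosion"
    markers <- corrodeIntoCores(region)
    if (is.null(markers)) {
      out <- region
      attr(out, "how") <- "unsplit"
      return(out)
    }
  }
  out <- markedWatershed(region, markers, params@watershedSurface)
  attr(out, "how") <- how
  out
}

# corrode a mask through the superlevel sets of its distance map until it
# falls apart into >= 2 cores; NULL when it never does
corrodeIntoCores <- function(mask) {
  d <- distanceTransform(mask)
  for (t in seq_len(ceiling(max(d)))) {
    lab <- dropNonCores(connectedComponents((d >= t) * 1L, 4))
    if (countLabels(lab) > 1) return(lab)
  }
  NULL
}

# a watershed marker must look like a cell core, not boundary noise: at
# least 25 px and at least a tenth of the largest core at the same depth
# (thresholded masks shed small boundary fragments under corrosion)
dropNonCores <- function(labels) {
  k <- max(0L, labels)
  if (k == 0L) return(labels)
  areas <- tabulate(labels[labels > 0], k)
  floorA <- max(25, 0.1 * max(areas))
  drop <- which(areas > 0 & areas < floorA)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

countLabels <- function(labels) length(setdiff(unique(as.vector(labels)), 0L))

#' Separate adhesive white blood cells (nucleus-marked watershed)
#'
#' Phase III. Adhesion of a cell-mask component is decided from three
#' complementary signals: the area/roundness rule of
#' \code{\link{detectAdhesion}}, the presence of two or more nucleus seeds
#' inside one component (one cell carries one nucleus group), and a nucleus
#' seed that is itself adhesive (roundness above
#' \code{nucleusAdhesionRoundness}, the signature of merged nuclei of
#' distinct cells). If no component is adhesive the 4-connected components
#' are returned directly. Otherwise a first watershed pass seeds every
#' component with its nucleus groups; basins still adhesive after that pass
#' go through \code{\link{adaptiveSplit}}. Components without any nucleus
#' seed are kept and labeled (post-processing removes them). Labels are
#' compacted to 1..K in raster order.
#'
#' @param outside binary whole-cell mask (the outside seeds).
#' @param inside binary nucleus-group mask (the inside seeds).
#' @param params \linkS4class{SegmentationParams}.
#' @param connectedSeeds optional binary mask of the pixels added by the
#'   centroid-connected operation. A seed containing such pixels was
#'   assembled from lobes the connection step already declared one nucleus
#'   group, so its (rectangular, high-roundness) shape is exempt from the
#'   merged-nucleus trigger; clusters whose nuclei were joined across cells
#'   are still caught by the region area rule.
#' @return integer label matrix with attribute \code{"provenance"}: per
#'   label \code{"single"}, \code{"split_pass1"} or \code{"split_pass2"}.
#' @export
separateWbcs <- function(outside, inside, params = segmentationParams(),
                         connectedSeeds = NULL) {
  outside <- binMat(outside)
  inside <- binMat(inside) * outside
  if (is.null(connectedSeeds))
    connectedSeeds <- matrix(0L, nrow(outside), ncol(outside))
  connectedSeeds <- binMat(connectedSeeds)
  comp <- connectedComponents(outside, 4)
  prp <- regionProps(comp)
  if (nrow(prp) == 0) {
    attr(comp, "provenance") <- character()
    return(comp)
  }
  markers <- connectedComponents(inside, 4)
  markProps <- regionProps(markers)
  # seeds assembled by centroid connection carry rectangle pixels; a merged
  # nucleus must also be bigger than a single core, which keeps naturally
  # fused lobes of one segmented nucleus from looking adhesive
  exempt <- vapply(markProps$label, function(m)
    any(connectedSeeds[markers == m] > 0), logical(1)) |
    markProps$area <= params@coreAreaRange[2]
  markRound <- ifelse(exempt, 0, markProps$roundness)
  # which cell component holds each nucleus seed
  markComp <- vapply(markProps$label, function(m)
    comp[which(markers == m)[1]], integer(1))
  nSeeds <- tabulate(markComp, nrow(prp))[prp$label]
  seedRound <- rep(0, nrow(prp))
  one <- which(nSeeds == 1)
  for (i in one)
    seedRound[i] <- markRound[markComp == prp$label[i]][1]
  adhesive <- detectAdhesion(prp, params) | nSeeds >= 2 |
    seedRound > params@nucleusAdhesionRoundness
  if (!any(adhesive)) {
    attr(comp, "provenance") <- rep("single", nrow(prp))
    return(comp)
  }
  # pass 1: flood from the nucleus groups
  if (max(markers) > 0) {
    w <- markedWatershed(outside, markers, params@watershedSurface)
  } else {
    w <- matrix(0L, nrow(outside), ncol(outside))
  }
  # seedless components survive as themselves (flagged; post-processing
  # removes them if they never acquire a nucleus)
  seedless <- outside > 0 & w == 0
  if (any(seedless)) {
    extra <- connectedComponents(seedless * 1L, 4)
    pos <- extra > 0
    w[pos] <- as.integer(max(w) + extra[pos])
  }
  adhesiveComp <- prp$label[adhesive]
  prov <- vapply(seq_len(max(0L, w)), function(lb) {
    pix <- which(w == lb)[1]
    if (is.na(pix)) return(NA_character_)
    if (comp[pix] %in% adhesiveComp) "split_pass1" else "single"
  }, character(1))
  # pass 2: re-test per basin and split the adhesive survivors; a basin is
  # re-tested when the area/roundness rule fires or its nucleus seed looks
  # merged
  prp1 <- regionProps(w)
  seedRound1 <- vapply(prp1$label, function(lb) {
    ms <- unique(markers[w == lb & markers > 0])
    if (!length(ms)) return(0)
    max(markRound[markProps$label %in% ms])
  }, numeric(1))
  redo <- prp1$label[detectAdhesion(prp1, params) |
                     seedRound1 > params@nucleusAdhesionRoundness]
  for (lb in redo) {
    piece <- (w == lb) * 1L
    # the basin's nucleus group is the preferred marker source; when its
    # corrosion yields no cores the split falls back to the region's shape
    sp <- adaptiveSplit(piece, params, seedMask = inside * piece)
    ks <- max(0L, sp)
    if (ks > 1) {
      base <- length(prov)
      w[w == lb] <- 0L
      pos <- sp > 0
      w[pos] <- as.integer(base + sp[pos])
      prov[lb] <- NA_character_
      prov <- c(prov, rep("split_pass2", ks))
    }
  }
  # compact labels in raster order of first pixel
  idx <- which(w > 0)
  if (!length(idx)) {
    out <- matrix(0L, nrow(outside), ncol(outside))
    attr(out, "provenance") <- character()
    return(out)
  }
  first <- tapply(idx, w[idx], min)
  old <- as.integer(names(first))[order(first)]
  map <- integer(length(prov))
  map[old] <- seq_along(old)
  w[idx] <- map[w[idx]]
  w <- storageInt(w)
  attr(w, "provenance") <- prov[old]
  w
}

#' Post-processing: assign nuclei to cells and drop impurities
#'
#' A logical AND between the separated cell labels and the nucleus mask
#' gives the nucleus of each cell (splitting a merged nucleus along the
#' watershed ridge), and every cell component without a single nucleus
#' pixel - stain debris, red-cell clumps - is removed, which is the
#' morphological reconstruction of the cell mask from the nucleus marker.
#' Surviving labels are compacted and their region features computed.
#'
#' @param wbcs integer label matrix from \code{\link{separateWbcs}}.
#' @param nucleus binary nucleus mask (pre-connection).
#' @param params \linkS4class{SegmentationParams}.
#' @return a \linkS4class{SegmentationResult}.
#' @export
postprocessSegmentation <- function(wbcs, nucleus,
                                    params = segmentationParams()) {
  if (!identical(dim(wbcs), dim(nucleus)))
    stop("postprocessSegmentation: shapes differ")
  nucleus <- binMat(nucleus)
  wbcs <- storageInt(wbcs)
  prov <- attr(wbcs, "provenance")
  k <- max(0L, wbcs)
  nuc <- wbcs * nucleus
  keep <- sort(unique(nuc[nuc > 0]))
  map <- integer(max(1L, k))
  map[keep] <- seq_along(keep)
  out <- wbcs
  out[out > 0] <- map[out[out > 0]]
  nucOut <- nuc
  nucOut[nucOut > 0] <- map[nucOut[nucOut > 0]]
  prov <- if (is.null(prov) || !length(keep)) rep("single", length(keep))
          else prov[keep]
  new("SegmentationResult",
      wbcLabels = storageInt(out), nucleusLabels = storageInt(nucOut),
      props = regionProps(out), provenance = as.character(prov),
      params = params)
}
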