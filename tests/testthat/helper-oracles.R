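# Brute-force reference implementations, independent of the package's
# compiled paths. Deliberately naive: correctness over speed.

# breadth-first flood fill labeling, raster order of first pixel
floodFillOracle <- function(mask, connectivity = 4) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 4) {
    nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  k <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    k <- k + 1L
    queue <- list(c(i, j)); lab[i, j] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(nb))) {
        r <- p[1] + nb[d, 1]; cc <- p[2] + nb[d, 2]
        if (r < 1 || r > h || cc < 1 || cc > w) next
        if (mask[r, cc] != 0 && lab[r, cc] == 0) {
          lab[r, cc] <- k
          queue[[length(queue) + 1]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# per-pixel window-mean mean-shift iteration with a flat kernel
meanShiftOracle <- function(plane, hs, hr, maxIters = 4, tol = 0.5) {
  h <- nrow(plane); w <- ncol(plane)
  out <- plane
  for (i in seq_len(h)) for (j in seq_len(w)) {
    cy <- i; cx <- j; cv <- plane[i, j]
    for (it in seq_len(maxIters)) {
      rws <- max(1, ceiling(cy - hs)):min(h, floor(cy + hs))
      cls <- max(1, ceiling(cx - hs)):min(w, floor(cx + hs))
      sub <- plane[rws, cls, drop = FALSE]
      sel <- abs(sub - cv) <= hr
      k <- sum(sel)
      if (k == 0) break
      rowIdx <- matrix(rws, length(rws), length(cls))
      colIdx <- matrix(cls, length(rws), length(cls), byrow = TRUE)
      nv <- sum(sub[sel]) / k
      shift <- abs(nv - cv)
      cy <- sum(rowIdx[sel]) / k
      cx <- sum(colIdx[sel]) / k
      cv <- nv
      if (shift < tol) break
    }
    out[i, j] <- cv
  }
  out
}

# priority-flood watershed: repeatedly pop the queued pixel with the lowest
# (height, insertion order) and claim its unlabeled 4-neighbours
watershedOracle <- function(surface, markers, domain) {
  h <- nrow(surface); w <- ncol(surface)
  lab <- matrix(0L, h, w)
  qh <- numeric(); qs <- numeric(); qi <- integer(); ql <- integer()
  seq0 <- 0
  push <- function(idx, label) {
    qh[length(qh) + 1] <<- surface[idx]
    qs[length(qs) + 1] <<- seq0
    qi[length(qi) + 1] <<- idx
    ql[length(ql) + 1] <<- label
    seq0 <<- seq0 + 1
  }
  # seeds are pushed in row-major raster order, matching the flood order of
  # the implementation under test
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (domain[i, j] && markers[i, j] > 0) {
      lab[i, j] <- markers[i, j]
      push(i + (j - 1L) * h, markers[i, j])
    }
  }
  nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  while (length(qh)) {
    m <- which(qh == min(qh))
    p <- m[which.min(qs[m])]
    idx <- qi[p]; labv <- ql[p]
    qh <- qh[-p]; qs <- qs[-p]; qi <- qi[-p]; ql <- ql[-p]
    r <- (idx - 1L) %% h + 1L
    cc <- (idx - 1L) %/% h + 1L
    for (d in 1:4) {
      rr <- r + nb[d, 1]; c2 <- cc + nb[d, 2]
      if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
      if (!domain[rr, c2] || lab[rr, c2] != 0) next
      lab[rr, c2] <- labv
      push(rr + (c2 - 1L) * h, labv)
    }
  }
  lab
}

# exhaustive scan of all 256 thresholds maximizing between-class variance
otsuScanOracle <- function(plane) {
  g <- as.integer(round(pmin(pmax(plane, 0), 255)))
  n <- length(g)
  best <- -Inf; bestT <- 0L
  for (t in 0:255) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (!length(lo) || !length(hi)) next
    sb <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; bestT <- t }
  }
  bestT
}

# Moore-neighbour boundary walk, independent tracing of one 4-connected
# shape; returns the sqrt(2)-weighted chain length
chainWalkOracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  start <- NULL
  for (i in seq_len(h)) { for (j in seq_len(w)) if (mask[i, j] != 0) { start <- c(i, j); break }; if (!is.null(start)) break }
  if (is.null(start)) return(NA_real_)
  # clockwise from north
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  inside <- function(p) p[1] >= 1 && p[1] <= h && p[2] >= 1 && p[2] <= w && mask[p[1], p[2]] != 0
  cur <- start; bdir <- 7L  # backtrack = west (index 7 of dirs, 1-based)
  per <- 0; firstMove <- NA; steps <- 0
  repeat {
    found <- NA
    for (k in 1:8) {
      d <- ((bdir - 1L + k) %% 8L) + 1L
      if (inside(cur + dirs[d, ])) { found <- d; break }
    }
    if (is.na(found)) return(1)  # single pixel convention
    per <- per + if (found %% 2 == 0) sqrt(2) else 1
    prev <- ((found - 2L) %% 8L) + 1L
    bt <- cur + dirs[prev, ]
    cur <- cur + dirs[found, ]
    bdir <- NA
    for (d in 1:8) if (all(cur + dirs[d, ] == bt)) { bdir <- d; break }
    if (is.na(bdir)) bdir <- 7L
    if (is.na(firstMove)) firstMove <- found
    steps <- steps + 1
    if (all(cur == start)) {
      nxt <- NA
      for (k in 1:8) {
        d <- ((bdir - 1L + k) %% 8L) + 1L
        if (inside(cur + dirs[d, ])) { nxt <- d; break }
      }
      if (is.na(nxt) || nxt == firstMove) break
    }
    if (steps > 8 * sum(mask != 0) + 16) break
  }
  per
}

# rasterized disk mask
diskMask <- function(h, w, cy, cx, r) {
  m <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1L
  m
}

workParams <- function(smearType = "peripheral", ...) {
  segmentationParams(smearType, resizeFactor = 1, ...)
}
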