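# Independent brute-force oracles, deliberately naive implementations
# kept separate from the package's code paths.

# ray-casting point-in-polygon (crossing number)
oracleInside <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# flood-fill 8-connected component labelling (queue-based)
oracleLabel <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  k <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (mask[r0, c0] > 0 && lab[r0, c0] == 0L) {
      k <- k + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] > 0 && lab[r, c] == 0L) {
            lab[r, c] <- k
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# per-pixel loop projections
oracleProject <- function(stack, kind) {
  d <- dim(stack)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- stack[i, j, ]
    out[i, j] <- if (kind == "sum") sum(v) else max(v)
  }
  out
}

# explicit-loop region sum and mean
oracleRegionSum <- function(img, px) {
  s <- 0
  for (i in seq_len(nrow(px))) s <- s + img[px[i, 1], px[i, 2]]
  s
}

oracleRegionMean <- function(img, px) oracleRegionSum(img, px) / nrow(px)

# textbook pooled-variance unpaired t statistic
oracleT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# direct Pearson chi-square over a contingency table
oracleChi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# a small, fast configuration for unit tests (band template, one gene)
testConfig <- function(pOn = 0.5, nuclei15 = 6, cv = 0, ...) {
  generatorConfig(
    name = "unit", muscle = "TEST",
    genes = list(burstSpec("g1", pOn = pOn, intensityCV = cv)),
    geometry = list(nucleiByStage = list(`12` = 1L, `13` = 2L, `14` = 4L,
                                         `15` = as.integer(nuclei15),
                                         `16` = 6L)),
    ...)
}

# geometry with an arbitrary number of grid-placed nuclei (for state
# sampling at large n without packing costs)
gridGeometry <- function(n, stage = 15L) {
  side <- ceiling(sqrt(n))
  gx <- (seq_len(side) - 1) * 20 + 10
  gy <- (seq_len(side) - 1) * 20 + 10
  centres <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n), , drop = FALSE]
  lim <- side * 20 + 10
  poly <- cbind(x = c(0, lim, lim, 0), y = c(0, 0, lim, lim))
  new("FibreGeometry", polygon = poly, nuclei = centres,
      nucleusRadius = 6, fcIndex = 1L,
      lineage = rep("unlabelled", n), stage = as.integer(stage),
      zExtent = c(2L, 5L), nSlices = 6L,
      imageSize = c(as.integer(lim + 10), as.integer(lim + 10)))
}
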