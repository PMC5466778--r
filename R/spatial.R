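#' Compute the muscle reference frame
#'
#' Area, centroid and minimal axis-aligned bounding rectangle of a muscle
#' region, the quantities from which dot and nucleus coordinates are
#' standardised. For a mask, area is the pixel count and the centroid the
#' mean of member-pixel 0-based coordinates; for a polygon, the shoelace
#' area and polygon centroid are used and the bounding rectangle spans the
#' vertex extents.
#'
#' @param region binary/label matrix, or an n x 2 polygon vertex matrix
#'   (interpreted as a polygon when it has exactly 2 columns and is not of
#'   image size).
#' @return a \code{\link{MuscleFrame-class}}.
#' @export
computeFrame <- function(region) {
  if (is.matrix(region) && ncol(region) == 2L && nrow(region) >= 3L &&
      !all(region %in% c(0, 1))) {
    poly <- region
    n <- nrow(poly)
    xi <- poly[, 1]; yi <- poly[, 2]
    xj <- xi[c(2:n, 1)]; yj <- yi[c(2:n, 1)]
    cross <- xi * yj - xj * yi
    area <- abs(sum(cross)) / 2
    if (area <= 0) stop("degenerate polygon: zero area")
    sgn <- sum(cross) # signed, for centroid
    cx <- sum((xi + xj) * cross) / (3 * sgn)
    cy <- sum((yi + yj) * cross) / (3 * sgn)
    br <- c(min(xi), min(yi), diff(range(xi)), diff(range(yi)))
  } else {
    px <- which(region > 0, arr.ind = TRUE)
    if (nrow(px) == 0L) stop("empty region: frame undefined")
    x <- px[, 2] - 1; y <- px[, 1] - 1
    area <- nrow(px)
    cx <- mean(x); cy <- mean(y)
    br <- c(min(x), min(y), max(x) - min(x) + 1, max(y) - min(y) + 1)
  }
  new("MuscleFrame", centroid = c(x = cx, y = cy), area = area,
      boundingRect = c(x = br[1], y = br[2], width = br[3], height = br[4]))
}

#' Standardise coordinates within a muscle frame
#'
#' Centres each point on the muscle centroid with the anatomical sign flip
#' on Y (image y grows downward, dorsal is up): \code{dX = X - Xc},
#' \code{dY = -(Y - Yc)}, then scales to a fixed reference area:
#' \code{std_dX = dX * 100 / area}, \code{std_dY = dY * 100 / area}. No
#' clamping is applied. Points below the centroid in the image (larger Y)
#' get negative dY: the antero-ventral side.
#'
#' @param points n x 2 matrix or data.frame of 0-based (x, y) positions.
#' @param frame a \code{MuscleFrame}.
#' @return data.frame: x, y, dX, dY, std_dX, std_dY.
#' @export
standardizeCoords <- function(points, frame) {
  if (frameArea(frame) <= 0) stop("frame area must be positive")
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  cen <- frameCentroid(frame)
  dX <- points[, 1] - cen[1]
  dY <- -(points[, 2] - cen[2])
  data.frame(x = points[, 1], y = points[, 2], dX = unname(dX),
             dY = unname(dY),
             std_dX = unname(dX * 100 / frameArea(frame)),
             std_dY = unname(dY * 100 / frameArea(frame)))
}

SUBDOMAINS <- c("antero-ventral", "central", "postero-dorsal")

#' Classify standardised coordinates into DA3 subdomains
#'
#' Total, single-valued rule in standardised units: antero-ventral when
#' \code{std_dY < avCut} (default -1); otherwise postero-dorsal when
#' \code{std_dX > pdCut} (default +1); otherwise central. Antero-ventral
#' takes priority in the (rare) overlap, and boundary equalities fall to
#' central (strict inequalities).
#'
#' @param coords data.frame with \code{std_dX}, \code{std_dY} (from
#'   \code{\link{standardizeCoords}}).
#' @param avCut,pdCut subdomain cut-offs in standardised units.
#' @return factor with levels antero-ventral, central, postero-dorsal.
#' @export
classifySubdomain <- function(coords, avCut = -1, pdCut = 1) {
  if (avCut >= pdCut) stop("avCut must be less than pdCut")
  lab <- ifelse(coords$std_dY < avCut, SUBDOMAINS[1],
                ifelse(coords$std_dX > pdCut, SUBDOMAINS[3], SUBDOMAINS[2]))
  factor(lab, levels = SUBDOMAINS)
}

#' Subdomain repartition percentages
#'
#' @param subdomains factor from \code{\link{classifySubdomain}} (or a
#'   data.frame of coordinates, classified with default cuts).
#' @return named numeric(3) of percentages (antero-ventral, central,
#'   postero-dorsal) summing to 100, with attribute \code{n}.
#' @export
repartition <- function(subdomains) {
  if (is.data.frame(subdomains)) subdomains <- classifySubdomain(subdomains)
  if (length(subdomains) == 0L) stop("empty item list: repartition undefined")
  tab <- table(factor(subdomains, levels = SUBDOMAINS))
  out <- 100 * as.numeric(tab) / length(subdomains)
  names(out) <- SUBDOMAINS
  attr(out, "n") <- length(subdomains)
  out
}

#' Orient a fibre along the anteroposterior axis and crop
#'
#' Rotates the mask (and optionally a stack) so the fibre's principal axis
#' lies along X (anterior left), then crops to the minimal bounding
#' rectangle of the rotated mask. The rotation uses inverse
#' nearest-neighbour mapping about the mask centroid. A nearly isotropic
#' (degenerate) region yields the identity rotation with a warning.
#'
#' @param mask binary matrix.
#' @param stack optional 3-D array rotated and cropped identically.
#' @param minAnisotropy smallest principal-axis eigenvalue ratio treated as
#'   orientable.
#' @return list: \code{mask}, \code{stack} (or NULL), \code{angle} (degrees,
#'   the rotation applied to align the fibre; positive = the fibre was
#'   rotated clockwise in image coordinates), \code{offset} (0-based (x, y)
#'   of the crop origin in the rotated frame).
#' @export
orientAndCrop <- function(mask, stack = NULL, minAnisotropy = 1.05) {
  px <- which(mask > 0, arr.ind = TRUE)
  if (nrow(px) < 3) stop("mask too small to orient")
  xy <- cbind(px[, 2] - 1, px[, 1] - 1)
  cen <- colMeans(xy)
  cv <- stats::cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 0 || eg$values[1] / eg$values[2] < minAnisotropy) {
    warning("degenerate (nearly isotropic) region: identity rotation")
    theta <- 0
  } else {
    v <- eg$vectors[, 1]
    if (v[1] < 0) v <- -v # anterior (negative x) stays left
    theta <- atan2(v[2], v[1])
  }
  h <- nrow(mask); w <- ncol(mask)
  if (theta == 0) { # identity: crop without resampling
    rows <- range(px[, 1]); cols <- range(px[, 2])
    return(list(
      mask = mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
      stack = if (!is.null(stack))
        stack[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
      angle = 0, offset = c(x = cols[1] - 1, y = rows[1] - 1)))
  }
  # rotate by -theta about the centroid; output grid big enough to hold it
  dg <- ceiling(sqrt(h^2 + w^2))
  oc <- c((dg - 1) / 2, (dg - 1) / 2) # centre of output (x, y)
  grid <- cbind(x = rep(0:(dg - 1), each = dg),
                y = rep(0:(dg - 1), times = dg))
  rel <- cbind(grid[, 1] - oc[1], grid[, 2] - oc[2])
  ct <- cos(theta); st <- sin(theta)
  srcx <- cen[1] + ct * rel[, 1] - st * rel[, 2]
  srcy <- cen[2] + st * rel[, 1] + ct * rel[, 2]
  sc <- round(srcx) + 1; sr <- round(srcy) + 1
  ok <- sc >= 1 & sc <= w & sr >= 1 & sr <= h
  vals <- numeric(nrow(grid))
  vals[ok] <- mask[cbind(sr[ok], sc[ok])]
  rot <- matrix(0, dg, dg)
  rot[cbind(grid[, 2] + 1, grid[, 1] + 1)] <- vals
  rpx <- which(rot > 0, arr.ind = TRUE)
  rows <- range(rpx[, 1]); cols <- range(rpx[, 2])
  cropped <- rot[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  outStack <- NULL
  if (!is.null(stack)) {
    nz <- dim(stack)[3]
    outStack <- array(0, c(nrow(cropped), ncol(cropped), nz))
    for (z in seq_len(nz)) {
      sl <- stack[, , z]
      v <- numeric(nrow(grid))
      v[ok] <- sl[cbind(sr[ok], sc[ok])]
      rz <- matrix(0, dg, dg)
      rz[cbind(grid[, 2] + 1, grid[, 1] + 1)] <- v
      outStack[, , z] <- rz[rows[1]:rows[2], cols[1]:cols[2]]
    }
  }
  list(mask = cropped, stack = outStack,
       angle = -theta * 180 / pi,
       offset = c(x = cols[1] - 1, y = rows[1] - 1))
}
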