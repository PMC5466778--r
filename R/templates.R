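#' Muscle outline templates
#'
#' Built-in muscle outline polygons used by the generator. Coordinates are
#' 0-based pixels, origin top-left, y increasing downward; anatomical
#' anterior is left and dorsal is up.
#'
#' \describe{
#'   \item{\code{band}}{A straight horizontal band, 200 x 30 px, standing in
#'     for elongated muscles (DT1, VA2, VT1, LL1) whose exact outline does
#'     not enter any measured statistic.}
#'   \item{\code{da3_angled}}{A slanted parallelogram running from the
#'     antero-ventral (bottom-left) to the postero-dorsal (top-right) corner
#'     of the image, emulating the angled late-stage-14 DA3 shape with its
#'     transient tripartite attachment. Length 200 px, vertical rise 150 px,
#'     vertical thickness 28.2 px (area 5640 px^2). The thickness is chosen
#'     so that, for positions uniform over the radius-eroded outline, the
#'     standardised-coordinate subdomain rule yields exactly 10/70/20
#'     percent antero-ventral/central/postero-dorsal in continuous geometry
#'     (see the package vignette for the closed form).}
#' }
#'
#' @param name template name, \code{"band"} or \code{"da3_angled"}.
#' @return list with \code{polygon} (n x 2 vertex matrix, columns x, y) and
#'   \code{imageSize} (height, width) in pixels.
#' @export
muscleTemplate <- function(name = c("band", "da3_angled")) {
  name <- match.arg(name)
  if (name == "band") {
    poly <- cbind(x = c(10, 210, 210, 10), y = c(10, 10, 40, 40))
    list(polygon = poly, imageSize = c(50L, 220L))
  } else {
    # midline y(x) = 165 - 0.75 (x - 10), vertical half-thickness 14.1
    h <- 14.1
    yl <- function(x) 165 - 0.75 * (x - 10) + h
    yu <- function(x) 165 - 0.75 * (x - 10) - h
    poly <- cbind(x = c(10, 210, 210, 10),
                  y = c(yl(10), yl(210), yu(210), yu(10)))
    list(polygon = poly, imageSize = c(190L, 220L))
  }
}

#' Point-in-polygon test
#'
#' @param points n x 2 matrix (x, y).
#' @param polygon m x 2 vertex matrix (x, y), not necessarily closed.
#' @return logical vector, TRUE where the point is inside.
#' @export
pointInPolygon <- function(points, polygon) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  bnd <- rbind(polygon, polygon[1, , drop = FALSE])
  mgcv::in.out(bnd, points)
}

# Minimum distance from points to the polygon boundary (segments).
distanceToBoundary <- function(points, polygon) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  n <- nrow(polygon)
  dmin <- rep(Inf, nrow(points))
  for (i in seq_len(n)) {
    a <- polygon[i, ]
    b <- polygon[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) /
      max(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    dx <- points[, 1] - (a[1] + t * ab[1])
    dy <- points[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

# TRUE where the point lies inside the polygon at depth >= margin
# (exact erosion test for interior points).
insideEroded <- function(points, polygon, margin) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  ok <- pointInPolygon(points, polygon)
  if (margin > 0 && any(ok))
    ok[ok] <- distanceToBoundary(points[ok, , drop = FALSE], polygon) >= margin
  ok
}

#' Rasterise a polygon to a binary mask
#'
#' A pixel belongs to the mask when its centre, at 0-based integer
#' coordinates (x = column - 1, y = row - 1), lies inside the polygon.
#'
#' @param polygon n x 2 vertex matrix (x, y).
#' @param imageSize integer(2), (height, width).
#' @return binary matrix (height x width).
#' @export
rasterisePolygon <- function(polygon, imageSize) {
  h <- imageSize[1]; w <- imageSize[2]
  grid <- cbind(x = rep(0:(w - 1), each = h), y = rep(0:(h - 1), times = w))
  matrix(as.numeric(pointInPolygon(grid, polygon)), nrow = h, ncol = w)
}

# memoised rasterisation (templates recur across simulated fibres)
.maskCache <- new.env(parent = emptyenv())

cachedPolygonMask <- function(polygon, imageSize) {
  key <- paste(c(imageSize, as.vector(signif(polygon, 10))), collapse = ",")
  if (is.null(.maskCache[[key]]))
    .maskCache[[key]] <- rasterisePolygon(polygon, imageSize)
  .maskCache[[key]]
}
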