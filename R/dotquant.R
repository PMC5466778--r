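#' Project an image stack along Z
#'
#' Sum-slices projection for intensity work (integrated densities are
#' measured on it) or max-intensity projection for spatial work.
#'
#' @param stack 3-D array (height, width, slices) or a matrix (returned
#'   unchanged for \code{kind = "sum"}; a single-slice stack).
#' @param kind "sum" or "max".
#' @return matrix with attributes \code{kind} and \code{nSlices}.
#' @export
projectStack <- function(stack, kind = c("sum", "max")) {
  kind <- match.arg(kind)
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (length(dim(stack)) != 3L || any(dim(stack) == 0L))
    stop("stack must be a non-empty 3-D array")
  d <- dim(stack)
  proj <- if (kind == "sum") {
    matrix(rowSums(matrix(stack, d[1] * d[2], d[3])), d[1], d[2])
  } else {
    m <- stack[, , 1]
    for (z in seq_len(d[3])[-1]) m <- pmax(m, stack[, , z])
    m
  }
  attr(proj, "kind") <- kind
  attr(proj, "nSlices") <- dim(stack)[3]
  proj
}

#' Threshold a projection into a mask of dots
#'
#' A pixel is foreground when strictly greater than the threshold (ties at
#' the threshold are background). The threshold is an absolute value, or an
#' automatic method: \code{"otsu"} (bimodal split) or
#' \code{"background_2sd"} (median + 2 standard deviations, the permissive
#' rule used for double-FISH counting where even small/weak dots count).
#' Automatic methods fail on a constant image, where no dots are inferable.
#'
#' @param projection intensity matrix.
#' @param threshold numeric value, "otsu", or "background_2sd".
#' @return binary (0/1) matrix with attribute \code{threshold} recording the
#'   value applied.
#' @export
thresholdDots <- function(projection, threshold = "otsu") {
  if (is.character(threshold)) {
    rng <- range(projection)
    if (rng[1] == rng[2])
      stop("automatic threshold ('", threshold,
           "') on a constant image: no dots inferable (value ", rng[1], ")")
    t0 <- switch(match.arg(threshold, c("otsu", "background_2sd")),
      otsu = {
        img <- EBImage::Image((projection - rng[1]) / diff(rng))
        EBImage::otsu(img, range = c(0, 1)) * diff(rng) + rng[1]
      },
      background_2sd = stats::median(projection) + 2 * stats::sd(projection)
    )
  } else {
    t0 <- threshold
  }
  mask <- (projection > t0) * 1
  attr(mask, "threshold") <- as.numeric(t0)
  mask
}

# 8-connected labelling by iterative minimum propagation (vectorised).
labelConnected <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- mask > 0
  if (!any(fg)) return(lab)
  lab[fg] <- seq_len(sum(fg))
  big <- .Machine$integer.max
  m <- matrix(big, h, w); m[fg] <- lab[fg]
  shift <- function(x, dr, dc) {
    out <- matrix(big, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    nm <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nm <- pmin(nm, shift(m, dr, dc))
    }
    nm[!fg] <- big
    if (identical(nm, m)) break
    m <- nm
  }
  m[!fg] <- 0L
  # relabel 1..k ordered by top-most, then left-most pixel (row, then col)
  ids <- unique(m[fg])
  first <- t(vapply(ids, function(i) {
    idx <- which(m == i, arr.ind = TRUE)
    rmin <- min(idx[, 1])
    c(rmin, min(idx[idx[, 1] == rmin, 2]))
  }, c(0, 0)))
  ord <- order(first[, 1], first[, 2])
  lut <- integer(max(ids)); lut[ids[ord]] <- seq_along(ids)
  m[fg] <- lut[m[fg]]
  storage.mode(m) <- "integer"
  m
}

#' Label candidate dot regions in a mask
#'
#' Connected-component particle analysis: 8-connectivity on the projection
#' grid, components below \code{minArea} discarded. Regions are ordered
#' deterministically by their top-most, then left-most pixel.
#'
#' @param mask binary matrix (from \code{\link{thresholdDots}}).
#' @param minArea minimum component area in pixels.
#' @return list of regions; each is a list with \code{id}, \code{pixels}
#'   (n x 2 matrix of (row, col), 1-based), \code{centroid} ((x, y),
#'   0-based), \code{area}.
#' @export
labelParticles <- function(mask, minArea = 2) {
  lab <- labelConnected(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  regions <- list()
  for (i in seq_len(k)) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) < minArea) next
    regions[[length(regions) + 1]] <- list(
      id = length(regions) + 1L,
      pixels = px,
      centroid = c(x = mean(px[, 2]) - 1, y = mean(px[, 1]) - 1),
      area = nrow(px))
  }
  regions
}

#' Retain dots whose centroid lies inside the muscle mask
#'
#' The "AND" intersection between the mask of dots and the muscle mask,
#' resolved per dot by the membership of its centroid pixel so that a dot
#' straddling a muscle boundary is assigned unambiguously to one muscle.
#' Retained dots are tagged with the muscle label at their centroid.
#'
#' @param regions list of dot regions from \code{\link{labelParticles}}.
#' @param muscleMask binary or label matrix on the same grid.
#' @return the retained regions, each with an added \code{muscle} element.
#' @export
intersectWithMuscle <- function(regions, muscleMask) {
  if (length(regions)) {
    g <- regions[[1]]$pixels
    if (max(g[, 1]) > nrow(muscleMask) || max(g[, 2]) > ncol(muscleMask))
      stop("muscle mask grid does not match the dot grid")
  }
  keep <- list()
  for (r in regions) {
    row <- round(r$centroid["y"]) + 1
    col <- round(r$centroid["x"]) + 1
    if (row < 1 || row > nrow(muscleMask) ||
        col < 1 || col > ncol(muscleMask)) next
    lbl <- muscleMask[row, col]
    if (lbl > 0) {
      r$muscle <- as.integer(lbl)
      keep[[length(keep) + 1]] <- r
    }
  }
  keep
}

#' Filter dots by Z position
#'
#' An automated proxy for the manual curation step that removed dots lying
#' above or below the muscle of interest: each dot's Z peak (the slice
#' maximising the summed intensity over the dot footprint) must fall within
#' the fibre's Z extent, within a tolerance.
#'
#' @param regions list of dot regions.
#' @param zExtent integer(2), first and last slice of the fibre.
#' @param stack the original 3-D stack the projection came from.
#' @param tolerance slices of slack on either side (default 1).
#' @return retained regions, each with an added \code{z_peak} element.
#' @export
zFilter <- function(regions, zExtent, stack, tolerance = 1) {
  nz <- dim(stack)[3]
  keep <- list()
  for (r in regions) {
    idx <- r$pixels
    prof <- vapply(seq_len(nz), function(z) {
      sum(stack[cbind(idx, z)])
    }, 0)
    zp <- which.max(prof)
    if (zp >= zExtent[1] - tolerance && zp <= zExtent[2] + tolerance) {
      r$z_peak <- zp
      keep[[length(keep) + 1]] <- r
    }
  }
  keep
}

#' Integrated density of a dot region
#'
#' IntDen: the exact sum of projection pixel values over the region pixels.
#'
#' @param projection intensity matrix (sum projection).
#' @param region a dot region (from \code{\link{labelParticles}}) or an
#'   n x 2 matrix of (row, col) pixels, 1-based.
#' @return numeric scalar.
#' @export
measureIntDen <- function(projection, region) {
  px <- if (is.list(region)) region$pixels else region
  if (is.null(px) || nrow(px) == 0L) stop("empty region: IntDen undefined")
  if (max(px[, 1]) > nrow(projection) || max(px[, 2]) > ncol(projection))
    stop("region pixels outside the projection grid")
  sum(projection[px])
}

#' Mean intensity over a muscle region
#'
#' @param projection intensity matrix (sum projection).
#' @param region binary/label matrix (non-zero = member) or an n x 2 matrix
#'   of (row, col) pixels, 1-based.
#' @return arithmetic mean of member pixel values.
#' @export
measureMuscleMean <- function(projection, region) {
  px <- if (is.matrix(region) && all(dim(region) == dim(projection)))
    which(region > 0, arr.ind = TRUE) else region
  if (nrow(px) == 0L) stop("empty region: mean undefined")
  mean(projection[px])
}

#' Quantify one dot channel of one fibre
#'
#' The full measurement chain in fixed order: sum projection, threshold,
#' particle labelling, muscle-mask intersection, Z filtering, per-dot
#' integrated density. Two detection profiles exist: \code{"standard"}
#' (configured absolute threshold, minimum area 2 px) for single-gene
#' stage-course quantification, and \code{"permissive"} (background + 2 SD
#' threshold, minimum area 1 px) for double-FISH counting where all dots
#' count, even small and weak ones.
#'
#' @param stack 3-D dot-channel array.
#' @param muscleMask binary/label matrix.
#' @param zExtent integer(2) fibre slice range.
#' @param threshold absolute threshold or automatic method name; ignored
#'   when \code{profile = "permissive"}.
#' @param minArea minimum dot area; overridden by the profile.
#' @param profile "standard" or "permissive".
#' @param zTolerance slack for the Z filter.
#' @return data.frame with one row per dot: x, y, area, intden, z_peak,
#'   muscle. Attribute \code{threshold} records the applied value.
#' @export
quantifyStack <- function(stack, muscleMask, zExtent, threshold = 2,
                          minArea = 2, profile = c("standard", "permissive"),
                          zTolerance = 1) {
  profile <- match.arg(profile)
  if (profile == "permissive") {
    rng <- range(stack)
    threshold <- if (rng[1] == rng[2]) rng[1] else "background_2sd"
    minArea <- 1
  }
  proj <- projectStack(stack, "sum")
  mask <- thresholdDots(proj, threshold)
  regions <- labelParticles(mask, minArea = minArea)
  regions <- intersectWithMuscle(regions, muscleMask)
  regions <- zFilter(regions, zExtent, stack, tolerance = zTolerance)
  out <- data.frame(
    x = vapply(regions, function(r) unname(r$centroid["x"]), 0),
    y = vapply(regions, function(r) unname(r$centroid["y"]), 0),
    area = vapply(regions, function(r) r$area, 0L),
    intden = vapply(regions, function(r) measureIntDen(proj, r), 0),
    z_peak = vapply(regions, function(r) r$z_peak, 0L),
    muscle = vapply(regions, function(r) r$muscle, 0L))
  attr(out, "threshold") <- if (is.numeric(threshold)) threshold
                            else attr(mask, "threshold")
  attr(out, "regions") <- regions
  out
}

#' Quantify a whole fibre (all dot channels)
#'
#' Runs \code{\link{quantifyStack}} on every \code{dot_<gene>} channel of a
#' simulated (or read-back) fibre and counts nuclei whose centroid lies
#' inside the muscle mask, yielding the per-fibre measurement record:
#' nuclei count, dot count, per-dot integrated densities and their sum
#' (Total IntDen per fibre).
#'
#' @param fibre a fibre object (list with \code{channels}, \code{masks},
#'   \code{geometry}) as from \code{\link{simulateFibre}}.
#' @param config a \code{GeneratorConfig}; its \code{detection} settings are
#'   used unless overridden.
#' @param profile detection profile; default from the config.
#' @param nuclei optional \code{NucleusSet} (e.g. from
#'   \code{\link{segmentNuclei}}); default: the ground-truth label mask.
#' @return list with \code{dots} (data.frame: fibre_id, gene, stage, x, y,
#'   area, intden, z_peak) and \code{fibres} (data.frame: fibre_id, gene,
#'   stage, n_nuclei, n_dots, total_intden).
#' @export
quantifyFibre <- function(fibre, config, profile = NULL, nuclei = NULL) {
  det <- config@detection
  if (is.null(profile)) profile <- det$profile
  geom <- fibre$geometry
  muscleMask <- fibre$masks$muscle
  if (is.null(nuclei)) {
    labs <- fibre$masks$nuclei
    info <- labelTable(labs)
  } else {
    labs <- nucleusLabels(nuclei)
    info <- nucleusInfo(nuclei)
  }
  inMuscle <- muscleMask[cbind(pmin(pmax(round(info$y) + 1, 1), nrow(muscleMask)),
                               pmin(pmax(round(info$x) + 1, 1), ncol(muscleMask)))] > 0
  nNuclei <- sum(inMuscle)
  fid <- fibre$truth$nuclei$fibre_id[1] %||% "f1"
  dotRows <- list(); fibreRows <- list()
  chn <- grep("^dot_", names(fibre$channels), value = TRUE)
  for (ch in chn) {
    gene <- sub("^dot_", "", ch)
    d <- quantifyStack(fibre$channels[[ch]], muscleMask, geom@zExtent,
                       threshold = det$threshold, minArea = det$minArea,
                       profile = profile, zTolerance = det$zTolerance)
    if (nrow(d)) {
      d <- cbind(fibre_id = fid, gene = gene, stage = geom@stage, d)
      dotRows[[length(dotRows) + 1]] <- d
    }
    fibreRows[[length(fibreRows) + 1]] <- data.frame(
      fibre_id = fid, gene = gene, stage = geom@stage,
      n_nuclei = nNuclei, n_dots = nrow(d),
      total_intden = sum(d$intden), stringsAsFactors = FALSE)
  }
  dots <- if (length(dotRows)) do.call(rbind, dotRows) else data.frame(
    fibre_id = character(), gene = character(), stage = integer(),
    x = numeric(), y = numeric(), area = integer(), intden = numeric(),
    z_peak = integer(), muscle = integer())
  list(dots = dots, fibres = do.call(rbind, fibreRows))
}

# centroid/area table from a label matrix (0-based centroids)
labelTable <- function(labels) {
  k <- max(labels)
  if (k == 0) return(data.frame(nucleus_id = integer(), x = numeric(),
                                y = numeric(), area = integer()))
  rows <- lapply(seq_len(k), function(i) {
    px <- which(labels == i, arr.ind = TRUE)
    data.frame(nucleus_id = i, x = mean(px[, 2]) - 1, y = mean(px[, 1]) - 1,
               area = nrow(px))
  })
  do.call(rbind, rows)
}
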