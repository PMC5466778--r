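#' Add one diffraction-limited spot to an image stack
#'
#' Renders an isotropic 2-D Gaussian profile of total (summed) intensity
#' \code{intensity} at continuous position (x, y), distributed across slices
#' with weights \code{zWeights}. The in-plane patch is normalised so the sum
#' of all rendered pixels equals \code{intensity} exactly before any
#' quantisation. A spot whose patch would extend outside the image is an
#' error, never silently clipped.
#'
#' @param stack 3-D array (height, width, slices).
#' @param x,y 0-based continuous centre position.
#' @param intensity total integrated intensity (arbitrary units).
#' @param sigma Gaussian sigma in pixels.
#' @param zWeights numeric, one weight per slice (normalised internally).
#' @param cutoffSigma patch half-width in sigmas.
#' @return the stack with the spot added.
#' @export
addSpot <- function(stack, x, y, intensity, sigma = 1.5,
                    zWeights = NULL, cutoffSigma = 4) {
  d <- dim(stack)
  h <- d[1]; w <- d[2]; nz <- d[3]
  if (is.null(zWeights)) zWeights <- rep(1, nz)
  if (length(zWeights) != nz) stop("zWeights must have one entry per slice")
  zWeights <- zWeights / sum(zWeights)
  R <- ceiling(cutoffSigma * sigma)
  rows <- (floor(y) - R):(ceiling(y) + R) # 0-based pixel y
  cols <- (floor(x) - R):(ceiling(x) + R)
  if (min(rows) < 0 || max(rows) > h - 1 || min(cols) < 0 || max(cols) > w - 1)
    stop(sprintf(
      "spot at (%.1f, %.1f) with patch radius %d px falls outside the %d x %d image",
      x, y, R, h, w))
  gy <- exp(-(rows - y)^2 / (2 * sigma^2))
  gx <- exp(-(cols - x)^2 / (2 * sigma^2))
  patch <- outer(gy, gx)
  patch <- patch / sum(patch) * intensity
  for (z in which(zWeights > 0))
    stack[rows + 1, cols + 1, z] <- stack[rows + 1, cols + 1, z] +
      patch * zWeights[z]
  stack
}

# Gaussian-in-Z weights over the fibre's slice extent (peak at its centre).
zProfile <- function(zExtent, nSlices) {
  wz <- numeric(nSlices)
  zs <- zExtent[1]:zExtent[2]
  mid <- mean(zs)
  sdz <- max((zExtent[2] - zExtent[1] + 1) / 4, 0.5)
  wz[zs] <- stats::dnorm(zs, mid, sdz)
  wz / sum(wz)
}

rasteriseNuclei <- function(geometry) {
  h <- geometry@imageSize[1]; w <- geometry@imageSize[2]
  labels <- matrix(0L, h, w)
  r <- geometry@nucleusRadius
  for (k in seq_len(nrow(geometry@nuclei))) {
    cx <- geometry@nuclei[k, 1]; cy <- geometry@nuclei[k, 2]
    cols <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
    rows <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
    dd <- outer((rows - cy)^2, (cols - cx)^2, "+")
    sel <- dd <= r^2
    sub <- labels[rows + 1, cols + 1]
    sub[sel] <- k
    labels[rows + 1, cols + 1] <- sub
  }
  labels
}

#' Render a multi-channel image stack with ground truth
#'
#' Renders one fibre: a muscle-outline channel (filled polygon across the
#' fibre's Z extent), a nuclear channel (filled discs), one dot channel per
#' gene (a diffraction-limited spot for every ON nucleus, at the nucleus
#' centre plus a small locus offset, with the drawn intensity spread over
#' the fibre's Z range), and optionally a lineage channel when lineage
#' mixing is configured. Noise (Poisson shot noise, Gaussian read noise) is
#' added per the configuration, then images are quantised to integer grey
#' levels by default, as a microscope detector would produce. Ground truth
#' (per-nucleus states and lineage, per-dot true position and intensity) is
#' returned alongside, together with the muscle and nucleus label masks.
#'
#' @param geometry a \code{FibreGeometry}.
#' @param states logical nuclei x genes matrix from
#'   \code{\link{sampleTranscriptionStates}}.
#' @param config a \code{GeneratorConfig}.
#' @param fibreId identifier recorded in the ground-truth tables.
#' @return list with \code{channels} (named list of 3-D arrays; dot channels
#'   are named \code{dot_<gene>}), \code{masks} (list: \code{muscle} binary
#'   matrix, \code{nuclei} label matrix), \code{truth} (list of data.frames
#'   \code{nuclei} and \code{dots}), \code{geometry}.
#' @export
renderStack <- function(geometry, states, config, fibreId = "f1") {
  h <- geometry@imageSize[1]; w <- geometry@imageSize[2]
  nz <- geometry@nSlices
  rnd <- config@render
  muscleMask <- cachedPolygonMask(geometry@polygon, geometry@imageSize)
  nucLabels <- rasteriseNuclei(geometry)
  wz <- zProfile(geometry@zExtent, nz)
  zs <- geometry@zExtent[1]:geometry@zExtent[2]

  inZ <- function(img2d, value) {
    a <- array(0, c(h, w, nz))
    for (z in zs) a[, , z] <- img2d * value
    a
  }
  channels <- list(
    muscle = inZ(muscleMask, rnd$muscleIntensity),
    nuclei = inZ(nucLabels > 0, rnd$nucleusIntensity)
  )
  if (config@lineage$pLabelled > 0) {
    lin <- matrix(0, h, w)
    for (k in seq_len(nrow(geometry@nuclei))) {
      v <- if (geometry@lineage[k] == "labelled")
        config@lineage$labelledIntensity else config@lineage$unlabelledIntensity
      lin[nucLabels == k] <- v
    }
    channels$lineage <- inZ(lin, 1)
  }

  genes <- colnames(states)
  dots <- list()
  for (g in genes) {
    spec <- geneSpec(config, g)
    ch <- array(0, c(h, w, nz))
    on <- which(states[, g])
    for (k in on) {
      mu <- spec@intensityMean *
        if (k == geometry@fcIndex) spec@fcMultiplier else 1
      intensity <- if (spec@intensityCV > 0) {
        shape <- 1 / spec@intensityCV^2
        stats::rgamma(1, shape = shape, scale = mu / shape)
      } else mu
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- rnd$dotJitter * sqrt(stats::runif(1))
      x0 <- geometry@nuclei[k, 1] + rad * cos(ang)
      y0 <- geometry@nuclei[k, 2] + rad * sin(ang)
      ch <- addSpot(ch, x0, y0, intensity, sigma = rnd$sigma,
                    zWeights = wz, cutoffSigma = rnd$cutoffSigma)
      dots[[length(dots) + 1]] <- data.frame(
        fibre_id = fibreId, stage = geometry@stage, gene = g,
        nucleus_id = k, dot_x = x0, dot_y = y0,
        dot_intensity = intensity, stringsAsFactors = FALSE)
    }
    channels[[paste0("dot_", g)]] <- ch
  }

  if (isTRUE(rnd$poissonNoise))
    channels <- lapply(channels, function(a) {
      array(stats::rpois(length(a), lambda = a), dim(a))
    })
  if (rnd$readNoiseSD > 0)
    channels <- lapply(channels, function(a) {
      pmax(a + stats::rnorm(length(a), 0, rnd$readNoiseSD), 0)
    })
  if (isTRUE(rnd$quantise))
    channels <- lapply(channels, round)

  nucTruth <- data.frame(
    fibre_id = fibreId, stage = geometry@stage,
    nucleus_id = seq_len(nrow(geometry@nuclei)),
    is_fc = seq_len(nrow(geometry@nuclei)) == geometry@fcIndex,
    x = geometry@nuclei[, 1], y = geometry@nuclei[, 2],
    lineage_label = geometry@lineage, stringsAsFactors = FALSE)
  for (g in genes) nucTruth[[paste0("state_", g)]] <- states[, g]

  dotTruth <- if (length(dots)) do.call(rbind, dots) else data.frame(
    fibre_id = character(), stage = integer(), gene = character(),
    nucleus_id = integer(), dot_x = numeric(), dot_y = numeric(),
    dot_intensity = numeric(), stringsAsFactors = FALSE)

  list(channels = channels,
       masks = list(muscle = muscleMask, nuclei = nucLabels),
       truth = list(nuclei = nucTruth, dots = dotTruth),
       geometry = geometry)
}

#' Simulate one fibre end to end
#'
#' Convenience wrapper: \code{\link{buildFibreGeometry}} then
#' \code{\link{sampleTranscriptionStates}} then \code{\link{renderStack}}.
#'
#' @inheritParams buildFibreGeometry
#' @param fibreId identifier recorded in ground truth.
#' @return see \code{\link{renderStack}}; the element \code{states} is added.
#' @export
simulateFibre <- function(config, stage, fibreId = "f1") {
  geometry <- buildFibreGeometry(config, stage)
  states <- sampleTranscriptionStates(geometry, config)
  out <- renderStack(geometry, states, config, fibreId = fibreId)
  out$states <- states
  out
}
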