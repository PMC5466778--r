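#' Segment nuclei from a nuclear-channel projection
#'
#' Threshold (Otsu by default) followed by distance-transform watershed to
#' split touching nuclei, the standard DAPI-segmentation recipe. Supplying
#' ground-truth label masks instead (see \code{\link{quantifyFibre}})
#' bypasses segmentation entirely.
#'
#' @param projection 2-D nuclear-channel image (e.g. a max projection).
#' @param threshold absolute value or "otsu".
#' @param minArea discard components smaller than this (pixels).
#' @param split split touching nuclei by watershed on the distance map.
#' @param wsTolerance watershed tolerance (minimum object-height separation
#'   in distance-map units before two maxima count as distinct nuclei).
#' @return a \code{\link{NucleusSet-class}}; empty (with a warning) when no
#'   foreground survives.
#' @export
segmentNuclei <- function(projection, threshold = "otsu", minArea = 20,
                          split = TRUE, wsTolerance = 1) {
  rng <- range(projection)
  if (rng[1] == rng[2]) {
    warning("constant nuclear channel: no nuclei found")
    return(new("NucleusSet", labels = matrix(0L, nrow(projection),
                                             ncol(projection)),
               info = data.frame(nucleus_id = integer(), x = numeric(),
                                 y = numeric(), area = integer())))
  }
  mask <- thresholdDots(projection, threshold)
  if (!any(mask > 0)) {
    warning("no foreground after thresholding the nuclear channel")
    return(new("NucleusSet", labels = matrix(0L, nrow(mask), ncol(mask)),
               info = data.frame(nucleus_id = integer(), x = numeric(),
                                 y = numeric(), area = integer())))
  }
  labs <- if (split) {
    dm <- EBImage::distmap(mask)
    as.matrix(EBImage::watershed(dm, tolerance = wsTolerance))
  } else {
    labelConnected(mask)
  }
  # drop undersized objects, relabel compactly
  tab <- tabulate(labs[labs > 0])
  keep <- which(tab >= minArea)
  lut <- integer(length(tab)); lut[keep] <- seq_along(keep)
  labs[labs > 0] <- lut[labs[labs > 0]]
  storage.mode(labs) <- "integer"
  new("NucleusSet", labels = labs, info = labelTable(labs))
}

#' Assign detected dots to nuclei
#'
#' Containment first: a dot whose centroid pixel falls inside a nucleus mask
#' belongs to that nucleus. Otherwise the nearest nucleus centroid within
#' \code{maxDistanceFactor} times the median nucleus radius is used; farther
#' dots stay unassigned. Ties break by smaller distance, then smaller
#' nucleus id.
#'
#' @param dots data.frame with 0-based columns \code{x}, \code{y} (as from
#'   \code{\link{quantifyStack}}).
#' @param nuclei a \code{NucleusSet}.
#' @param maxDistanceFactor multiple of the median nucleus radius allowed
#'   for nearest-centroid assignment (default 1.5).
#' @return the dots data.frame with an added \code{nucleus_id} column
#'   (\code{NA} = unassigned).
#' @export
assignDots <- function(dots, nuclei, maxDistanceFactor = 1.5) {
  labs <- nucleusLabels(nuclei)
  info <- nucleusInfo(nuclei)
  n <- nrow(dots)
  out <- rep(NA_integer_, n)
  if (n == 0 || nrow(info) == 0) {
    dots$nucleus_id <- out
    return(dots)
  }
  medRadius <- stats::median(sqrt(info$area / pi))
  maxDist <- maxDistanceFactor * medRadius
  for (i in seq_len(n)) {
    row <- round(dots$y[i]) + 1; col <- round(dots$x[i]) + 1
    if (row >= 1 && row <= nrow(labs) && col >= 1 && col <= ncol(labs) &&
        labs[row, col] > 0) {
      out[i] <- labs[row, col]
      next
    }
    d <- sqrt((info$x - dots$x[i])^2 + (info$y - dots$y[i])^2)
    ord <- order(d, info$nucleus_id)
    if (d[ord[1]] <= maxDist) out[i] <- info$nucleus_id[ord[1]]
  }
  dots$nucleus_id <- out
  dots
}

#' Per-nucleus ON/OFF states from assigned dots
#'
#' A nucleus is ON for a gene iff at least one dot of that gene was assigned
#' to it (several dots, e.g. sister-chromatid pairs, still count as one ON
#' nucleus).
#'
#' @param dots data.frame with \code{gene} and \code{nucleus_id} columns
#'   (from \code{\link{assignDots}}).
#' @param nuclei a \code{NucleusSet} (defines the nucleus universe).
#' @param genes genes to tabulate (default: those present in \code{dots}).
#' @return logical matrix, nuclei x genes.
#' @export
nucleusStates <- function(dots, nuclei, genes = NULL) {
  info <- nucleusInfo(nuclei)
  if (is.null(genes)) genes <- unique(dots$gene)
  st <- matrix(FALSE, nrow(info), length(genes),
               dimnames = list(NULL, genes))
  ok <- !is.na(dots$nucleus_id) & dots$gene %in% genes
  for (i in which(ok))
    st[match(dots$nucleus_id[i], info$nucleus_id), dots$gene[i]] <- TRUE
  st
}

#' Tabulate co-transcription for a gene pair
#'
#' Exact four-way counts of nuclei in \{A only, B only, both, neither\} and
#' the derived fractions: \code{active} = fraction of nuclei transcribing at
#' least one of the pair, and \code{co_given_active} = fraction of active
#' nuclei transcribing both.
#'
#' @param states logical nuclei x genes matrix (ground truth or
#'   \code{\link{nucleusStates}} output).
#' @param genes character(2), the pair (A, B).
#' @return one-row data.frame: n_total, n_a_only, n_b_only, n_both,
#'   n_neither, active, co_given_active.
#' @export
tabulateCotranscription <- function(states, genes) {
  if (nrow(states) == 0) stop("zero nuclei: co-transcription undefined")
  a <- states[, genes[1]]; b <- states[, genes[2]]
  nBoth <- sum(a & b); nA <- sum(a & !b); nB <- sum(!a & b)
  nNeither <- sum(!a & !b)
  nAct <- nA + nB + nBoth
  data.frame(
    geneA = genes[1], geneB = genes[2],
    n_total = nrow(states), n_a_only = nA, n_b_only = nB,
    n_both = nBoth, n_neither = nNeither,
    active = nAct / nrow(states),
    co_given_active = if (nAct > 0) nBoth / nAct else NA_real_,
    stringsAsFactors = FALSE)
}

#' Count nuclei jointly ON for a mutually exclusive gene pair
#'
#' Under the exclusion model (e.g. the FCM programme gene sns versus the
#' fibre-programme genes col/duf) this count is exactly zero for any sample
#' size.
#'
#' @inheritParams tabulateCotranscription
#' @return integer count of co-ON nuclei (0 for an empty state matrix).
#' @export
exclusionCheck <- function(states, genes) {
  if (nrow(states) == 0) return(0L)
  sum(states[, genes[1]] & states[, genes[2]])
}

#' Classify lineage labels from a lineage channel
#'
#' Proxies the manual RFP-positive call: a nucleus is labelled when the mean
#' lineage-channel intensity over its mask exceeds the threshold.
#'
#' @param nuclei a \code{NucleusSet}.
#' @param lineageProjection 2-D lineage-channel image.
#' @param threshold intensity cut-off for the labelled call.
#' @return character vector "labelled"/"unlabelled" per nucleus.
#' @export
classifyLineage <- function(nuclei, lineageProjection, threshold) {
  labs <- nucleusLabels(nuclei)
  info <- nucleusInfo(nuclei)
  vapply(info$nucleus_id, function(i) {
    m <- mean(lineageProjection[labs == i])
    if (m > threshold) "labelled" else "unlabelled"
  }, "")
}

#' Count lineage-labelled nuclei within a muscle
#'
#' @param nuclei a \code{NucleusSet}.
#' @param lineage character vector per nucleus ("labelled"/"unlabelled"),
#'   e.g. from \code{\link{classifyLineage}} or ground truth.
#' @param muscleMask binary/label matrix; only nuclei whose centroid lies
#'   inside count.
#' @return named integer vector \code{c(n_labelled, n_total)}.
#' @export
countLabelledNuclei <- function(nuclei, lineage, muscleMask) {
  info <- nucleusInfo(nuclei)
  if (nrow(info) == 0) return(c(n_labelled = 0L, n_total = 0L))
  inside <- muscleMask[cbind(round(info$y) + 1, round(info$x) + 1)] > 0
  c(n_labelled = sum(inside & lineage == "labelled"),
    n_total = sum(inside))
}
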