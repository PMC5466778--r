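#' @import methods
NULL

STAGES <- 12:16

#' Per-gene transcriptional burst specification
#'
#' Describes how one gene bursts across the nuclei of a syncytial fibre:
#' the per-stage probability that a nucleus is transcriptionally ON (a
#' nascent-transcript dot is present at the locus), whether transcription is
#' restricted to the founder-cell (FC) nucleus, the FC intensity multiplier,
#' and the dot-intensity model (gamma-distributed, mean in arbitrary
#' fluorescence units, coefficient of variation).
#'
#' @slot gene gene name.
#' @slot pOn named numeric, ON probability per embryonic stage ("12".."16").
#' @slot pOnFC ON probability for the FC nucleus; \code{NA} means same as
#'   \code{pOn}. For FC-restricted genes this is the only probability used.
#' @slot fcRestricted logical; if \code{TRUE} only the FC nucleus can be ON.
#' @slot fcMultiplier dimensionless >= 1; the FC dot intensity mean is
#'   \code{fcMultiplier * intensityMean}.
#' @slot intensityMean mean dot integrated intensity (arbitrary units).
#' @slot intensityCV coefficient of variation of dot intensity.
#' @slot exclusionGroup optional group name; genes sharing a group are never
#'   jointly ON in one nucleus. \code{NA} for none.
#'
#' @export
setClass("GeneBurstSpec",
  representation(
    gene = "character",
    pOn = "numeric",
    pOnFC = "numeric",
    fcRestricted = "logical",
    fcMultiplier = "numeric",
    intensityMean = "numeric",
    intensityCV = "numeric",
    exclusionGroup = "character"
  ),
  prototype(
    pOnFC = NA_real_, fcRestricted = FALSE, fcMultiplier = 1,
    intensityMean = 20000, intensityCV = 0.2, exclusionGroup = NA_character_
  )
)

setValidity("GeneBurstSpec", function(object) {
  msg <- character()
  if (length(object@gene) != 1L || !nzchar(object@gene))
    msg <- c(msg, "'gene' must be a single non-empty name")
  if (!all(as.character(STAGES) %in% names(object@pOn)))
    msg <- c(msg, "pOn must be named for every stage 12..16")
  if (any(object@pOn < 0 | object@pOn > 1, na.rm = TRUE))
    msg <- c(msg, "pOn values must lie in [0, 1]")
  if (!is.na(object@pOnFC) && (object@pOnFC < 0 || object@pOnFC > 1))
    msg <- c(msg, "pOnFC must lie in [0, 1]")
  if (object@fcMultiplier < 1)
    msg <- c(msg, "fcMultiplier must be >= 1")
  if (object@intensityMean <= 0)
    msg <- c(msg, "intensityMean must be positive")
  if (object@intensityCV < 0)
    msg <- c(msg, "intensityCV must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Joint ON/OFF burst table for a correlated gene pair
#'
#' A categorical law over the four joint transcriptional states of two genes
#' in one nucleus. Needed when the reported union and co-transcription
#' fractions are infeasible under independent bursting, as for the duf/col
#' pair (80\% union with 50\% co-transcription among active nuclei).
#'
#' @slot genes ordered pair of gene names (A, B).
#' @slot probabilities numeric(4) named \code{both}, \code{a_only},
#'   \code{b_only}, \code{neither}; non-negative, summing to 1.
#'
#' @export
setClass("JointBurstTable",
  representation(genes = "character", probabilities = "numeric")
)

JOINT_STATES <- c("both", "a_only", "b_only", "neither")

setValidity("JointBurstTable", function(object) {
  msg <- character()
  if (length(object@genes) != 2L || anyDuplicated(object@genes))
    msg <- c(msg, "'genes' must be two distinct gene names")
  p <- object@probabilities
  if (!identical(sort(names(p)), sort(JOINT_STATES)))
    msg <- c(msg, "probabilities must be named both/a_only/b_only/neither")
  if (any(p < 0))
    msg <- c(msg, "probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "probabilities must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Generator configuration
#'
#' Bundles everything needed to simulate fibres: the burst specification of
#' each gene, joint burst tables for correlated pairs, fibre geometry
#' parameters (muscle template, nuclei counts per stage, nucleus radius and
#' packing constraints, FC placement mode, Z geometry), rendering parameters
#' (spot width, noise, quantisation), lineage-label mixing, and the default
#' detection profile used when quantifying the rendered images.
#'
#' @slot name configuration name.
#' @slot muscle muscle identity label (e.g. "DA3", "DT1").
#' @slot template muscle template name; see \code{\link{muscleTemplate}}.
#' @slot genes list of \code{GeneBurstSpec}.
#' @slot jointTables list of \code{JointBurstTable}.
#' @slot geometry named list of geometry parameters.
#' @slot render named list of rendering parameters.
#' @slot lineage named list of lineage-label parameters.
#' @slot detection named list of detection defaults.
#'
#' @export
setClass("GeneratorConfig",
  representation(
    name = "character", muscle = "character", template = "character",
    genes = "list", jointTables = "list",
    geometry = "list", render = "list", lineage = "list", detection = "list",
    recovery = "list"
  ),
  prototype(recovery = list())
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (!all(vapply(object@genes, is, TRUE, "GeneBurstSpec")))
    msg <- c(msg, "all elements of 'genes' must be GeneBurstSpec")
  if (!all(vapply(object@jointTables, is, TRUE, "JointBurstTable")))
    msg <- c(msg, "all elements of 'jointTables' must be JointBurstTable")
  gn <- vapply(object@genes, function(g) g@gene, "")
  if (anyDuplicated(gn))
    msg <- c(msg, "duplicated gene names")
  jointGenes <- unlist(lapply(object@jointTables, function(j) j@genes))
  if (anyDuplicated(jointGenes))
    msg <- c(msg, "a gene may reference at most one joint table")
  if (!all(jointGenes %in% gn))
    msg <- c(msg, "joint tables reference genes missing from 'genes'")
  for (g in object@genes) {
    if (g@fcRestricted && g@gene %in% jointGenes)
      msg <- c(msg, sprintf(
        "gene '%s' is both fc_restricted and in a joint table", g@gene))
    if (g@gene %in% jointGenes && !is.na(g@exclusionGroup))
      msg <- c(msg, sprintf(
        "gene '%s' cannot be in both a joint table and an exclusion group",
        g@gene))
  }
  geo <- object@geometry
  need <- c("nucleiByStage", "nucleusRadius", "minSeparation", "fcPosition",
            "fcJitter", "nSlices", "zExtent")
  if (!all(need %in% names(geo)))
    msg <- c(msg, paste("geometry must contain:", paste(need, collapse = ", ")))
  else {
    if (!all(as.character(STAGES) %in% names(geo$nucleiByStage)))
      msg <- c(msg, "geometry$nucleiByStage must cover stages 12..16")
    if (!geo$fcPosition %in% c("centre", "uniform"))
      msg <- c(msg, "geometry$fcPosition must be 'centre' or 'uniform'")
    if (length(geo$zExtent) != 2L || geo$zExtent[1] > geo$zExtent[2] ||
        geo$zExtent[1] < 1 || geo$zExtent[2] > geo$nSlices)
      msg <- c(msg, "geometry$zExtent must be a valid slice range")
  }
  if (length(msg)) msg else TRUE
})

#' Geometry of one simulated syncytial fibre
#'
#' The muscle outline polygon, the nucleus centres and common radius, which
#' nucleus is the founder cell, the embryonic stage, the Z slices occupied by
#' the fibre and the image size. All coordinates are 0-based pixels, origin
#' top-left, y increasing downward (image convention; anatomical dorsal up).
#'
#' @slot polygon n x 2 matrix of muscle outline vertices (x, y).
#' @slot nuclei n x 2 matrix of nucleus centres (x, y).
#' @slot nucleusRadius common nucleus radius in pixels.
#' @slot fcIndex index (row of \code{nuclei}) of the founder-cell nucleus.
#' @slot lineage character vector, "labelled"/"unlabelled" per nucleus.
#' @slot stage embryonic stage, 12..16.
#' @slot zExtent integer(2), first and last slice occupied by the fibre.
#' @slot nSlices total number of Z slices in the stack.
#' @slot imageSize integer(2), (height, width) in pixels.
#'
#' @export
setClass("FibreGeometry",
  representation(
    polygon = "matrix", nuclei = "matrix", nucleusRadius = "numeric",
    fcIndex = "integer", lineage = "character", stage = "integer",
    zExtent = "integer", nSlices = "integer", imageSize = "integer"
  )
)

setValidity("FibreGeometry", function(object) {
  msg <- character()
  if (ncol(object@polygon) != 2L || nrow(object@polygon) < 3L)
    msg <- c(msg, "polygon must be an n x 2 matrix with n >= 3")
  if (ncol(object@nuclei) != 2L)
    msg <- c(msg, "nuclei must be an n x 2 matrix of centres")
  if (length(object@fcIndex) != 1L ||
      object@fcIndex < 1L || object@fcIndex > nrow(object@nuclei))
    msg <- c(msg, "exactly one fcIndex, pointing at a nucleus")
  if (!object@stage %in% STAGES)
    msg <- c(msg, "stage must be in 12..16")
  if (length(object@lineage) != nrow(object@nuclei))
    msg <- c(msg, "lineage must have one entry per nucleus")
  if (nrow(object@nuclei) > 0 &&
      !all(pointInPolygon(object@nuclei, object@polygon)))
    msg <- c(msg, "all nucleus centres must lie inside the muscle polygon")
  if (length(msg)) msg else TRUE
})

#' Muscle reference frame for coordinate standardisation
#'
#' The measured area, centroid and minimal axis-aligned bounding rectangle of
#' a muscle region, from which dot and nucleus coordinates are standardised.
#' The bounding rectangle is stored as (x, y, width, height) of its top-left
#' corner; the anterior anchor BRant is its bottom-left corner and the
#' posterior anchor BRpost its top-right corner (dorsal up, anterior left).
#'
#' @slot centroid numeric(2), (x, y) centroid in 0-based pixels.
#' @slot area region area in pixels^2.
#' @slot boundingRect numeric(4), (x, y, width, height).
#'
#' @export
setClass("MuscleFrame",
  representation(centroid = "numeric", area = "numeric",
                 boundingRect = "numeric")
)

setValidity("MuscleFrame", function(object) {
  msg <- character()
  if (object@area <= 0) msg <- c(msg, "area must be positive")
  br <- object@boundingRect
  if (length(br) != 4L || br[3] <= 0 || br[4] <= 0)
    msg <- c(msg, "boundingRect must be (x, y, width, height) with positive size")
  else {
    cx <- object@centroid[1]; cy <- object@centroid[2]
    if (cx < br[1] || cx > br[1] + br[3] || cy < br[2] || cy > br[2] + br[4])
      msg <- c(msg, "centroid must lie inside the bounding rectangle")
  }
  if (length(msg)) msg else TRUE
})

#' Segmented nuclei of one fibre
#'
#' A label image (0 background, k = nucleus k) together with a per-nucleus
#' table of centroid and area, as produced by \code{\link{segmentNuclei}} or
#' from ground-truth masks.
#'
#' @slot labels integer label matrix.
#' @slot info data.frame with columns nucleus_id, x, y, area (0-based pixel
#'   centroids).
#'
#' @export
setClass("NucleusSet",
  representation(labels = "matrix", info = "data.frame")
)

setValidity("NucleusSet", function(object) {
  msg <- character()
  need <- c("nucleus_id", "x", "y", "area")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must contain:", paste(need, collapse = ", ")))
  k <- max(0, object@labels)
  if (nrow(object@info) != k)
    msg <- c(msg, "info must have one row per label")
  if (length(msg)) msg else TRUE
})
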