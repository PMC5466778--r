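# Accessor functions for the S4 containers (slot access stays internal).

#' @rdname MuscleFrame-accessors
#' @title MuscleFrame accessors
#' @description Accessors for the components of a \code{MuscleFrame}:
#'   area, centroid, bounding rectangle, and the derived anterior
#'   (\code{brAnt}, bottom-left corner) and posterior (\code{brPost},
#'   top-right corner) anchors of the bounding rectangle.
#' @param frame a \code{MuscleFrame}.
#' @return \code{frameArea}: scalar; \code{frameCentroid}: numeric(2);
#'   \code{boundingRect}: numeric(4) (x, y, width, height);
#'   \code{brAnt}, \code{brPost}: numeric(2).
#' @export
frameArea <- function(frame) frame@area

#' @rdname MuscleFrame-accessors
#' @export
frameCentroid <- function(frame) frame@centroid

#' @rdname MuscleFrame-accessors
#' @export
boundingRect <- function(frame) frame@boundingRect

#' @rdname MuscleFrame-accessors
#' @export
brAnt <- function(frame) {
  br <- frame@boundingRect
  c(x = unname(br[1]), y = unname(br[2] + br[4]))
}

#' @rdname MuscleFrame-accessors
#' @export
brPost <- function(frame) {
  br <- frame@boundingRect
  c(x = unname(br[1] + br[3]), y = unname(br[2]))
}

#' @rdname FibreGeometry-accessors
#' @title FibreGeometry accessors
#' @description Accessors for a simulated fibre's geometry: nucleus centres,
#'   the founder-cell index, the muscle outline polygon and the stage.
#' @param geometry a \code{FibreGeometry}.
#' @export
nucleusCentres <- function(geometry) geometry@nuclei

#' @rdname FibreGeometry-accessors
#' @export
fcIndex <- function(geometry) geometry@fcIndex

#' @rdname FibreGeometry-accessors
#' @export
musclePolygon <- function(geometry) geometry@polygon

#' @rdname FibreGeometry-accessors
#' @export
fibreStage <- function(geometry) geometry@stage

#' @rdname NucleusSet-accessors
#' @title NucleusSet accessors
#' @description The label image and the per-nucleus table of a
#'   \code{NucleusSet}.
#' @param x a \code{NucleusSet}.
#' @export
nucleusLabels <- function(x) x@labels

#' @rdname NucleusSet-accessors
#' @export
nucleusInfo <- function(x) x@info

#' @rdname GeneratorConfig-accessors
#' @title GeneratorConfig accessors
#' @param config a \code{GeneratorConfig}.
#' @param gene gene name (for \code{geneSpec}).
#' @export
configGenes <- function(config) vapply(config@genes, function(g) g@gene, "")

#' @rdname GeneratorConfig-accessors
#' @export
geneSpec <- function(config, gene) {
  i <- match(gene, configGenes(config))
  if (is.na(i)) stop("no such gene in config: ", gene)
  config@genes[[i]]
}

#' @rdname GeneratorConfig-accessors
#' @export
jointTables <- function(config) config@jointTables
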