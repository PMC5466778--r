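#' Build the geometry of one simulated fibre
#'
#' Places the configured number of nuclei for the stage inside the muscle
#' template polygon. The founder-cell (FC) nucleus is placed first: at the
#' polygon centroid with uniform jitter (\code{fcPosition = "centre"},
#' default), or drawn uniformly over the radius-eroded outline
#' (\code{fcPosition = "uniform"}, used to model an FC whose position is
#' only statistically stereotyped). Remaining nuclei are placed by rejection
#' sampling with a minimum centre separation so that rendered nuclei do not
#' overlap and diffraction-limited dots stay resolvable. Lineage labels
#' (labelled/unlabelled, emulating a lineage-tracing marker such as H2B-RFP)
#' are drawn per nucleus with the configured mixing probability.
#'
#' Uses the R random number generator; seed with \code{set.seed} for
#' reproducible geometries.
#'
#' @param config a \code{GeneratorConfig}.
#' @param stage embryonic stage, 12..16.
#' @return a \code{\link{FibreGeometry-class}} object.
#' @export
buildFibreGeometry <- function(config, stage) {
  stage <- as.integer(stage)
  if (!stage %in% STAGES) stop("stage must be in 12..16, got ", stage)
  geo <- config@geometry
  n <- geo$nucleiByStage[[as.character(stage)]]
  if (is.null(n)) stop("no nuclei count configured for stage ", stage)
  n <- as.integer(n)
  tmpl <- muscleTemplate(config@template)
  poly <- tmpl$polygon
  r <- geo$nucleusRadius
  minSep <- geo$minSeparation

  bb <- apply(poly, 2, range)
  sampleInside <- function() {
    for (i in 1:5000) {
      p <- c(stats::runif(1, bb[1, 1], bb[2, 1]),
             stats::runif(1, bb[1, 2], bb[2, 2]))
      if (insideEroded(p, poly, r)) return(p)
    }
    stop("could not place a nucleus inside the eroded outline (radius ", r,
         ", template '", config@template, "')")
  }

  placeFC <- function() {
    if (geo$fcPosition == "uniform") return(sampleInside())
    cen <- colMeans(poly)
    repeat {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- geo$fcJitter * sqrt(stats::runif(1))
      p <- cen + rad * c(cos(ang), sin(ang))
      if (insideEroded(p, poly, r)) return(p)
    }
  }
  # sequential rejection can dead-end on a dense packing; restart the whole
  # placement a few times before declaring it unsatisfiable
  attemptPlacement <- function(triesPerNucleus) {
    centres <- matrix(NA_real_, n, 2)
    centres[1, ] <- placeFC()
    for (k in seq_len(n)[-1]) {
      placed <- FALSE
      for (i in seq_len(triesPerNucleus)) {
        p <- sampleInside()
        d <- sqrt(rowSums((centres[1:(k - 1), , drop = FALSE] -
                             matrix(p, k - 1, 2, byrow = TRUE))^2))
        if (all(d >= minSep)) { centres[k, ] <- p; placed <- TRUE; break }
      }
      if (!placed) return(NULL)
    }
    centres
  }
  centres <- NULL
  for (attempt in 1:25) {
    centres <- attemptPlacement(if (attempt == 1) 2000 else 500)
    if (!is.null(centres)) break
  }
  if (is.null(centres))
    stop("unsatisfiable nucleus packing: could not place ", n,
         " nuclei with minSeparation ", minSep, " px and radius ", r,
         " px in template '", config@template, "'")

  pl <- config@lineage$pLabelled
  lineage <- ifelse(stats::runif(n) < pl, "labelled", "unlabelled")

  new("FibreGeometry",
      polygon = poly, nuclei = centres, nucleusRadius = r,
      fcIndex = 1L, lineage = lineage, stage = stage,
      zExtent = as.integer(geo$zExtent), nSlices = as.integer(geo$nSlices),
      imageSize = as.integer(tmpl$imageSize))
}
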