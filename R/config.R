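#' Construct a per-gene burst specification
#'
#' @param gene gene name.
#' @param pOn ON probability per stage: either a single value recycled over
#'   stages 12..16 or a named vector/list ("12".."16"); missing stages
#'   default to 0.
#' @param pOnFC ON probability of the founder-cell nucleus (\code{NA}: use
#'   the stage's \code{pOn}). FC-restricted genes use only this.
#' @param fcRestricted logical; restrict transcription to the FC nucleus.
#' @param fcMultiplier intensity multiplier for FC dots (>= 1).
#' @param intensityMean mean dot integrated intensity, arbitrary units.
#' @param intensityCV coefficient of variation of dot intensity.
#' @param exclusionGroup optional exclusion-group name.
#' @return a \code{\link{GeneBurstSpec-class}} object.
#' @export
burstSpec <- function(gene, pOn = 0, pOnFC = NA_real_, fcRestricted = FALSE,
                      fcMultiplier = 1, intensityMean = 20000,
                      intensityCV = 0.2, exclusionGroup = NA_character_) {
  p <- stats::setNames(rep(0, length(STAGES)), as.character(STAGES))
  if (is.null(names(pOn)) && length(pOn) == 1L) {
    p[] <- pOn
  } else {
    pOn <- unlist(pOn)
    bad <- setdiff(names(pOn), names(p))
    if (length(bad)) stop("unknown stages in pOn: ", paste(bad, collapse = ", "))
    p[names(pOn)] <- pOn
  }
  new("GeneBurstSpec", gene = gene, pOn = p, pOnFC = as.numeric(pOnFC),
      fcRestricted = fcRestricted, fcMultiplier = fcMultiplier,
      intensityMean = intensityMean, intensityCV = intensityCV,
      exclusionGroup = as.character(exclusionGroup))
}

#' Construct a joint burst table for a correlated gene pair
#'
#' @param genes character(2), the ordered gene pair (A, B).
#' @param both,aOnly,bOnly,neither probabilities of the four joint states;
#'   must sum to 1.
#' @return a \code{\link{JointBurstTable-class}} object.
#' @export
jointBurstTable <- function(genes, both, aOnly, bOnly, neither) {
  new("JointBurstTable", genes = genes,
      probabilities = c(both = both, a_only = aOnly, b_only = bOnly,
                        neither = neither))
}

defaultGeometry <- function() list(
  nucleiByStage = list(`12` = 1L, `13` = 4L, `14` = 7L, `15` = 10L, `16` = 12L),
  nucleusRadius = 6, minSeparation = 15,
  fcPosition = "centre", fcJitter = 4,
  nSlices = 6L, zExtent = c(2L, 5L)
)

defaultRender <- function() list(
  sigma = 1.5, cutoffSigma = 4, dotJitter = 2, quantise = TRUE,
  poissonNoise = FALSE, readNoiseSD = 0,
  nucleusIntensity = 120, muscleIntensity = 80
)

defaultLineage <- function() list(
  pLabelled = 0, labelledIntensity = 100, unlabelledIntensity = 20,
  threshold = 60
)

defaultDetection <- function() list(
  threshold = 2, minArea = 2, profile = "standard",
  zTolerance = 1, maxDistanceFactor = 1.5
)

#' Construct a generator configuration
#'
#' @param name configuration name.
#' @param muscle muscle label (e.g. "DA3").
#' @param genes list of \code{\link{burstSpec}} objects.
#' @param jointTables list of \code{\link{jointBurstTable}} objects.
#' @param template muscle template name, see \code{\link{muscleTemplate}}.
#' @param geometry,render,lineage,detection named lists overriding individual
#'   defaults (see the vignette for each parameter's meaning and unit).
#' @return a validated \code{\link{GeneratorConfig-class}} object.
#' @export
generatorConfig <- function(name, muscle, genes, jointTables = list(),
                            template = "band", geometry = list(),
                            render = list(), lineage = list(),
                            detection = list(), recovery = list()) {
  new("GeneratorConfig", name = name, muscle = muscle, template = template,
      genes = genes, jointTables = jointTables,
      geometry = utils::modifyList(defaultGeometry(), geometry),
      render = utils::modifyList(defaultRender(), render),
      lineage = utils::modifyList(defaultLineage(), lineage),
      detection = utils::modifyList(defaultDetection(), detection),
      recovery = recovery)
}

specToList <- function(g) {
  out <- list(gene = g@gene, p_on = as.list(g@pOn))
  if (!is.na(g@pOnFC)) out$p_on_fc <- g@pOnFC
  out$fc_restricted <- g@fcRestricted
  out$fc_multiplier <- g@fcMultiplier
  out$intensity_mean <- g@intensityMean
  out$intensity_cv <- g@intensityCV
  if (!is.na(g@exclusionGroup)) out$exclusion_group <- g@exclusionGroup
  out
}

specFromList <- function(x) {
  burstSpec(
    gene = x$gene,
    pOn = if (is.null(x$p_on)) 0 else unlist(x$p_on),
    pOnFC = if (is.null(x$p_on_fc)) NA_real_ else x$p_on_fc,
    fcRestricted = isTRUE(x$fc_restricted),
    fcMultiplier = if (is.null(x$fc_multiplier)) 1 else x$fc_multiplier,
    intensityMean = if (is.null(x$intensity_mean)) 20000 else x$intensity_mean,
    intensityCV = if (is.null(x$intensity_cv)) 0.2 else x$intensity_cv,
    exclusionGroup = if (is.null(x$exclusion_group)) NA_character_
                     else x$exclusion_group
  )
}

#' Read / write generator configurations as YAML
#'
#' \code{readGeneratorConfig} parses a YAML file into a validated
#' \code{GeneratorConfig}; \code{writeGeneratorConfig} writes one back.
#' Round-tripping preserves the configuration.
#'
#' @param path YAML file path.
#' @param config a \code{GeneratorConfig}.
#' @return \code{readGeneratorConfig}: a \code{GeneratorConfig};
#'   \code{writeGeneratorConfig}: the path, invisibly.
#' @export
readGeneratorConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  jts <- lapply(x$joint_tables, function(j) {
    jointBurstTable(genes = unlist(j$genes), both = j$p$both,
                    aOnly = j$p$a_only, bOnly = j$p$b_only,
                    neither = j$p$neither)
  })
  geo <- x$geometry %||% list()
  if (!is.null(geo$nuclei_by_stage)) {
    geo$nucleiByStage <- geo$nuclei_by_stage; geo$nuclei_by_stage <- NULL
  }
  if (!is.null(geo$z_extent)) geo$z_extent <- as.integer(unlist(geo$z_extent))
  generatorConfig(
    name = x$name %||% tools::file_path_sans_ext(basename(path)),
    muscle = x$muscle %||% "NA",
    genes = lapply(x$genes, specFromList),
    jointTables = jts,
    template = x$template %||% "band",
    geometry = snakeToCamel(geo),
    render = snakeToCamel(x$render %||% list()),
    lineage = snakeToCamel(x$lineage %||% list()),
    detection = snakeToCamel(x$detection %||% list()),
    recovery = x$recovery %||% list()
  )
}

#' @rdname readGeneratorConfig
#' @export
writeGeneratorConfig <- function(config, path) {
  x <- list(
    name = config@name, muscle = config@muscle, template = config@template,
    genes = lapply(config@genes, specToList),
    joint_tables = lapply(config@jointTables, function(j) {
      list(genes = as.list(j@genes), p = as.list(j@probabilities))
    }),
    geometry = camelToSnake(config@geometry),
    render = camelToSnake(config@render),
    lineage = camelToSnake(config@lineage),
    detection = camelToSnake(config@detection),
    recovery = config@recovery
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

snakeToCamel <- function(x) {
  if (!length(x)) return(x)
  names(x) <- gsub("_(\\w)", "\\U\\1", names(x), perl = TRUE)
  x
}

camelToSnake <- function(x) {
  if (!length(x)) return(x)
  names(x) <- tolower(gsub("([A-Z])", "_\\1", names(x)))
  x
}

#' Packaged generator configurations
#'
#' The configurations shipped with the package encode, as generator
#' parameters, the summary statistics that the quantification pipeline is
#' expected to recover end-to-end (burst probabilities, the founder-cell
#' intensity multiplier, the duf/col joint burst table, the lineage mixing
#' fraction, the FC positional distribution). See the vignette for the
#' provenance of each number.
#'
#' @param name preset name; call \code{presetNames()} for the list.
#' @return a \code{GeneratorConfig}.
#' @export
presetConfig <- function(name) {
  path <- system.file("extdata", "configs", paste0(name, ".yaml"),
                      package = "fibreFISH")
  if (path == "") stop("unknown preset: ", name, "; see presetNames()")
  readGeneratorConfig(path)
}

#' @rdname presetConfig
#' @export
presetNames <- function() {
  dir <- system.file("extdata", "configs", package = "fibreFISH")
  sort(tools::file_path_sans_ext(list.files(dir, pattern = "\\.yaml$")))
}
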