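# End-to-end simulate -> quantify -> tabulate loops and the
# parameter-recovery harness built on them.

segmentFromFibre <- function(fb) {
  segmentNuclei(projectStack(fb$channels$nuclei, "max"))
}

# segmented nucleus id nearest the ground-truth FC centre
matchFC <- function(nuclei, fb) {
  info <- nucleusInfo(nuclei)
  if (nrow(info) == 0) return(NA_integer_)
  fcXY <- fb$geometry@nuclei[fb$geometry@fcIndex, ]
  d <- sqrt((info$x - fcXY[1])^2 + (info$y - fcXY[2])^2)
  info$nucleus_id[which.min(d)]
}

#' Simulate a cohort and run the quantification pipeline
#'
#' Loops \code{\link{simulateFibre}} over a cohort, then for each fibre
#' segments nuclei from the nuclear channel, quantifies every dot channel,
#' assigns dots to nuclei and derives per-nucleus states. The workhorse
#' behind the recovery experiments; also usable directly.
#'
#' @param config a \code{GeneratorConfig}.
#' @param nFibres number of fibres to simulate.
#' @param stage embryonic stage.
#' @param seed optional seed (set once, before the first fibre).
#' @param profile detection profile override ("standard"/"permissive").
#' @param useTruthNuclei use ground-truth nucleus masks instead of
#'   segmentation.
#' @return list of data.frames: \code{fibres} (per fibre x gene:
#'   n_nuclei, n_dots, total_intden, n_active), \code{dots} (with
#'   nucleus_id and is_fc), \code{states} (long per-nucleus table with
#'   lineage call when a lineage channel exists), \code{coloc}
#'   (per-fibre four-way counts for each configured joint pair).
#' @export
runPipeline <- function(config, nFibres, stage, seed = NULL, profile = NULL,
                        useTruthNuclei = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  genes <- configGenes(config)
  fibresL <- list(); dotsL <- list(); statesL <- list(); colocL <- list()
  for (f in seq_len(nFibres)) {
    fid <- sprintf("f%04d", f)
    fb <- simulateFibre(config, stage, fibreId = fid)
    nuc <- if (useTruthNuclei) {
      new("NucleusSet", labels = fb$masks$nuclei,
          info = labelTable(fb$masks$nuclei))
    } else segmentFromFibre(fb)
    q <- quantifyFibre(fb, config, profile = profile, nuclei = nuc)
    d <- q$dots
    d <- assignDots(d, nuc,
                    maxDistanceFactor = config@detection$maxDistanceFactor)
    fcId <- matchFC(nuc, fb)
    d$is_fc <- !is.na(d$nucleus_id) & !is.na(fcId) & d$nucleus_id %in% fcId
    st <- nucleusStates(d, nuc, genes = genes)
    info <- nucleusInfo(nuc)
    lin <- if (!is.null(fb$channels$lineage)) {
      classifyLineage(nuc, projectStack(fb$channels$lineage, "max"),
                      threshold = config@lineage$threshold)
    } else rep(NA_character_, nrow(info))
    stDf <- data.frame(fibre_id = fid, stage = stage,
                       nucleus_id = info$nucleus_id, x = info$x, y = info$y,
                       is_fc = info$nucleus_id %in% fcId,
                       lineage_label = lin, stringsAsFactors = FALSE)
    for (g in genes) stDf[[paste0("state_", g)]] <- st[, g]
    fi <- q$fibres
    fi$n_active <- vapply(fi$gene, function(g) sum(st[, g]), 0L)
    fibresL[[f]] <- fi
    dotsL[[f]] <- d
    statesL[[f]] <- stDf
    for (jt in config@jointTables) {
      ct <- tabulateCotranscription(st, jt@genes)
      ct <- cbind(fibre_id = fid, stage = stage, ct)
      colocL[[length(colocL) + 1]] <- ct
    }
  }
  list(
    fibres = do.call(rbind, fibresL),
    dots = do.call(rbind, dotsL),
    states = do.call(rbind, statesL),
    coloc = if (length(colocL)) do.call(rbind, colocL) else NULL
  )
}

#' Parameter-recovery measurements
#'
#' Each function simulates a cohort with a configuration, runs the full
#' image pipeline and recovers one of the summary statistics that the
#' configuration encodes. See the vignette for the experimental design.
#'
#' \describe{
#'   \item{recoverFcIntensityRatio}{mean over fibres of (FC-nucleus dot
#'     IntDen) / (mean syncytial-nucleus dot IntDen); fibres lacking either
#'     an FC dot or a syncytial dot are skipped.}
#'   \item{recoverActiveFraction}{mean per-fibre percentage of nuclei
#'     bearing at least one dot of the gene.}
#'   \item{recoverMeanDots}{mean number of detected dots per fibre.}
#'   \item{recoverCotranscription}{pooled union percentage (nuclei
#'     transcribing at least one of the pair) and co-transcription
#'     percentage among active nuclei.}
#'   \item{recoverCentralFraction}{percentage of detected dots classified
#'     into each DA3 subdomain by the spatial chain (max projection frame,
#'     standardisation, rule).}
#'   \item{recoverLabelledFraction}{percentage of lineage-labelled nuclei
#'     (image-based call) among all nuclei within the muscle.}
#' }
#'
#' @param config a \code{GeneratorConfig}.
#' @param nFibres cohort size.
#' @param stage embryonic stage.
#' @param gene gene name (defaults to the config's first gene).
#' @param seed seed for the cohort.
#' @name recovery
NULL

#' @rdname recovery
#' @export
recoverFcIntensityRatio <- function(config, nFibres = 200, stage = 14,
                                    gene = NULL, seed = NULL) {
  if (is.null(gene)) gene <- configGenes(config)[1]
  pl <- runPipeline(config, nFibres, stage, seed = seed)
  d <- pl$dots[pl$dots$gene == gene & !is.na(pl$dots$nucleus_id), ]
  ratios <- vapply(split(d, d$fibre_id), function(df) {
    fcI <- df$intden[df$is_fc]
    syn <- df$intden[!df$is_fc]
    if (length(fcI) == 1 && length(syn) >= 1) fcI / mean(syn) else NA_real_
  }, 0)
  list(ratio = mean(ratios, na.rm = TRUE),
       n = sum(!is.na(ratios)), per_fibre = ratios)
}

#' @rdname recovery
#' @export
recoverActiveFraction <- function(config, nFibres = 200, stage = 15,
                                  gene = NULL, seed = NULL) {
  if (is.null(gene)) gene <- configGenes(config)[1]
  pl <- runPipeline(config, nFibres, stage, seed = seed)
  fi <- pl$fibres[pl$fibres$gene == gene, ]
  fa <- fractionActive(fi, mode = "nuclei")
  list(mean_pct = fa$mean_pct, sem_pct = fa$sem_pct, n = nrow(fi),
       n_nuclei_total = sum(fi$n_nuclei))
}

#' @rdname recovery
#' @export
recoverMeanDots <- function(config, nFibres = 200, stage = 15, gene = NULL,
                            seed = NULL) {
  if (is.null(gene)) gene <- configGenes(config)[1]
  pl <- runPipeline(config, nFibres, stage, seed = seed)
  fi <- pl$fibres[pl$fibres$gene == gene, ]
  list(mean_dots = mean(fi$n_dots),
       sem = stats::sd(fi$n_dots) / sqrt(nrow(fi)), n = nrow(fi))
}

#' @rdname recovery
#' @param genes gene pair for co-transcription (default: the config's first
#'   joint table).
#' @export
recoverCotranscription <- function(config, nFibres = 200, stage = 14,
                                   genes = NULL, seed = NULL) {
  if (is.null(genes)) genes <- config@jointTables[[1]]@genes
  pl <- runPipeline(config, nFibres, stage, seed = seed,
                    profile = "permissive")
  cc <- pl$coloc[pl$coloc$geneA == genes[1] & pl$coloc$geneB == genes[2], ]
  nTot <- sum(cc$n_total)
  nAct <- sum(cc$n_a_only + cc$n_b_only + cc$n_both)
  nBoth <- sum(cc$n_both)
  list(union_pct = 100 * nAct / nTot,
       co_given_active_pct = 100 * nBoth / nAct,
       n_nuclei = nTot, n_active = nAct)
}

#' @rdname recovery
#' @export
recoverCentralFraction <- function(config, nFibres = 200, stage = 14,
                                   gene = NULL, seed = NULL) {
  if (is.null(gene)) gene <- configGenes(config)[1]
  if (!is.null(seed)) set.seed(seed)
  labs <- factor(character(), levels = SUBDOMAINS)
  for (f in seq_len(nFibres)) {
    fb <- simulateFibre(config, stage, fibreId = sprintf("f%04d", f))
    q <- quantifyFibre(fb, config)
    d <- q$dots[q$dots$gene == gene, ]
    if (!nrow(d)) next
    frame <- computeFrame(fb$masks$muscle)
    sc <- standardizeCoords(d, frame)
    labs <- c(labs, classifySubdomain(sc))
  }
  rp <- repartition(labs)
  list(central_pct = unname(rp["central"]), repartition = rp,
       n_dots = length(labs))
}

#' @rdname recovery
#' @export
recoverLabelledFraction <- function(config, nFibres = 200, stage = 15,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nLab <- 0L; nTot <- 0L
  for (f in seq_len(nFibres)) {
    fb <- simulateFibre(config, stage, fibreId = sprintf("f%04d", f))
    nuc <- segmentFromFibre(fb)
    lin <- classifyLineage(nuc, projectStack(fb$channels$lineage, "max"),
                           threshold = config@lineage$threshold)
    ct <- countLabelledNuclei(nuc, lin, fb$masks$muscle)
    nLab <- nLab + ct["n_labelled"]; nTot <- nTot + ct["n_total"]
  }
  list(labelled_pct = 100 * unname(nLab) / unname(nTot),
       n_nuclei = unname(nTot))
}

# configured (generator-side) expectation for each recovery quantity
configuredValue <- function(config, entry) {
  g <- if (!is.null(entry$gene)) geneSpec(config, entry$gene) else NULL
  stage <- as.character(entry$stage)
  switch(entry$quantity,
    fc_intensity_ratio = g@fcMultiplier,
    active_fraction = 100 * g@pOn[[stage]],
    mean_dots = {
      n <- config@geometry$nucleiByStage[[stage]]
      p <- g@pOn[[stage]]
      pFC <- if (is.na(g@pOnFC)) p else g@pOnFC
      if (g@fcRestricted) pFC else (n - 1) * p + pFC
    },
    union_pct = 100 * (1 - config@jointTables[[1]]@probabilities[["neither"]]),
    co_given_active_pct = {
      p <- config@jointTables[[1]]@probabilities
      100 * p[["both"]] / (1 - p[["neither"]])
    },
    central_pct = expectedCentralFraction(config, n = 200000),
    labelled_pct = 100 * config@lineage$pLabelled,
    stop("unknown recovery quantity: ", entry$quantity)
  )
}

# Generator-level expectation of the central-subdomain fraction: samples FC
# positions directly from the configured positional law (no rendering or
# detection) and classifies them against the rasterised template frame.
expectedCentralFraction <- function(config, n = 200000) {
  tmpl <- muscleTemplate(config@template)
  mask <- cachedPolygonMask(tmpl$polygon, tmpl$imageSize)
  frame <- computeFrame(mask)
  r <- config@geometry$nucleusRadius
  bb <- apply(tmpl$polygon, 2, range)
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    cand <- cbind(stats::runif(2 * n, bb[1, 1], bb[2, 1]),
                  stats::runif(2 * n, bb[1, 2], bb[2, 2]))
    cand <- cand[insideEroded(cand, tmpl$polygon, r), , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(n), ]
  sc <- standardizeCoords(pts, frame)
  unname(repartition(classifySubdomain(sc))["central"])
}

#' Run an end-to-end recovery experiment
#'
#' Simulates cohorts with a configuration and checks that the image
#' pipeline recovers each statistic declared in the configuration's
#' \code{recovery} block, within its declared tolerance (relative, or a
#' multiple of the binomial/empirical standard error).
#'
#' @param config a \code{GeneratorConfig} (or preset name).
#' @param nFibres cohort size per quantity.
#' @param seed base seed; quantity k uses \code{seed + k - 1}.
#' @return data.frame: parameter, configured, recovered, tolerance, pass.
#'   Attribute \code{pass} is TRUE when all rows pass.
#' @export
runRecoveryExperiment <- function(config, nFibres = 200, seed = 1) {
  if (is.character(config)) config <- presetConfig(config)
  entries <- config@recovery
  if (!length(entries)) stop("config '", config@name,
                             "' declares no recovery block")
  rows <- list()
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    sd_k <- seed + k - 1
    stage <- e$stage
    conf <- as.numeric(configuredValue(config, e))
    rec <- switch(e$quantity,
      fc_intensity_ratio =
        recoverFcIntensityRatio(config, nFibres, stage, e$gene, sd_k)$ratio,
      active_fraction =
        recoverActiveFraction(config, nFibres, stage, e$gene, sd_k)$mean_pct,
      mean_dots =
        recoverMeanDots(config, nFibres, stage, e$gene, sd_k)$mean_dots,
      union_pct =
        recoverCotranscription(config, nFibres, stage, seed = sd_k)$union_pct,
      co_given_active_pct =
        recoverCotranscription(config, nFibres, stage,
                               seed = sd_k)$co_given_active_pct,
      central_pct =
        recoverCentralFraction(config, nFibres, stage, e$gene,
                               sd_k)$central_pct,
      labelled_pct =
        recoverLabelledFraction(config, nFibres, stage, sd_k)$labelled_pct
    )
    tol <- if (!is.null(e$tolerance_rel)) {
      e$tolerance_rel * abs(conf)
    } else if (!is.null(e$tolerance_se)) {
      # binomial SE on the underlying proportion, expressed in percent
      p <- conf / 100
      nPerFibre <- mean(unlist(
        config@geometry$nucleiByStage[as.character(stage)]))
      nEff <- switch(e$quantity,
        central_pct = nFibres, # one FC dot per fibre
        co_given_active_pct = nFibres * nPerFibre *
          (1 - config@jointTables[[1]]@probabilities[["neither"]]),
        nFibres * nPerFibre)
      e$tolerance_se * 100 * sqrt(p * (1 - p) / nEff)
    } else if (!is.null(e$tolerance_abs)) {
      e$tolerance_abs
    } else stop("recovery entry lacks a tolerance")
    rows[[k]] <- data.frame(
      parameter = paste0(e$quantity, if (!is.null(e$gene))
        paste0("(", e$gene, ")") else ""),
      configured = conf, recovered = rec, tolerance = tol,
      pass = abs(rec - conf) <= tol, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  out
}
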