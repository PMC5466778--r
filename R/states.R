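#' Sample per-nucleus per-gene transcriptional states
#'
#' Draws the ON/OFF transcriptional state of every gene in every nucleus of
#' a fibre, emulating stochastic (asynchronous) bursting:
#' \itemize{
#'   \item genes in a joint burst table are drawn pairwise from the
#'     categorical law over \{both, A only, B only, neither\};
#'   \item FC-restricted genes can be ON only in the founder-cell nucleus,
#'     with probability \code{pOnFC} (default: the stage's \code{pOn});
#'   \item all other genes are independent Bernoulli draws at the stage's
#'     \code{pOn} (the FC nucleus uses \code{pOnFC} when set);
#'   \item exclusion groups are enforced in gene order: once an
#'     earlier-listed gene of a group is ON in a nucleus, later genes of
#'     that group are forced OFF there (so the first-listed gene keeps its
#'     exact marginal; see the vignette).
#' }
#'
#' @param geometry a \code{FibreGeometry}.
#' @param config a \code{GeneratorConfig} (its genes and joint tables are
#'   used; configuration inconsistencies are rejected by the config
#'   validity, e.g. a gene both FC-restricted and in a joint table).
#' @return logical matrix, nuclei x genes (column names = gene names).
#' @export
sampleTranscriptionStates <- function(geometry, config) {
  genes <- configGenes(config)
  n <- nrow(geometry@nuclei)
  states <- matrix(FALSE, n, length(genes), dimnames = list(NULL, genes))
  stage <- as.character(geometry@stage)
  fc <- geometry@fcIndex

  jointGenes <- unlist(lapply(config@jointTables, function(j) j@genes))
  for (jt in config@jointTables) {
    draw <- sample(JOINT_STATES, n, replace = TRUE,
                   prob = jt@probabilities[JOINT_STATES])
    states[, jt@genes[1]] <- draw %in% c("both", "a_only")
    states[, jt@genes[2]] <- draw %in% c("both", "b_only")
  }

  for (g in config@genes) {
    if (g@gene %in% jointGenes) next
    pStage <- g@pOn[[stage]]
    pFC <- if (is.na(g@pOnFC)) pStage else g@pOnFC
    if (g@fcRestricted) {
      states[fc, g@gene] <- stats::runif(1) < pFC
    } else {
      p <- rep(pStage, n)
      p[fc] <- pFC
      states[, g@gene] <- stats::runif(n) < p
    }
  }

  # exclusion groups: earlier-listed gene wins
  groups <- vapply(config@genes, function(g) g@exclusionGroup, "")
  for (grp in unique(groups[!is.na(groups) & groups != "NA"])) {
    members <- genes[which(groups == grp)]
    if (length(members) < 2) next
    taken <- rep(FALSE, n)
    for (m in members) {
      states[, m] <- states[, m] & !taken
      taken <- taken | states[, m]
    }
  }
  states
}
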