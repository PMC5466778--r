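#' Summarise fibre measurements by group
#'
#' Exact sample statistics (mean, SD with n-1 denominator, SEM = SD/sqrt(n),
#' min, max) of dot counts, nuclei counts and Total IntDen per group, plus
#' the same statistics of individual dot integrated densities when a dots
#' table is supplied. Groups with no measurements are omitted with a
#' warning; group ordering is deterministic (sorted keys).
#'
#' @param fibres data.frame of per-fibre measurements (columns
#'   \code{n_dots}, \code{n_nuclei}, \code{total_intden} plus the grouping
#'   keys).
#' @param dots optional data.frame of per-dot records (column
#'   \code{intden} plus the keys).
#' @param by grouping columns, default \code{c("gene", "stage")}.
#' @return data.frame, one row per group per variable: the keys,
#'   \code{variable}, \code{n}, \code{mean}, \code{sd}, \code{sem},
#'   \code{min}, \code{max}.
#' @export
summarizeFibres <- function(fibres, dots = NULL, by = c("gene", "stage")) {
  statRow <- function(v) {
    n <- length(v)
    s <- if (n > 1) stats::sd(v) else 0
    data.frame(n = n, mean = mean(v), sd = s, sem = s / sqrt(n),
               min = min(v), max = max(v))
  }
  oneTable <- function(df, vars) {
    keys <- unique(df[by])
    keys <- keys[do.call(order, keys), , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(keys))) {
      sel <- rep(TRUE, nrow(df))
      for (k in by) sel <- sel & df[[k]] == keys[[k]][i]
      sub <- df[sel, , drop = FALSE]
      if (nrow(sub) == 0L) { warning("empty group omitted"); next }
      for (v in vars) {
        rows[[length(rows) + 1]] <-
          cbind(keys[i, , drop = FALSE], variable = v, statRow(sub[[v]]))
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out <- oneTable(fibres, intersect(c("n_dots", "n_nuclei", "total_intden"),
                                    names(fibres)))
  if (!is.null(dots) && nrow(dots))
    out <- rbind(out, oneTable(dots, "intden"))
  rownames(out) <- NULL
  out
}

#' Significance class of a p-value
#'
#' The star convention: *** for p < 0.001, ** for p < 0.01, * for p < 0.05,
#' ns otherwise.
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of classes.
#' @export
significanceClass <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Unpaired two-sample t test
#'
#' Equal-variance (pooled) unpaired t test by default, Welch optionally.
#' Two groups with zero variance and equal means are reported as t = 0,
#' p = 1 (the degenerate case the underlying test refuses).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) form.
#' @return one-row data.frame: test, statistic, df, p, class.
#' @export
tTestUnpaired <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(data.frame(test = "unpaired t", statistic = 0,
                        df = length(a) + length(b) - 2, p = 1, class = "ns",
                        stringsAsFactors = FALSE))
    }
    stop("both groups constant with different means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  data.frame(test = if (welch) "Welch t" else "unpaired t",
             statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, class = significanceClass(ht$p.value),
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test on active/inactive proportions
#'
#' Pearson's chi-square (no continuity correction) over a k x 2 table of
#' (active, inactive) nucleus counts, df = k - 1, used to compare the
#' fraction of transcribing nuclei between muscles.
#'
#' @param counts k x 2 matrix or data.frame of counts.
#' @return one-row data.frame: test, statistic, df, p, class.
#' @export
chi2Proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero-sum row or column: chi-square undefined")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("all expected counts must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  data.frame(test = "Pearson chi-square", statistic = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value,
             class = significanceClass(ht$p.value), stringsAsFactors = FALSE)
}

#' Percentage of transcribing nuclei
#'
#' Per-fibre percentage of nuclei transcribing a gene, aggregated as mean
#' percentage with its SEM. In \code{"nuclei"} mode the numerator is the
#' number of dot-bearing nuclei (requires a per-fibre \code{n_active}
#' column); in \code{"dots"} mode the dot count stands in for it (the
#' single-gene proxy, flagged in the output).
#'
#' @param perFibre data.frame with columns \code{n_nuclei} and either
#'   \code{n_active} (nuclei mode) or \code{n_dots} (dots mode).
#' @param mode "nuclei" or "dots".
#' @return list: \code{mean_pct}, \code{sem_pct}, \code{mode},
#'   \code{per_fibre_pct}.
#' @export
fractionActive <- function(perFibre, mode = c("nuclei", "dots")) {
  mode <- match.arg(mode)
  if (any(perFibre$n_nuclei <= 0))
    stop("n_nuclei must be positive in every fibre")
  num <- if (mode == "nuclei") {
    if (is.null(perFibre$n_active))
      stop("nuclei mode requires an n_active column")
    perFibre$n_active
  } else perFibre$n_dots
  pct <- 100 * num / perFibre$n_nuclei
  n <- length(pct)
  s <- if (n > 1) stats::sd(pct) else 0
  list(mean_pct = mean(pct), sem_pct = s / sqrt(n), mode = mode,
       per_fibre_pct = pct)
}

#' Export summaries, tests and repartitions as a report
#'
#' Writes \code{summary.csv}, \code{tests.csv}, \code{repartition.csv} and
#' a human-readable \code{report.txt} with run metadata (configuration
#' hash, seed, package version). Re-running with identical inputs produces
#' byte-identical files.
#'
#' @param summaries data.frame from \code{\link{summarizeFibres}} (or NULL).
#' @param tests data.frame of test results (or NULL).
#' @param repartitions data.frame of subdomain percentages (or NULL).
#' @param outDir output directory.
#' @param config optional \code{GeneratorConfig} (hashed into the metadata).
#' @param seed the seed used, recorded in the metadata.
#' @return invisibly, the files written.
#' @export
exportReport <- function(summaries = NULL, tests = NULL, repartitions = NULL,
                         outDir, config = NULL, seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  files <- character()
  wcsv <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(summaries)) wcsv(summaries, "summary.csv")
  if (!is.null(tests)) wcsv(tests, "tests.csv")
  if (!is.null(repartitions)) wcsv(repartitions, "repartition.csv")
  hash <- if (is.null(config)) "none" else {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    writeGeneratorConfig(config, tmp)
    unname(tools::md5sum(tmp))
  }
  lines <- c(
    "fibreFISH report",
    paste0("package version: ",
           as.character(utils::packageVersion("fibreFISH"))),
    paste0("config hash: ", hash),
    paste0("seed: ", seed),
    paste0("note: no multiple-testing correction is applied"),
    "",
    if (!is.null(summaries))
      c("== summaries ==", utils::capture.output(print(summaries)), ""),
    if (!is.null(tests))
      c("== tests ==", utils::capture.output(print(tests)), ""),
    if (!is.null(repartitions))
      c("== repartitions ==", utils::capture.output(print(repartitions)))
  )
  p <- file.path(outDir, "report.txt")
  writeLines(lines, p)
  files <- c(files, p)
  invisible(files)
}
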