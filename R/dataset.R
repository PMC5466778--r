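#' Write a simulated dataset to disk
#'
#' Writes, for each fibre, one multi-page 16-bit TIFF per channel (filename
#' pattern \code{{fibre}_{stage}_{channel}.tif}), 16-bit label-mask TIFFs
#' for the muscle and nuclei (0 = background, k = object k), the ground
#' truth as CSV (\code{ground_truth_nuclei.csv},
#' \code{ground_truth_dots.csv}) and an echo of the configuration as YAML.
#' Channel values must be integers in [0, 65535] (the generator's default
#' quantisation guarantees this), so re-reading reproduces the arrays
#' bit-exactly.
#'
#' @param fibres list of fibre objects from \code{\link{simulateFibre}} /
#'   \code{\link{renderStack}}.
#' @param outDir output directory (created if missing).
#' @param config the \code{GeneratorConfig} to echo (optional).
#' @return invisibly, the vector of files written.
#' @export
writeDataset <- function(fibres, outDir, config = NULL) {
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  written <- character()
  wr16 <- function(pages, path) {
    mx <- max(vapply(pages, max, 0))
    if (mx > 65535)
      stop("pixel values exceed 16-bit range in ", path)
    if (any(vapply(pages, function(p) any(p != round(p) | p < 0), TRUE)))
      stop("non-integer or negative pixel values in ", path,
           "; enable render quantisation")
    res <- try(tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                               bits.per.sample = 16L), silent = TRUE)
    if (inherits(res, "try-error"))
      stop("TIFF write failed for ", path, ": ", attr(res, "condition")$message)
    written <<- c(written, path)
  }
  nucAll <- list(); dotAll <- list()
  for (fb in fibres) {
    id <- fb$truth$nuclei$fibre_id[1]
    stage <- fb$geometry@stage
    for (chn in names(fb$channels)) {
      a <- fb$channels[[chn]]
      pages <- lapply(seq_len(dim(a)[3]), function(z) a[, , z])
      wr16(pages, file.path(outDir,
                            sprintf("%s_%d_%s.tif", id, stage, chn)))
    }
    wr16(list(fb$masks$muscle),
         file.path(outDir, sprintf("%s_%d_mask_muscle.tif", id, stage)))
    wr16(list(fb$masks$nuclei),
         file.path(outDir, sprintf("%s_%d_mask_nuclei.tif", id, stage)))
    nucAll[[length(nucAll) + 1]] <- fb$truth$nuclei
    dotAll[[length(dotAll) + 1]] <- fb$truth$dots
  }
  p <- file.path(outDir, "ground_truth_nuclei.csv")
  utils::write.csv(do.call(rbind, nucAll), p, row.names = FALSE)
  written <- c(written, p)
  p <- file.path(outDir, "ground_truth_dots.csv")
  utils::write.csv(do.call(rbind, dotAll), p, row.names = FALSE)
  written <- c(written, p)
  if (!is.null(config)) {
    p <- file.path(outDir, "config.yaml")
    writeGeneratorConfig(config, p)
    written <- c(written, p)
  }
  invisible(written)
}

#' Read a TIFF stack or mask written by \code{writeDataset}
#'
#' @param path TIFF file path.
#' @return for multi-page files a 3-D array (height, width, slices), for
#'   single-page files a matrix, in the original integer grey levels.
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) round(p * 65535))
  if (length(pages) == 1L) return(pages[[1]])
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) a[, , z] <- pages[[z]]
  a
}
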