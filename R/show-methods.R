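setMethod("show", "GeneBurstSpec", function(object) {
  cat("GeneBurstSpec for", object@gene,
      if (object@fcRestricted) "(FC-restricted)" else "", "\n")
  cat("  p(ON) by stage:",
      paste(names(object@pOn), signif(object@pOn, 3), sep = "=", collapse = " "),
      "\n")
  if (!is.na(object@pOnFC)) cat("  p(ON) in FC:", object@pOnFC, "\n")
  cat("  intensity: mean", object@intensityMean, "AU, CV", object@intensityCV,
      if (object@fcMultiplier != 1)
        paste0(", FC x", object@fcMultiplier) else "", "\n")
  if (!is.na(object@exclusionGroup))
    cat("  exclusion group:", object@exclusionGroup, "\n")
})

setMethod("show", "JointBurstTable", function(object) {
  cat("JointBurstTable:", object@genes[1], "/", object@genes[2], "\n")
  p <- object@probabilities[JOINT_STATES]
  cat(" ", paste(JOINT_STATES, signif(p, 3), sep = "=", collapse = "  "), "\n")
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig '", object@name, "' (muscle ", object@muscle,
      ", template ", object@template, ")\n", sep = "")
  cat("  genes:", paste(vapply(object@genes, function(g) g@gene, ""),
                        collapse = ", "), "\n")
  if (length(object@jointTables))
    cat("  joint tables:",
        paste(vapply(object@jointTables,
                     function(j) paste(j@genes, collapse = "/"), ""),
              collapse = ", "), "\n")
  nb <- object@geometry$nucleiByStage
  cat("  nuclei by stage:",
      paste(names(nb), unlist(nb), sep = "=", collapse = " "), "\n")
})

setMethod("show", "FibreGeometry", function(object) {
  cat("FibreGeometry: stage", object@stage, "-", nrow(object@nuclei),
      "nuclei (FC at index", object@fcIndex, ")\n")
  cat("  image", object@imageSize[1], "x", object@imageSize[2],
      "px,", object@nSlices, "slices, fibre in Z",
      object@zExtent[1], "..", object@zExtent[2], "\n")
})

setMethod("show", "MuscleFrame", function(object) {
  br <- object@boundingRect
  cat("MuscleFrame: area", object@area, "px^2, centroid (",
      round(object@centroid[1], 2), ",", round(object@centroid[2], 2), ")\n")
  cat("  bounding rect x =", br[1], "y =", br[2],
      "w =", br[3], "h =", br[4], "\n")
  a <- brAnt(object); p <- brPost(object)
  cat("  BRant (", a[1], ",", a[2], ")  BRpost (", p[1], ",", p[2], ")\n")
})

setMethod("show", "NucleusSet", function(object) {
  cat("NucleusSet:", nrow(object@info), "nuclei on a",
      nrow(object@labels), "x", ncol(object@labels), "grid\n")
})
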