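#' @rdname PathwayFactors-class
#' @aliases factorScores,PathwayFactors-method
setMethod("factorScores", "PathwayFactors", function(x) x@scores)

#' @rdname PathwayFactors-class
setMethod("pathwayNames", "PathwayFactors", function(x) x@pathwayNames)

#' @rdname PathwayFactors-class
setMethod("clipBound", "PathwayFactors", function(x) x@clipBound)

#' @rdname PathwayFactors-class
setMethod("show", "PathwayFactors", function(object) {
  cat("PathwayFactors:", nrow(object@scores), "cells x",
      ncol(object@scores), "factor columns\n")
  cat("  pathways:", length(object@pathwayNames),
      " factors per pathway:", object@nFactors,
      " clip bound: +/-", object@clipBound, "\n")
})

#' @rdname ClusteringRun-class
setMethod("latentCoords", "ClusteringRun", function(x) x@latent)

#' @rdname ClusteringRun-class
setMethod("clusterLabels", "ClusteringRun", function(x) {
  stats::setNames(x@labels, rownames(x@latent))
})

#' @rdname ClusteringRun-class
setMethod("nClusters", "ClusteringRun", function(x) x@k)

#' @rdname ClusteringRun-class
setMethod("backendName", "ClusteringRun", function(x) x@backendName)

#' @rdname ClusteringRun-class
setMethod("show", "ClusteringRun", function(object) {
  cat("ClusteringRun:", nrow(object@latent), "cells,",
      ncol(object@latent), "latent dims, k =", object@k,
      "(", object@backendName, ", seed", object@seed, ")\n")
  cat("  cluster sizes:", paste(tabulate(object@labels, object@k),
      collapse = " "), "\n")
})

#' @rdname TrajectoryTree-class
setMethod("treeParents", "TrajectoryTree", function(x) x@parent)

#' @rdname TrajectoryTree-class
setMethod("treeClusters", "TrajectoryTree", function(x) x@clusterIndex)

#' @rdname TrajectoryTree-class
setMethod("treeCenters", "TrajectoryTree", function(x) x@centers)

#' @rdname TrajectoryTree-class
setMethod("treePseudotime", "TrajectoryTree", function(x) x@meanPseudotime)

#' @rdname TrajectoryTree-class
setMethod("treeMembers", "TrajectoryTree", function(x) x@memberCells)

#' @rdname TrajectoryTree-class
setMethod("treeEdgeWeights", "TrajectoryTree", function(x) x@edgeWeights)

#' @rdname TrajectoryTree-class
setMethod("nSwaps", "TrajectoryTree", function(x) x@swaps)

#' @rdname TrajectoryTree-class
setMethod("show", "TrajectoryTree", function(object) {
  n <- length(object@parent)
  cat("TrajectoryTree:", n, "cluster positions,",
      sum(!is.na(object@parent)), "edges,",
      object@swaps, "fine-tune swaps\n")
  root <- which(is.na(object@parent))
  cat("  root cluster:", object@clusterIndex[root], "\n")
  if (n > 1L) {
    e <- which(!is.na(object@parent))
    cat("  edges (parent -> child cluster):",
        paste(sprintf("%d->%d", object@clusterIndex[object@parent[e]],
                      object@clusterIndex[e]), collapse = ", "), "\n")
  }
})

#' @rdname TrajectoryTopology-class
setMethod("milestones", "TrajectoryTopology", function(x) x@milestones)

#' @rdname TrajectoryTopology-class
setMethod("milestoneParents", "TrajectoryTopology", function(x) x@parents)

#' @rdname TrajectoryTopology-class
setMethod("milestoneRoot", "TrajectoryTopology", function(x) x@root)

#' @rdname TrajectoryTopology-class
setMethod("show", "TrajectoryTopology", function(object) {
  cat("TrajectoryTopology:", length(object@milestones),
      "milestones, root", object@root, "\n")
  if (length(object@parents))
    cat("  edges:", paste(sprintf("%s->%s", object@parents,
        names(object@parents)), collapse = ", "), "\n")
})
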