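#' @rdname PathwayFactors-class
#' @param object,x an object.
#' @export
setGeneric("factorScores", function(x) standardGeneric("factorScores"))

#' @rdname PathwayFactors-class
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname PathwayFactors-class
#' @export
setGeneric("clipBound", function(x) standardGeneric("clipBound"))

#' @rdname ClusteringRun-class
#' @param x an object.
#' @export
setGeneric("latentCoords", function(x) standardGeneric("latentCoords"))

#' @rdname ClusteringRun-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusteringRun-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusteringRun-class
#' @export
setGeneric("backendName", function(x) standardGeneric("backendName"))

#' @rdname TrajectoryTree-class
#' @param x an object.
#' @export
setGeneric("treeParents", function(x) standardGeneric("treeParents"))

#' @rdname TrajectoryTree-class
#' @export
setGeneric("treeClusters", function(x) standardGeneric("treeClusters"))

#' @rdname TrajectoryTree-class
#' @export
setGeneric("treeCenters", function(x) standardGeneric("treeCenters"))

#' @rdname TrajectoryTree-class
#' @export
setGeneric("treePseudotime", function(x) standardGeneric("treePseudotime"))

#' @rdname TrajectoryTree-class
#' @export
setGeneric("treeMembers", function(x) standardGeneric("treeMembers"))

#' @rdname TrajectoryTree-class
#' @export
setGeneric("treeEdgeWeights", function(x) standardGeneric("treeEdgeWeights"))

#' @rdname TrajectoryTree-class
#' @export
setGeneric("nSwaps", function(x) standardGeneric("nSwaps"))

#' @rdname TrajectoryTopology-class
#' @param x an object.
#' @export
setGeneric("milestones", function(x) standardGeneric("milestones"))

#' @rdname TrajectoryTopology-class
#' @export
setGeneric("milestoneParents", function(x) standardGeneric("milestoneParents"))

#' @rdname TrajectoryTopology-class
#' @export
setGeneric("milestoneRoot", function(x) standardGeneric("milestoneRoot"))

#' Embed features into a latent space
#'
#' Backend-dispatched dimension reduction. See [embedCells()] for the
#' user-facing wrapper.
#'
#' @param backend an [EmbedClusterBackend-class] object.
#' @param features numeric matrix, cells in rows.
#' @param d target latent dimensionality.
#' @param seed integer seed.
#' @return numeric matrix, cells in rows, at most `d` columns, centered.
#' @export
setGeneric("backendEmbed",
  function(backend, features, d = 15L, seed = 1L)
    standardGeneric("backendEmbed"))

#' Cluster cells in a latent space
#'
#' Backend-dispatched clustering into exactly `k` nonempty clusters. See
#' [clusterFixedK()] for the user-facing wrapper.
#'
#' @param backend an [EmbedClusterBackend-class] object.
#' @param latent numeric matrix, cells in rows.
#' @param k number of clusters.
#' @param seed integer seed.
#' @return integer vector of 1-based labels, one per cell.
#' @export
setGeneric("backendCluster",
  function(backend, latent, k, seed = 1L)
    standardGeneric("backendCluster"))

#' Base-2 log rescaling of an expression matrix
#'
#' Repeatedly replaces every entry `x` by `log2(x + 1)` until the global
#' range (max minus min over all entries) falls below `rangeThreshold`.
#' A matrix already within range is returned unchanged; the operation is
#' idempotent and preserves the within-gene rank order of cells.
#'
#' @param x a nonnegative numeric matrix (any orientation; the transform is
#'   elementwise) or a [SingleCellExperiment::SingleCellExperiment-class]
#'   whose `counts` assay is transformed.
#' @param rangeThreshold positive numeric; iteration stops when the global
#'   range is strictly below this (default 100).
#' @return An object of the same class as `x` with the rescaled values.
#' @examples
#' m <- matrix(c(0, 1023), 1)
#' logRescale(m)  # one pass: c(0, 10)
#' @export
setGeneric("logRescale",
  function(x, rangeThreshold = 100) standardGeneric("logRescale"))

#' Gene quality control by expressed fraction
#'
#' Keeps a gene if and only if it is expressed (value > 0) in at least
#' `minExpressedFraction` of cells; genes expressed in strictly fewer cells
#' are removed. Retained values are untouched and gene order is preserved.
#'
#' @param x a numeric matrix with cells in rows and genes in columns, or a
#'   [SingleCellExperiment::SingleCellExperiment-class] (genes in rows).
#' @param minExpressedFraction fraction in (0, 1]; default 0.2, i.e. genes
#'   expressed in less than 20\% of cells are dropped.
#' @return Same class as `x`, with failing genes removed.
#' @export
setGeneric("filterGenes",
  function(x, minExpressedFraction = 0.2) standardGeneric("filterGenes"))

#' Intersect an expression matrix with pathway gene sets
#'
#' For each gene set, extracts the submatrix of matching genes; pathways
#' matching fewer than `minPathwayGenes` genes are dropped. Gene-set order
#' is preserved.
#'
#' @param x a numeric matrix (cells in rows, genes in columns) or a
#'   [SingleCellExperiment::SingleCellExperiment-class].
#' @param geneSets named list of character vectors (see [readGeneSets()]).
#' @param minPathwayGenes minimum number of matched genes for a pathway to
#'   survive (default 10, threshold inclusive: exactly 10 matches is kept).
#' @return Named list of cells-by-matched-genes matrices, one per surviving
#'   pathway, in gene-set order.
#' @export
setGeneric("intersectPathways",
  function(x, geneSets, minPathwayGenes = 10L)
    standardGeneric("intersectPathways"))

#' Pathway factor features from an expression matrix
#'
#' Convenience composition of [intersectPathways()], [factorizePathway()]
#' and [assembleFactors()].
#'
#' @param x preprocessed expression (matrix, cells in rows, or a
#'   [SingleCellExperiment::SingleCellExperiment-class]).
#' @param geneSets named list of character vectors.
#' @param minPathwayGenes pathway-survival threshold (default 10).
#' @param nFactors factors per pathway (default 2).
#' @param clipBound clipping bound for factor scores (default 5).
#' @param seed integer seed (kept for contract symmetry; extraction is
#'   deterministic).
#' @return A [PathwayFactors-class] object.
#' @export
setGeneric("pathwayFactors",
  function(x, geneSets, minPathwayGenes = 10L, nFactors = 2L,
           clipBound = 5, seed = 1L)
    standardGeneric("pathwayFactors"))
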