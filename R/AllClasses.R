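#' @import methods
#' @importFrom stats cor dist kmeans prcomp factanal sd rnorm rpois runif
#' @importFrom utils read.csv read.delim write.table modifyList
NULL

#' Pathway factor-score matrix
#'
#' Cells-by-factors matrix obtained by per-pathway factor analysis of a
#' preprocessed expression matrix: each surviving pathway contributes
#' `nFactors` score columns (two by default), and every entry is clipped to
#' `[-clipBound, clipBound]`. This is the feature space fed to the embedding
#' and clustering backend.
#'
#' @slot scores numeric matrix, cells in rows, `nFactors * P` columns for
#'   `P` surviving pathways; row names are cell identifiers.
#' @slot pathwayNames character vector of the `P` surviving pathway names,
#'   in input gene-set order.
#' @slot nFactors integer, factors extracted per pathway.
#' @slot clipBound positive numeric; all scores lie within `[-clipBound,
#'   clipBound]`.
#'
#' @seealso [pathwayFactors()], [assembleFactors()]
#' @exportClass PathwayFactors
setClass("PathwayFactors",
  representation(
    scores = "matrix",
    pathwayNames = "character",
    nFactors = "integer",
    clipBound = "numeric"
  )
)

setValidity("PathwayFactors", function(object) {
  msg <- character()
  if (length(object@clipBound) != 1L || object@clipBound <= 0)
    msg <- c(msg, "clipBound must be a single positive number")
  if (ncol(object@scores) != object@nFactors * length(object@pathwayNames))
    msg <- c(msg, "column count must equal nFactors * number of pathways")
  if (length(object@scores) &&
      max(abs(object@scores)) > object@clipBound + 1e-8)
    msg <- c(msg, "scores exceed the clip bound")
  if (anyDuplicated(object@pathwayNames))
    msg <- c(msg, "pathway names must be unique")
  if (length(msg)) msg else TRUE
})

#' One clustering of cells in a latent space
#'
#' The result of a single backend run: latent coordinates for every cell and
#' a partition of the cells into `k` nonempty clusters. Cluster labels are
#' 1-based integers in `1..k`.
#'
#' @slot latent numeric matrix, cells in rows (row names = cell ids).
#' @slot labels integer vector, one label per cell, values in `1..k`.
#' @slot k integer, number of clusters.
#' @slot backendName character, name of the backend that produced the run.
#' @slot seed integer seed the run was produced under.
#'
#' @seealso [clusterFixedK()], [clusterAuto()]
#' @exportClass ClusteringRun
setClass("ClusteringRun",
  representation(
    latent = "matrix",
    labels = "integer",
    k = "integer",
    backendName = "character",
    seed = "integer"
  )
)

setValidity("ClusteringRun", function(object) {
  msg <- character()
  if (nrow(object@latent) != length(object@labels))
    msg <- c(msg, "latent row count must equal number of labels")
  if (length(object@labels)) {
    if (min(object@labels) < 1L || max(object@labels) > object@k)
      msg <- c(msg, "labels must lie in 1..k")
    if (length(unique(object@labels)) != object@k)
      msg <- c(msg, "every cluster must be nonempty")
  }
  if (length(msg)) msg else TRUE
})

#' Milestone topology of a simulated trajectory
#'
#' A rooted tree over named developmental milestones (stages); the latent
#' skeleton that [simulateTrajectory()] arranges cells along.
#'
#' @slot milestones character, ordered stage names.
#' @slot parents named character: for every non-root milestone, its parent.
#' @slot root character, the root milestone.
#'
#' @seealso [linearTopology()], [bifurcationTopology()], [treeTopology()]
#' @exportClass TrajectoryTopology
setClass("TrajectoryTopology",
  representation(
    milestones = "character",
    parents = "character",
    root = "character"
  )
)

setValidity("TrajectoryTopology", function(object) {
  m <- object@milestones
  p <- object@parents
  msg <- character()
  if (anyDuplicated(m)) msg <- c(msg, "milestone names must be unique")
  if (!(object@root %in% m)) msg <- c(msg, "root must be a milestone")
  nonroot <- setdiff(m, object@root)
  if (!setequal(names(p), nonroot))
    msg <- c(msg, "parents must be named by every non-root milestone")
  if (!all(p %in% m)) msg <- c(msg, "every parent must be a milestone")
  # rooted tree: walking parent pointers from any node must reach the root
  if (!length(msg)) {
    for (v in nonroot) {
      seen <- character()
      while (v != object@root) {
        if (v %in% seen) {
          msg <- c(msg, "parent pointers contain a cycle")
          break
        }
        seen <- c(seen, v)
        v <- p[[v]]
      }
      if (length(msg)) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Rooted cluster-level trajectory tree
#'
#' A rooted tree whose positions carry cluster payloads (cluster index,
#' latent center, mean pseudotime, member cells) and whose edge weights are
#' the Euclidean distances between the centers of the payloads at the edge's
#' endpoints. The tree shape (parent pointers) is fixed; fine-tuning permutes
#' the payloads across positions.
#'
#' @slot parent integer vector; `parent[i]` is the position index of the
#'   parent of position `i`, `NA` for the root.
#' @slot clusterIndex integer vector; cluster id of the payload at each
#'   position.
#' @slot centers numeric matrix, one row per position: the latent center of
#'   the payload currently at that position.
#' @slot meanPseudotime numeric vector; mean ensemble pseudotime of the
#'   payload at each position.
#' @slot memberCells list of character vectors; member cell ids of the
#'   payload at each position.
#' @slot edgeWeights numeric vector; `edgeWeights[i]` is the weight of the
#'   edge from `parent[i]` to `i` (`NA` at the root).
#' @slot swaps integer; number of payload swaps applied by [finetuneMST()]
#'   (0 for a freshly built tree).
#'
#' @seealso [buildMST()], [finetuneMST()], [inferTrajectory()]
#' @exportClass TrajectoryTree
setClass("TrajectoryTree",
  representation(
    parent = "integer",
    clusterIndex = "integer",
    centers = "matrix",
    meanPseudotime = "numeric",
    memberCells = "list",
    edgeWeights = "numeric",
    swaps = "integer"
  )
)

setValidity("TrajectoryTree", function(object) {
  n <- length(object@parent)
  msg <- character()
  if (sum(is.na(object@parent)) != 1L)
    msg <- c(msg, "exactly one root (NA parent) required")
  if (length(object@clusterIndex) != n || nrow(object@centers) != n ||
      length(object@meanPseudotime) != n ||
      length(object@memberCells) != n || length(object@edgeWeights) != n)
    msg <- c(msg, "all per-position slots must have one entry per position")
  if (anyDuplicated(object@clusterIndex))
    msg <- c(msg, "cluster indices must be unique across positions")
  if (!length(msg) && n > 1L) {
    # connectivity: every node reaches the root
    root <- which(is.na(object@parent))
    for (i in seq_len(n)) {
      v <- i
      steps <- 0L
      while (!is.na(object@parent[v])) {
        v <- object@parent[v]
        steps <- steps + 1L
        if (steps > n) {
          msg <- c(msg, "parent pointers contain a cycle")
          break
        }
      }
      if (length(msg)) break
      if (v != root) {
        msg <- c(msg, "tree is not connected")
        break
      }
    }
    # edge weights consistent with payload centers
    if (!length(msg)) {
      for (i in seq_len(n)) {
        p <- object@parent[i]
        if (is.na(p)) next
        w <- sqrt(sum((object@centers[i, ] - object@centers[p, ])^2))
        if (abs(w - object@edgeWeights[i]) > 1e-8 * max(1, w)) {
          msg <- c(msg, "edge weight inconsistent with payload centers")
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Virtual embedding/clustering backend
#'
#' Contract for the dimension-reduction + clustering engine used by the
#' pipeline. A backend must provide methods for [backendEmbed()] and
#' [backendCluster()]; everything downstream (ensemble pseudotime, trajectory
#' construction) only touches that surface, so any conforming implementation
#' can be swapped in.
#'
#' @slot name character, human-readable backend name (recorded in run
#'   metadata).
#' @exportClass EmbedClusterBackend
setClass("EmbedClusterBackend",
  representation("VIRTUAL", name = "character"))

#' Default backend: truncated PCA + k-means
#'
#' @slot nstart integer, number of k-means restarts.
#' @exportClass PCAKmeansBackend
setClass("PCAKmeansBackend",
  contains = "EmbedClusterBackend",
  representation(nstart = "integer"))

#' @describeIn PCAKmeansBackend-class Construct the default backend.
#' @param nstart integer, number of k-means restarts (default 10).
#' @return A `PCAKmeansBackend` object.
#' @export
pcaKmeansBackend <- function(nstart = 10L) {
  new("PCAKmeansBackend", name = "pca_kmeans", nstart = as.integer(nstart))
}
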