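## Ensemble pseudotime: for each clustering resolution k, cells in the
## start cluster get pseudotime 0 and every other cell inherits the
## Euclidean distance from its cluster's center to the start cluster's
## center; the per-resolution vectors are averaged element-wise.

#' Start cluster of a clustering run
#'
#' The cluster label occurring most often among the supplied start cells
#' (the mode); ties go to the smallest cluster index.
#'
#' @param run a [ClusteringRun-class].
#' @param startCells nonempty character vector of cell identifiers, all
#'   present in the run.
#' @return Integer cluster index in `1..k`.
#' @export
startCluster <- function(run, startCells) {
  if (!length(startCells)) stop("start-cell list is empty", call. = FALSE)
  labels <- clusterLabels(run)
  missing <- setdiff(startCells, names(labels))
  if (length(missing))
    stop("start cells not present in the data: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  counts <- tabulate(labels[startCells], nbins = nClusters(run))
  which.max(counts)  # ties: smallest index
}

.clusterCenters <- function(run) {
  latent <- latentCoords(run)
  labels <- run@labels
  k <- nClusters(run)
  centers <- matrix(0, k, ncol(latent))
  for (c in seq_len(k))
    centers[c, ] <- colMeans(latent[labels == c, , drop = FALSE])
  centers
}

#' Per-cell pseudotime from one clustering run
#'
#' Cluster centers are the arithmetic means of their member cells' latent
#' coordinates. Every cell's pseudotime is the Euclidean distance from its
#' cluster's center to the start cluster's center; cells in the start
#' cluster get exactly 0.
#'
#' @param run a [ClusteringRun-class].
#' @param start integer start-cluster index (see [startCluster()]).
#' @return Named nonnegative numeric vector, one value per cell.
#' @export
clusterPseudotime <- function(run, start) {
  k <- nClusters(run)
  if (start < 1L || start > k)
    stop("start cluster out of range", call. = FALSE)
  centers <- .clusterCenters(run)
  d <- sqrt(colSums((t(centers) - centers[start, ])^2))
  d[start] <- 0  # exact zero for the start cluster
  stats::setNames(d[run@labels], rownames(latentCoords(run)))
}

.ensembleFromLatent <- function(latent, startCells, kMin, kMax, seed,
                                backend, normalizeRuns = FALSE) {
  kMin <- as.integer(kMin)
  kMax <- as.integer(kMax)
  if (kMin < 2L || kMax < kMin)
    stop("need kMax >= kMin >= 2", call. = FALSE)
  if (kMax > nrow(latent))
    stop("kMax exceeds the number of cells", call. = FALSE)
  total <- NULL
  for (k in kMin:kMax) {
    run <- clusterFixedK(latent, k, seed = seed + k, backend = backend)
    sc <- startCluster(run, startCells)
    pt <- clusterPseudotime(run, sc)
    if (normalizeRuns && max(pt) > 0) pt <- pt / max(pt)
    total <- if (is.null(total)) pt else total + pt
  }
  total / (kMax - kMin + 1L)
}

#' Ensemble pseudotime over multiple clustering resolutions
#'
#' Embeds the features once, then for every `k` in `[kMin, kMax]` clusters
#' the shared latent space, computes per-cell pseudotime from the start
#' cluster ([clusterPseudotime()]), and averages the per-resolution vectors
#' element-wise. Per-run seeds are derived as `seed + k`, so runs differ but
#' the whole ensemble is deterministic given `seed`.
#'
#' @param features a [PathwayFactors-class] or numeric matrix (cells in
#'   rows, row names = cell ids).
#' @param startCells character vector of start-cell identifiers.
#' @param kMin,kMax clustering resolution range (defaults 5 and 10).
#' @param d latent dimensionality for the shared embedding (default 15).
#' @param seed integer seed.
#' @param backend an [EmbedClusterBackend-class].
#' @param normalizeRuns if `TRUE`, rescale each per-resolution vector to
#'   maximum 1 before averaging (default `FALSE`: plain element-wise mean).
#' @return Named nonnegative numeric vector; start cells are exactly 0.
#' @export
ensemblePseudotime <- function(features, startCells, kMin = 5L, kMax = 10L,
                               d = 15L, seed = 1L,
                               backend = pcaKmeansBackend(),
                               normalizeRuns = FALSE) {
  latent <- embedCells(features, d = d, seed = seed, backend = backend)
  .ensembleFromLatent(latent, startCells, kMin, kMax, seed, backend,
                      normalizeRuns)
}
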