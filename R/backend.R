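## Default embedding/clustering backend: truncated, sign-fixed PCA for the
## latent space; k-means (k-means++-like multiple restarts via nstart) for
## clustering; mean silhouette width for automatic cluster-number selection.
## The backend surface (backendEmbed / backendCluster) is the only thing
## downstream code touches, so any conforming implementation can be
## substituted.

#' @rdname backendEmbed
#' @export
setMethod("backendEmbed", "PCAKmeansBackend",
  function(backend, features, d = 15L, seed = 1L) {
    if (!nrow(features) || !ncol(features))
      stop("empty feature matrix", call. = FALSE)
    d <- as.integer(d)
    if (d < 1L) stop("d must be >= 1", call. = FALSE)
    if (ncol(features) < d) {
      warning("latent dimension lowered to feature count (",
              ncol(features), ")", call. = FALSE)
      d <- ncol(features)
    }
    p <- stats::prcomp(features, center = TRUE, scale. = FALSE)
    d <- min(d, ncol(p$x))
    latent <- p$x[, seq_len(d), drop = FALSE]
    # PCA sign indeterminacy: largest-|rotation| entry of each axis positive
    for (j in seq_len(d)) {
      r <- p$rotation[, j]
      if (r[which.max(abs(r))] < 0) latent[, j] <- -latent[, j]
    }
    rownames(latent) <- rownames(features)
    colnames(latent) <- paste0("L", seq_len(d))
    latent
  })

#' @rdname backendCluster
#' @export
setMethod("backendCluster", "PCAKmeansBackend",
  function(backend, latent, k, seed = 1L) {
    n <- nrow(latent)
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1", call. = FALSE)
    if (k > n) stop("k exceeds the number of cells", call. = FALSE)
    if (k == 1L) return(rep(1L, n))
    if (k == n) return(seq_len(n))
    withr::with_seed(seed, {
      km <- stats::kmeans(latent, centers = k, nstart = backend@nstart,
                          iter.max = 100L)
      as.integer(km$cluster)
    })
  })

#' Embed pathway factors into a latent space
#'
#' User-facing wrapper around [backendEmbed()]. The latent is centered and
#' deterministic given the seed; if the feature matrix has fewer than `d`
#' columns, `d` is lowered with a warning.
#'
#' @param features a [PathwayFactors-class] or numeric matrix (cells in
#'   rows).
#' @param d latent dimensionality (default 15).
#' @param seed integer seed.
#' @param backend an [EmbedClusterBackend-class] (default
#'   [pcaKmeansBackend()]).
#' @return Numeric matrix, cells x (at most `d`).
#' @export
embedCells <- function(features, d = 15L, seed = 1L,
                       backend = pcaKmeansBackend()) {
  if (methods::is(features, "PathwayFactors"))
    features <- factorScores(features)
  backendEmbed(backend, features, d = d, seed = seed)
}

.makeRun <- function(latent, labels, k, backend, seed) {
  new("ClusteringRun", latent = latent, labels = as.integer(labels),
      k = as.integer(k), backendName = backend@name,
      seed = as.integer(seed))
}

#' Cluster a latent space into exactly k clusters
#'
#' @param latent numeric matrix, cells in rows (row names = cell ids).
#' @param k number of clusters (`k <=` number of cells).
#' @param seed integer seed.
#' @param backend an [EmbedClusterBackend-class].
#' @return A [ClusteringRun-class] with exactly `k` nonempty clusters;
#'   deterministic given the seed.
#' @export
clusterFixedK <- function(latent, k, seed = 1L,
                          backend = pcaKmeansBackend()) {
  labels <- backendCluster(backend, latent, k = k, seed = seed)
  .makeRun(latent, labels, k, backend, seed)
}

.meanSilhouette <- function(labels, dmat) {
  sil <- cluster::silhouette(labels, dmatrix = dmat)
  mean(sil[, "sil_width"])
}

#' Cluster with automatic selection of the cluster number
#'
#' Runs the backend for every `k` in `[kMin, kMax]` and keeps the partition
#' maximizing the mean silhouette width; ties go to the smallest `k`. With
#' `kMin == kMax` that `k` is used without a search.
#'
#' @param latent numeric matrix, cells in rows.
#' @param kMin,kMax search range (defaults 2 and 15). `kMax` is capped at
#'   one less than the number of distinct latent points.
#' @param seed integer seed.
#' @param backend an [EmbedClusterBackend-class].
#' @return A [ClusteringRun-class].
#' @export
clusterAuto <- function(latent, kMin = 2L, kMax = 15L, seed = 1L,
                        backend = pcaKmeansBackend()) {
  n <- nrow(latent)
  kMin <- as.integer(kMin)
  kMax <- as.integer(kMax)
  if (kMax > n) stop("kMax exceeds the number of cells", call. = FALSE)
  nDistinct <- nrow(unique(latent))
  if (nDistinct < 2L)
    stop("degenerate latent space: all points identical", call. = FALSE)
  if (kMin == kMax) {
    labels <- backendCluster(backend, latent, k = kMin, seed = seed)
    return(.makeRun(latent, labels, kMin, backend, seed))
  }
  kGrid <- seq(max(2L, kMin), min(kMax, nDistinct - 1L, n - 1L))
  if (!length(kGrid))
    stop("no feasible cluster number in the requested range", call. = FALSE)
  dmat <- as.matrix(stats::dist(latent))
  best <- NULL
  bestSil <- -Inf
  for (k in kGrid) {
    labels <- backendCluster(backend, latent, k = k, seed = seed)
    s <- .meanSilhouette(labels, dmat)
    if (s > bestSil + 1e-12) {  # strict improvement: ties keep smallest k
      bestSil <- s
      best <- list(labels = labels, k = k)
    }
  }
  .makeRun(latent, best$labels, best$k, backend, seed)
}
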