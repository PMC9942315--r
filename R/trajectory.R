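## Cluster-level trajectory: minimum spanning tree over cluster centers
## (complete Euclidean graph), rooted at the start cluster, then fine-tuned
## so that mean pseudotime never decreases from a position towards its
## descendants.

.kruskalMST <- function(D) {
  # Deterministic Kruskal: edges sorted by (weight, smaller index, larger
  # index), union-find. Returns 2-column matrix of tree edges.
  n <- nrow(D)
  if (n < 2L) return(matrix(integer(), 0, 2))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  edges <- matrix(integer(), n - 1L, 2)
  taken <- 0L
  for (e in seq_len(nrow(idx))) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      taken <- taken + 1L
      edges[taken, ] <- idx[e, ]
      if (taken == n - 1L) break
    }
  }
  edges
}

#' Build the rooted cluster-center minimum spanning tree
#'
#' Computes the Euclidean distance matrix between cluster centers, takes
#' the minimum spanning tree of the complete graph it defines, and directs
#' the tree away from the position holding `rootCluster`. Equal-weight
#' edges are broken deterministically by lexicographic (smaller index,
#' larger index) order.
#'
#' @param centers numeric matrix, one row per cluster (latent coordinates).
#' @param rootCluster cluster id of the root.
#' @param clusterIds integer ids of the clusters (default `1..n`).
#' @param meanPseudotime per-cluster mean ensemble pseudotime (default 0s;
#'   required for meaningful [finetuneMST()]).
#' @param memberCells list of member-cell id vectors per cluster (default
#'   empty).
#' @return A [TrajectoryTree-class] rooted at `rootCluster`.
#' @export
buildMST <- function(centers, rootCluster,
                     clusterIds = seq_len(nrow(centers)),
                     meanPseudotime = numeric(nrow(centers)),
                     memberCells = rep(list(character()), nrow(centers))) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n < 1L) stop("at least one cluster required", call. = FALSE)
  rootPos <- match(rootCluster, clusterIds)
  if (is.na(rootPos))
    stop("root cluster not among the cluster ids", call. = FALSE)
  D <- as.matrix(stats::dist(centers))
  edges <- .kruskalMST(D)
  # orient away from the root by BFS over the undirected tree edges
  adj <- rep(list(integer()), n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  queue <- rootPos
  visited[rootPos] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  ew <- rep(NA_real_, n)
  for (i in seq_len(n)) if (!is.na(parent[i])) ew[i] <- D[i, parent[i]]
  new("TrajectoryTree", parent = parent,
      clusterIndex = as.integer(clusterIds), centers = centers,
      meanPseudotime = as.numeric(meanPseudotime),
      memberCells = memberCells, edgeWeights = ew, swaps = 0L)
}

.childrenOf <- function(parent, pos) which(!is.na(parent) & parent == pos)

.descendantsOf <- function(parent, pos) {
  out <- integer()
  stack <- .childrenOf(parent, pos)
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    out <- c(out, v)
    stack <- c(stack, .childrenOf(parent, v))
  }
  out
}

#' Fine-tune a trajectory tree by pseudotime
#'
#' Recursive payload reordering starting at the root position: among the
#' payloads at all strict descendants of the current position, find the one
#' with minimum mean pseudotime (ties: smallest cluster index); if the
#' current position's payload has larger mean pseudotime, exchange the two
#' payloads between their positions and recompute the weights of all edges
#' incident to either position from the new endpoint centers. Then recurse
#' into each child position (using the post-swap payload assignment).
#'
#' The tree's shape (positions and parent pointers) is never changed — only
#' the payload-to-position assignment and the edge weights. After the
#' procedure, every position's payload mean pseudotime is less than or
#' equal to that of every strict-descendant payload: each visited position
#' receives the minimum over its whole descendant set before the recursion
#' descends, so no later swap below it can introduce a smaller value above.
#' For the same reason the procedure is idempotent, and a root fed
#' ensemble pseudotime (start cluster = 0) is never swapped away.
#'
#' @param tree a [TrajectoryTree-class] with mean pseudotime set.
#' @return A [TrajectoryTree-class] with identical shape, possibly permuted
#'   payloads, edge weights recomputed from the final centers, and the
#'   number of swaps recorded (see [nSwaps()]).
#' @export
finetuneMST <- function(tree) {
  parent <- tree@parent
  cidx <- tree@clusterIndex
  centers <- tree@centers
  pt <- tree@meanPseudotime
  members <- tree@memberCells
  ew <- tree@edgeWeights
  swaps <- 0L

  recompute <- function(pos) {
    p <- parent[pos]
    if (!is.na(p))
      ew[pos] <<- sqrt(sum((centers[pos, ] - centers[p, ])^2))
    for (ch in .childrenOf(parent, pos))
      ew[ch] <<- sqrt(sum((centers[ch, ] - centers[pos, ])^2))
  }

  swapPayloads <- function(a, b) {
    cidx[c(a, b)] <<- cidx[c(b, a)]
    centers[c(a, b), ] <<- centers[c(b, a), , drop = FALSE]
    pt[c(a, b)] <<- pt[c(b, a)]
    members[c(a, b)] <<- members[c(b, a)]
    recompute(a)
    recompute(b)
    swaps <<- swaps + 1L
  }

  visit <- function(pos) {
    desc <- .descendantsOf(parent, pos)
    if (length(desc)) {
      ord <- order(pt[desc], cidx[desc])  # ties: smallest cluster index
      vmin <- desc[ord[1]]
      if (pt[pos] > pt[vmin]) swapPayloads(pos, vmin)
      for (ch in .childrenOf(parent, pos)) visit(ch)
    }
  }

  visit(which(is.na(parent)))
  new("TrajectoryTree", parent = parent, clusterIndex = cidx,
      centers = centers, meanPseudotime = pt, memberCells = members,
      edgeWeights = ew, swaps = tree@swaps + swaps)
}

#' Run the full trajectory-inference pipeline on features
#'
#' Embeds the features once, computes the ensemble pseudotime over the
#' `[kMin, kMax]` resolutions, obtains the final partition by automatic
#' cluster-number selection on the same latent space, builds the
#' cluster-center MST rooted at the mode start cluster of that partition,
#' and fine-tunes it by mean pseudotime.
#'
#' @param features a [PathwayFactors-class] or numeric matrix (cells in
#'   rows).
#' @param startCells character vector of start-cell identifiers.
#' @param seed integer seed.
#' @param kMin,kMax ensemble resolution range (defaults 5 and 10).
#' @param d latent dimensionality (default 15).
#' @param kAutoMin,kAutoMax range for the automatic cluster-number search
#'   (defaults 2 and 15).
#' @param backend an [EmbedClusterBackend-class].
#' @param normalizeRuns passed to [ensemblePseudotime()].
#' @return A list with components `tree` (fine-tuned
#'   [TrajectoryTree-class]), `run` (the auto-k [ClusteringRun-class]) and
#'   `pseudotime` (named numeric, the ensemble pseudotime).
#' @export
inferTrajectory <- function(features, startCells, seed = 1L,
                            kMin = 5L, kMax = 10L, d = 15L,
                            kAutoMin = 2L, kAutoMax = 15L,
                            backend = pcaKmeansBackend(),
                            normalizeRuns = FALSE) {
  latent <- embedCells(features, d = d, seed = seed, backend = backend)
  pt <- .ensembleFromLatent(latent, startCells, kMin, kMax, seed, backend,
                            normalizeRuns)
  autoRun <- clusterAuto(latent, kMin = kAutoMin,
                         kMax = min(kAutoMax, nrow(latent)),
                         seed = seed, backend = backend)
  labels <- clusterLabels(autoRun)
  k <- nClusters(autoRun)
  centers <- .clusterCenters(autoRun)
  meanPt <- vapply(seq_len(k), function(c) mean(pt[labels == c]),
                   numeric(1))
  members <- lapply(seq_len(k), function(c) names(labels)[labels == c])
  rootCluster <- startCluster(autoRun, startCells)
  tree <- buildMST(centers, rootCluster, clusterIds = seq_len(k),
                   meanPseudotime = meanPt, memberCells = members)
  tree <- finetuneMST(tree)
  list(tree = tree, run = autoRun, pseudotime = pt)
}
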