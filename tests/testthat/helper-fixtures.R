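# Shared fixtures: Gaussian blob matrices, random rooted trees with
# payloads, and an independent naive transcription of the pseudotime
# fine-tune procedure used as the oracle against finetuneMST().

makeBlobs <- function(centers, nPerBlob, sd = 0.1, seed = 1L) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  d <- ncol(centers)
  withr::with_seed(seed, {
    x <- centers[rep(seq_len(k), each = nPerBlob), , drop = FALSE] +
      matrix(rnorm(k * nPerBlob * d, sd = sd), k * nPerBlob, d)
  })
  rownames(x) <- sprintf("cell%03d", seq_len(nrow(x)))
  attr(x, "blob") <- rep(seq_len(k), each = nPerBlob)
  x
}

# Build a TrajectoryTree directly from a parent vector and payload data
# (edge weights derived from the centers).
makeTree <- function(parent, clusterIndex, centers, pt,
                     members = rep(list(character()), length(parent))) {
  n <- length(parent)
  ew <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(parent[i]))
      ew[i] <- sqrt(sum((centers[i, ] - centers[parent[i], ])^2))
  }
  new("TrajectoryTree", parent = as.integer(parent),
      clusterIndex = as.integer(clusterIndex),
      centers = as.matrix(centers), meanPseudotime = as.numeric(pt),
      memberCells = members, edgeWeights = ew, swaps = 0L)
}

# Random rooted tree on n positions (node 1 is the root) with random
# payloads; rounding pseudotime to one decimal introduces ties that
# exercise the smallest-cluster-index tie-break.
randomPayloadTree <- function(n, seed, withTies = FALSE) {
  withr::with_seed(seed, {
    parent <- c(NA_integer_,
                if (n > 1) vapply(2:n, function(i)
                  sample.int(i - 1L, 1), integer(1)))
    centers <- matrix(rnorm(n * 3), n, 3)
    pt <- runif(n, 0, 10)
    if (withTies) pt <- round(pt, 0)
    cidx <- sample.int(100L, n)
  })
  makeTree(parent, cidx, centers, pt)
}

# All rooted tree shapes on n positions, as parent vectors with node 1 the
# root and parent(i) < i. Every unlabeled rooted shape occurs.
enumerateParentVectors <- function(n) {
  if (n == 1L) return(list(NA_integer_))
  grids <- lapply(2:n, function(i) seq_len(i - 1L))
  combos <- expand.grid(grids)
  lapply(seq_len(nrow(combos)), function(r)
    c(NA_integer_, as.integer(combos[r, ])))
}

# Independent naive transcription of the fine-tune procedure: plain
# vectors, recursive descendant scans, weights recomputed wholesale at the
# end. Deliberately shares no code with finetuneMST().
oracleFinetune <- function(parent, clusterIndex, centers, pt) {
  childrenOf <- function(v) which(!is.na(parent) & parent == v)
  descend <- function(v) {
    out <- integer()
    for (ch in childrenOf(v)) out <- c(out, ch, descend(ch))
    out
  }
  step <- function(v) {
    desc <- descend(v)
    if (length(desc)) {
      best <- desc[1]
      for (u in desc) {
        if (pt[u] < pt[best] ||
            (pt[u] == pt[best] && clusterIndex[u] < clusterIndex[best]))
          best <- u
      }
      if (pt[v] > pt[best]) {
        tmp <- clusterIndex[v]
        clusterIndex[v] <<- clusterIndex[best]; clusterIndex[best] <<- tmp
        tmpc <- centers[v, ]
        centers[v, ] <<- centers[best, ]; centers[best, ] <<- tmpc
        tmpp <- pt[v]
        pt[v] <<- pt[best]; pt[best] <<- tmpp
      }
      for (ch in childrenOf(v)) step(ch)
    }
  }
  step(which(is.na(parent)))
  w <- rep(NA_real_, length(parent))
  for (i in seq_along(parent)) {
    if (!is.na(parent[i]))
      w[i] <- sqrt(sum((centers[i, ] - centers[parent[i], ])^2))
  }
  list(clusterIndex = clusterIndex, centers = centers, pt = pt,
       weights = w)
}

# Strict-descendant pseudotimes for the min-heap postcondition check.
treeIsMinHeap <- function(tree) {
  parent <- treeParents(tree)
  pt <- treePseudotime(tree)
  for (i in seq_along(parent)) {
    v <- parent[i]
    while (!is.na(v)) {
      if (pt[v] > pt[i] + 1e-12) return(FALSE)
      v <- parent[v]
    }
  }
  TRUE
}

# Undirected milestone-level adjacency of a fine-tuned tree: clusters are
# mapped to the majority stage of their member cells and same-stage edges
# contracted. Returns a sorted character vector of "a|b" pairs.
majorityStageEdges <- function(tree, stages) {
  members <- treeMembers(tree)
  stageOf <- vapply(members, function(cells) {
    tab <- table(as.character(stages[cells]))
    names(tab)[which.max(tab)]
  }, character(1))
  parent <- treeParents(tree)
  edges <- character()
  for (i in seq_along(parent)) {
    if (is.na(parent[i])) next
    a <- stageOf[parent[i]]; b <- stageOf[i]
    if (a != b) edges <- c(edges, paste(sort(c(a, b)), collapse = "|"))
  }
  sort(unique(edges))
}

topologyEdges <- function(topology) {
  p <- milestoneParents(topology)
  sort(unique(vapply(names(p), function(ch)
    paste(sort(c(p[[ch]], ch)), collapse = "|"), character(1))))
}

# One full pipeline run on simulated data; returns what the acceptance
# properties score.
simulatedPipelineRun <- function(topology, cellsPerStage, noiseSd, seed,
                                 full = FALSE) {
  sim <- simulateTrajectory(topology, cellsPerStage = cellsPerStage,
                            noiseSd = noiseSd, seed = seed)
  geneSets <- simulateGeneSets(rownames(sim$sce), seed = seed + 1L)
  sce <- filterGenes(logRescale(sim$sce))
  features <- suppressWarnings(pathwayFactors(sce, geneSets))
  if (full) {
    res <- suppressWarnings(inferTrajectory(features, sim$startCells,
                                            seed = seed))
    c(res, list(stages = sim$stages, startCells = sim$startCells))
  } else {
    pt <- suppressWarnings(ensemblePseudotime(features, sim$startCells,
                                              seed = seed))
    list(pseudotime = pt, stages = sim$stages,
         startCells = sim$startCells)
  }
}
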