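## Synthetic-trajectory simulator. Milestone centers of a rooted topology
## are placed in latent space so that adjacent milestones are unit distance
## apart and non-adjacent ones farther (each new branch takes a fresh
## orthogonal axis). Cells are their stage center plus isotropic Gaussian
## noise; expression is a softplus readout of a fixed random linear map of
## latent position, scaled to count magnitude.

#' Construct a trajectory topology
#'
#' @param milestones ordered character vector of stage names.
#' @param parents named character vector: parent of every non-root stage.
#' @param root the root stage name.
#' @return A [TrajectoryTopology-class].
#' @export
trajectoryTopology <- function(milestones, parents, root) {
  new("TrajectoryTopology", milestones = milestones,
      parents = parents, root = root)
}

#' @describeIn trajectoryTopology Linear chain of `nStages` stages.
#' @param nStages number of stages.
#' @param names optional stage names (default `S1..Sn`).
#' @export
linearTopology <- function(nStages, names = paste0("S", seq_len(nStages))) {
  stopifnot(nStages >= 1L)
  parents <- if (nStages > 1L)
    stats::setNames(names[-nStages], names[-1]) else
    stats::setNames(character(), character())
  trajectoryTopology(names, parents, names[1])
}

#' @describeIn trajectoryTopology Root followed by two linear arms of
#'   `armLength` stages each.
#' @param armLength stages per arm (default 2).
#' @export
bifurcationTopology <- function(armLength = 2L) {
  arms <- c(paste0("A", seq_len(armLength)), paste0("B", seq_len(armLength)))
  milestones <- c("M0", arms)
  parents <- character()
  for (br in c("A", "B")) {
    prev <- "M0"
    for (i in seq_len(armLength)) {
      nm <- paste0(br, i)
      parents[nm] <- prev
      prev <- nm
    }
  }
  trajectoryTopology(milestones, parents, "M0")
}

#' @describeIn trajectoryTopology Small fixed tree: root, one intermediate
#'   stage, and a bifurcation after it plus a direct branch off the root.
#' @export
treeTopology <- function() {
  milestones <- c("M0", "T1", "T2a", "T2b", "U1")
  parents <- c(T1 = "M0", T2a = "T1", T2b = "T1", U1 = "M0")
  trajectoryTopology(milestones, parents, "M0")
}

.placeMilestones <- function(topology, latentDim) {
  m <- milestones(topology)
  p <- milestoneParents(topology)
  root <- milestoneRoot(topology)
  centers <- matrix(0, length(m), latentDim, dimnames = list(m, NULL))
  incomingAxis <- stats::setNames(rep(NA_integer_, length(m)), m)
  nextAxis <- 1L
  # DFS in milestone order; first child continues the parent's axis,
  # further children (and every child of the root) take a fresh axis
  childrenOf <- function(v) names(p)[p == v]
  stack <- root
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    ch <- childrenOf(v)
    first <- TRUE
    for (w in ch) {
      axis <- if (!first || is.na(incomingAxis[v])) {
        a <- nextAxis
        nextAxis <- nextAxis + 1L
        a
      } else incomingAxis[v]
      if (axis > latentDim)
        stop("latentDim too small for this topology's branch count",
             call. = FALSE)
      centers[w, ] <- centers[v, ]
      centers[w, axis] <- centers[w, axis] + 1
      incomingAxis[w] <- axis
      first <- FALSE
    }
    stack <- c(ch, stack)
  }
  centers
}

.softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Simulate cells along a latent trajectory
#'
#' Milestone centers are placed in a `latentDim`-dimensional latent space
#' with adjacent milestones unit distance apart and non-adjacent ones
#' farther. Each cell is its stage center plus isotropic Gaussian noise
#' (`noiseSd`); expression is the softplus of a fixed random linear map of
#' the latent position, scaled by `countScale` (optionally Poisson-sampled
#' for count noise). Start cells are `nStartCells` cells sampled from the
#' root stage. Fully seeded and deterministic.
#'
#' @param topology a [TrajectoryTopology-class].
#' @param cellsPerStage cells simulated per milestone.
#' @param nGenes number of genes (default 200; must be `>= latentDim`).
#' @param latentDim latent dimensionality (default 5).
#' @param noiseSd isotropic latent noise standard deviation.
#' @param seed integer seed.
#' @param countScale multiplier taking softplus readout to count magnitude
#'   (default 50).
#' @param countNoise `"none"` (default) or `"poisson"`.
#' @param nStartCells start cells sampled from the root stage (default 5).
#' @return A list with components `sce` (a
#'   [SingleCellExperiment::SingleCellExperiment-class], genes x cells,
#'   `counts` assay, per-cell `stage` column data), `stages` (named ordered
#'   factor) and `startCells` (character vector).
#' @export
simulateTrajectory <- function(topology, cellsPerStage, nGenes = 200L,
                               latentDim = 5L, noiseSd = 0.1, seed = 1L,
                               countScale = 50, countNoise = c("none",
                               "poisson"), nStartCells = 5L) {
  countNoise <- match.arg(countNoise)
  if (nGenes < latentDim)
    stop("nGenes must be >= latentDim", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be nonnegative", call. = FALSE)
  centers <- .placeMilestones(topology, latentDim)
  stageNames <- milestones(topology)
  nStages <- length(stageNames)
  nCells <- nStages * cellsPerStage

  withr::with_seed(seed, {
    stageIdx <- rep(seq_len(nStages), each = cellsPerStage)
    latent <- centers[stageIdx, , drop = FALSE] +
      matrix(stats::rnorm(nCells * latentDim, sd = noiseSd),
             nCells, latentDim)
    W <- matrix(stats::rnorm(latentDim * nGenes), latentDim, nGenes)
    expr <- .softplus(latent %*% W) * countScale
    if (countNoise == "poisson") {
      expr <- matrix(stats::rpois(length(expr), lambda = expr),
                     nrow(expr), ncol(expr))
      storage.mode(expr) <- "double"
    }
    cellIds <- sprintf("cell%04d", seq_len(nCells))
    geneIds <- sprintf("g%04d", seq_len(nGenes))
    dimnames(expr) <- list(cellIds, geneIds)
    rootCells <- cellIds[stageIdx == match(milestoneRoot(topology),
                                           stageNames)]
    startCells <- sample(rootCells, min(nStartCells, length(rootCells)))
  })

  stages <- stats::setNames(
    factor(stageNames[stageIdx], levels = stageNames, ordered = TRUE),
    rownames(expr))
  sce <- .asSCE(expr, rownames(expr), colnames(expr))
  SummarizedExperiment::colData(sce)$stage <- stages
  list(sce = sce, stages = stages, startCells = startCells)
}

#' Simulate a gene-set collection over a gene universe
#'
#' Each set's size is drawn uniformly from `setSizeRange` and its genes are
#' sampled without replacement from `geneIds`. Fully seeded.
#'
#' @param geneIds character vector, the gene universe.
#' @param nSets number of sets (default 15).
#' @param setSizeRange integer pair, inclusive size range (default
#'   `c(10, 40)`).
#' @param seed integer seed.
#' @return Named list of character vectors (same shape as
#'   [readGeneSets()]), names `PW01..`, with a `"description"` attribute
#'   marking the sets as synthetic.
#' @export
simulateGeneSets <- function(geneIds, nSets = 15L,
                             setSizeRange = c(10L, 40L), seed = 1L) {
  lo <- setSizeRange[1]; hi <- setSizeRange[2]
  if (lo < 1L || hi < lo) stop("invalid set size range", call. = FALSE)
  if (hi > length(geneIds))
    stop("maximum set size exceeds the gene universe", call. = FALSE)
  withr::with_seed(seed, {
    sizes <- if (lo == hi) rep(lo, nSets)
             else sample(lo:hi, nSets, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(geneIds, s))
  })
  names(sets) <- sprintf("PW%02d", seq_len(nSets))
  attr(sets, "description") <- stats::setNames(
    rep("synthetic gene set", nSets), names(sets))
  sets
}
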