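test_that("the cluster-center MST picks the shortest spanning tree", {
  # two payloads: single edge with the center distance as weight
  t2 <- buildMST(rbind(c(0, 0), c(3, 4)), rootCluster = 1)
  expect_equal(sum(!is.na(treeParents(t2))), 1)
  expect_equal(treeEdgeWeights(t2)[2], 5)

  # three collinear centers at 0, 1, 3: edges {0-1, 1-3}; brute force over
  # the three possible spanning trees gives weights 3 < 4 < 5
  t3 <- buildMST(cbind(c(0, 1, 3)), rootCluster = 1)
  parent <- treeParents(t3)
  expect_equal(parent, c(NA_integer_, 1L, 2L))
  expect_equal(sum(treeEdgeWeights(t3), na.rm = TRUE), 3)

  # duplicate centers: zero-weight edge allowed, tree still spans
  td <- buildMST(rbind(c(0, 0), c(0, 0), c(2, 0)), rootCluster = 1)
  expect_equal(sum(!is.na(treeParents(td))), 2)
  expect_equal(min(treeEdgeWeights(td), na.rm = TRUE), 0)
  expect_true(validObject(td))
})

test_that("the MST total weight matches the igraph oracle", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      centers <- matrix(rnorm(8 * 3), 8, 3)
    })
    tree <- buildMST(centers, rootCluster = 1)
    D <- as.matrix(dist(centers))
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    ref <- igraph::mst(g)
    expect_equal(sum(treeEdgeWeights(tree), na.rm = TRUE),
                 sum(igraph::E(ref)$weight), tolerance = 1e-10)
  }
})

test_that("fine-tuning fixes a mis-ordered chain and leaves sorted trees alone", {
  # chain root(pt 0) -> A(pt 5) -> B(pt 2): A and B must swap
  centers <- rbind(c(0, 0), c(1, 0), c(2, 0))
  chain <- makeTree(c(NA, 1L, 2L), clusterIndex = 1:3, centers,
                    pt = c(0, 5, 2))
  out <- finetuneMST(chain)
  expect_identical(treeParents(out), treeParents(chain))  # shape kept
  expect_equal(treeClusters(out), c(1L, 3L, 2L))
  expect_equal(treePseudotime(out), c(0, 2, 5))
  expect_equal(nSwaps(out), 1L)
  expect_true(validObject(out))  # weights consistent with moved centers

  # already sorted chain: identity
  sorted <- makeTree(c(NA, 1L, 2L), 1:3, centers, pt = c(0, 2, 5))
  expect_equal(finetuneMST(sorted), sorted)

  # star root(0) with leaf pts 3, 1, 2: min descendant 1 >= 0, no swap
  star <- makeTree(c(NA, 1L, 1L, 1L), 1:4,
                   rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0)),
                   pt = c(0, 3, 1, 2))
  expect_equal(finetuneMST(star), star)
})

test_that("fine-tuning satisfies its structural invariants on random trees", {
  for (seed in 1:40) {
    tree <- randomPayloadTree(n = 3 + seed %% 10, seed = seed,
                              withTies = seed %% 3 == 0)
    out <- finetuneMST(tree)
    expect_identical(treeParents(out), treeParents(tree))
    expect_setequal(treeClusters(out), treeClusters(tree))
    expect_setequal(treePseudotime(out), treePseudotime(tree))
    expect_true(treeIsMinHeap(out))
    expect_equal(finetuneMST(out), out)  # idempotent
    expect_true(validObject(out))
  }
})

test_that("fine-tuning agrees with the naive prose transcription", {
  for (seed in 101:140) {
    tree <- randomPayloadTree(n = 2 + seed %% 6, seed = seed,
                              withTies = seed %% 2 == 0)
    out <- finetuneMST(tree)
    ref <- oracleFinetune(treeParents(tree), treeClusters(tree),
                          treeCenters(tree), treePseudotime(tree))
    expect_identical(treeClusters(out), ref$clusterIndex)
    expect_equal(treeEdgeWeights(out), ref$weights)
  }
})

test_that("a root with zero pseudotime is never swapped away", {
  for (seed in 1:20) {
    tree <- randomPayloadTree(n = 6, seed = seed)
    pt <- treePseudotime(tree)
    pt[1] <- 0  # ensemble pseudotime: start cluster is exactly 0
    tree2 <- makeTree(treeParents(tree), treeClusters(tree),
                      treeCenters(tree), pt)
    out <- finetuneMST(tree2)
    expect_equal(treeClusters(out)[1], treeClusters(tree2)[1])
  }
})

test_that("the full trajectory pipeline recovers a linear chain of blobs", {
  res <- simulatedPipelineRun(linearTopology(3), cellsPerStage = 60,
                              noiseSd = 0.05, seed = 31, full = TRUE)
  tree <- res$tree
  # chain topology: no position has more than one child
  parent <- treeParents(tree)
  expect_lte(max(table(parent[!is.na(parent)])), 1)
  # payload order along the chain matches stage order
  edges <- majorityStageEdges(tree, res$stages)
  expect_identical(edges, topologyEdges(linearTopology(3)))
  # root cluster holds the start cells' stage
  rootPos <- which(is.na(parent))
  rootStage <- names(which.max(table(
    as.character(res$stages[treeMembers(tree)[[rootPos]]]))))
  expect_identical(rootStage, "S1")
})

test_that("single-cluster data produce a single-vertex, edgeless tree", {
  x <- makeBlobs(rbind(c(0, 0)), nPerBlob = 30, sd = 0.05, seed = 13)
  start <- rownames(x)[1:3]
  run <- clusterFixedK(x, 1, seed = 1)
  pt <- clusterPseudotime(run, 1)
  tree <- buildMST(matrix(colMeans(x), 1), rootCluster = 1,
                   meanPseudotime = mean(pt),
                   memberCells = list(rownames(x)))
  expect_equal(length(treeParents(tree)), 1)
  expect_true(all(is.na(treeEdgeWeights(tree))))
  expect_equal(finetuneMST(tree), tree)
})

test_that("the trajectory pipeline is deterministic under a fixed seed", {
  x <- makeBlobs(rbind(0, 2, 4, 6, 8), nPerBlob = 25, sd = 0.3, seed = 19)
  start <- rownames(x)[1:5]
  a <- suppressWarnings(inferTrajectory(x, start, seed = 23))
  b <- suppressWarnings(inferTrajectory(x, start, seed = 23))
  expect_identical(a$pseudotime, b$pseudotime)
  expect_equal(a$tree, b$tree)
  expect_identical(clusterLabels(a$run), clusterLabels(b$run))
})
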