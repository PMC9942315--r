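test_that("pathway intersection applies the 10-gene survival threshold inclusively", {
  withr::with_seed(3, {
    m <- matrix(runif(40 * 30), 40, 30,
                dimnames = list(sprintf("c%02d", 1:40),
                                sprintf("g%02d", 1:30)))
  })
  gs <- list(nine = sprintf("g%02d", 1:9),            # 9 matches: dropped
             ten = sprintf("g%02d", 1:10),            # exactly 10: kept
             disjoint = sprintf("x%02d", 1:20),       # 0 matches: dropped
             big = sprintf("g%02d", 10:30))
  subs <- intersectPathways(m, gs)
  expect_identical(names(subs), c("ten", "big"))
  expect_identical(colnames(subs$ten), sprintf("g%02d", 1:10))
  expect_equal(nrow(subs$ten), 40)

  expect_error(intersectPathways(m, list(none = paste0("z", 1:12))),
               "no pathways matched")
})

test_that("raising the pathway threshold never adds a pathway", {
  withr::with_seed(4, {
    m <- matrix(runif(20 * 50), 20, 50,
                dimnames = list(sprintf("c%02d", 1:20),
                                sprintf("g%02d", 1:50)))
    gs <- simulateGeneSets(colnames(m), nSets = 8,
                           setSizeRange = c(5L, 30L), seed = 9)
  })
  prev <- names(intersectPathways(m, gs, minPathwayGenes = 1L))
  for (thr in c(5L, 10L, 20L, 30L)) {
    cur <- tryCatch(names(intersectPathways(m, gs, minPathwayGenes = thr)),
                    error = function(e) character())
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("factor extraction has the contracted shape and degenerate fallback", {
  withr::with_seed(21, {
    sub <- matrix(rnorm(100 * 20), 100, 20,
                  dimnames = list(sprintf("c%03d", 1:100), NULL))
  })
  sc <- suppressWarnings(factorizePathway(sub))
  expect_equal(dim(sc), c(100L, 2L))
  expect_identical(rownames(sc), rownames(sub))

  const <- matrix(7, 100, 6, dimnames = list(rownames(sub), NULL))
  expect_warning(z <- factorizePathway(const), "non-constant")
  expect_equal(z, matrix(0, 100, 2, dimnames = list(rownames(sub), NULL)))
})

test_that("a seeded rank-1 signal is recovered by the first factor", {
  withr::with_seed(42, {
    s <- rnorm(100)
    loadings <- runif(20, 0.5, 1)
    sub <- s %o% loadings + matrix(rnorm(100 * 20, sd = 0.1), 100, 20)
  })
  rownames(sub) <- sprintf("c%03d", 1:100)
  sc <- suppressWarnings(factorizePathway(sub))
  expect_gte(abs(cor(sc[, 1], s)), 0.95)
})

test_that("factor scores are invariant to cell order up to the same permutation", {
  withr::with_seed(15, {
    s <- rnorm(60)
    sub <- s %o% runif(12, 0.5, 1) +
      matrix(rnorm(60 * 12, sd = 0.2), 60, 12)
    rownames(sub) <- sprintf("c%03d", 1:60)
    perm <- sample(60)
  })
  a <- suppressWarnings(factorizePathway(sub))
  b <- suppressWarnings(factorizePathway(sub[perm, ]))
  expect_equal(b, a[perm, ], tolerance = 1e-6)
})

test_that("assembled factors are concatenated in pathway order and clipped", {
  rows <- sprintf("c%02d", 1:4)
  sA <- matrix(c(7.3, 0, 1, -6), 4, 2, dimnames = list(rows, NULL))
  sB <- matrix(0.5, 4, 2, dimnames = list(rows, NULL))
  sC <- matrix(-1, 4, 2, dimnames = list(rows, NULL))
  pf <- assembleFactors(list(pA = sA, pB = sB, pC = sC))
  expect_s4_class(pf, "PathwayFactors")
  expect_equal(ncol(factorScores(pf)), 6)  # 2 x 3 pathways
  expect_identical(pathwayNames(pf), c("pA", "pB", "pC"))
  expect_equal(unname(factorScores(pf)[1, 1]), 5)    # 7.3 clipped to 5
  expect_equal(unname(factorScores(pf)[4, 1]), -5)   # -6 clipped to -5
  expect_equal(factorScores(pf)[, 3:4], sB, ignore_attr = TRUE)

  # identity under clipping when everything is in range
  inRange <- matrix(runif(8, -4, 4), 4, 2, dimnames = list(rows, NULL))
  pf2 <- assembleFactors(list(p = inRange))
  expect_equal(factorScores(pf2), inRange, ignore_attr = TRUE)

  expect_error(assembleFactors(list(a = sA, b = sB[1:3, ])),
               "row counts")
})

test_that("clipping bound holds over random factor inputs", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      sc <- lapply(1:3, function(i) matrix(rnorm(50, sd = 4), 25, 2))
    })
    names(sc) <- paste0("p", 1:3)
    pf <- assembleFactors(sc, clipBound = 5)
    expect_lte(max(abs(factorScores(pf))), 5)
  }
})

test_that("the full pathway-factor composition obeys the width contract", {
  withr::with_seed(33, {
    m <- matrix(rexp(80 * 60), 80, 60,
                dimnames = list(sprintf("c%02d", 1:80),
                                sprintf("g%02d", 1:60)))
    gs <- simulateGeneSets(colnames(m), nSets = 5,
                           setSizeRange = c(12L, 20L), seed = 2)
  })
  pf <- suppressWarnings(pathwayFactors(m, gs))
  expect_equal(ncol(factorScores(pf)),
               2L * length(pathwayNames(pf)))
  expect_identical(rownames(factorScores(pf)), rownames(m))
})
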