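## Preprocessing: iterated base-2 log rescaling until the global expression
## range drops below a threshold, then gene quality control by the fraction
## of cells expressing each gene.

.logRescaleMatrix <- function(m, rangeThreshold) {
  if (rangeThreshold <= 0)
    stop("rangeThreshold must be positive", call. = FALSE)
  if (any(m < 0))
    stop("negative expression values are not allowed", call. = FALSE)
  iter <- 0L
  # log2(x+1) shrinks any finite range below 100 in one or two passes; the
  # cap only guards pathological non-finite input
  while (length(m) && diff(range(m)) >= rangeThreshold) {
    m <- log2(m + 1)
    iter <- iter + 1L
    if (iter >= 30L)
      stop("log rescaling did not converge in 30 iterations", call. = FALSE)
  }
  m
}

#' @rdname logRescale
#' @export
setMethod("logRescale", "matrix", function(x, rangeThreshold = 100) {
  .logRescaleMatrix(x, rangeThreshold)
})

#' @rdname logRescale
#' @export
setMethod("logRescale", "SingleCellExperiment",
  function(x, rangeThreshold = 100) {
    SummarizedExperiment::assay(x, "counts") <-
      .logRescaleMatrix(as.matrix(SummarizedExperiment::assay(x, "counts")),
                        rangeThreshold)
    x
  })

.geneKeepMask <- function(cellsByGenes, minExpressedFraction) {
  if (minExpressedFraction <= 0 || minExpressedFraction > 1)
    stop("minExpressedFraction must be in (0, 1]", call. = FALSE)
  if (!nrow(cellsByGenes))
    stop("expression matrix has no cells", call. = FALSE)
  frac <- colMeans(cellsByGenes > 0)
  keep <- frac >= minExpressedFraction
  if (!any(keep))
    stop("no genes survive quality control", call. = FALSE)
  keep
}

#' @rdname filterGenes
#' @export
setMethod("filterGenes", "matrix",
  function(x, minExpressedFraction = 0.2) {
    keep <- .geneKeepMask(x, minExpressedFraction)
    x[, keep, drop = FALSE]
  })

#' @rdname filterGenes
#' @export
setMethod("filterGenes", "SingleCellExperiment",
  function(x, minExpressedFraction = 0.2) {
    m <- t(as.matrix(SummarizedExperiment::assay(x, "counts")))
    keep <- .geneKeepMask(m, minExpressedFraction)
    x[keep, ]
  })
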