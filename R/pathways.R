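## Pathway gene-set intersection and per-pathway factor extraction.
##
## Each gene set is intersected with the (preprocessed) expression matrix;
## pathways matching fewer than 10 genes are dropped. Every surviving
## pathway submatrix is summarized by 2 factor-analysis score columns, and
## the per-pathway scores are concatenated and clipped to [-5, 5]. The
## result is the low-dimensional feature space the embedding backend sees:
## 2 x (number of surviving pathways) columns.

.cellsByGenes <- function(x) {
  if (methods::is(x, "SingleCellExperiment"))
    t(as.matrix(SummarizedExperiment::assay(x, "counts")))
  else x
}

.intersectPathwaysMatrix <- function(m, geneSets, minPathwayGenes) {
  if (!length(geneSets)) stop("gene-set collection is empty", call. = FALSE)
  if (minPathwayGenes < 1) stop("minPathwayGenes must be >= 1", call. = FALSE)
  out <- list()
  for (nm in names(geneSets)) {
    hit <- intersect(colnames(m), geneSets[[nm]])
    # threshold inclusive: exactly minPathwayGenes matches is kept
    if (length(hit) >= minPathwayGenes)
      out[[nm]] <- m[, hit, drop = FALSE]
  }
  if (!length(out)) stop("no pathways matched", call. = FALSE)
  out
}

#' @rdname intersectPathways
#' @export
setMethod("intersectPathways", "matrix",
  function(x, geneSets, minPathwayGenes = 10L) {
    .intersectPathwaysMatrix(x, geneSets, minPathwayGenes)
  })

#' @rdname intersectPathways
#' @export
setMethod("intersectPathways", "SingleCellExperiment",
  function(x, geneSets, minPathwayGenes = 10L) {
    .intersectPathwaysMatrix(.cellsByGenes(x), geneSets, minPathwayGenes)
  })

.fixSigns <- function(scores, loadings) {
  # sign indeterminacy: make each factor's largest-|loading| entry positive
  for (j in seq_len(ncol(scores))) {
    l <- loadings[, j]
    if (all(l == 0)) next
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

.pcaScores <- function(std, nFactors) {
  p <- stats::prcomp(std, center = FALSE, scale. = FALSE)
  k <- min(nFactors, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  scores <- .fixSigns(scores, p$rotation[, seq_len(k), drop = FALSE])
  if (k < nFactors)
    scores <- cbind(scores,
                    matrix(0, nrow(scores), nFactors - k))
  scores
}

#' Factor scores for one pathway submatrix
#'
#' Standardizes the submatrix columns (constant genes are dropped first) and
#' extracts `nFactors` factor-analysis scores (maximum likelihood, no
#' rotation, regression scores). Factor signs are fixed so that each
#' factor's largest-magnitude loading is positive, making the output
#' deterministic across platforms. If the factor fit fails or the submatrix
#' is too degenerate for maximum likelihood, the first `nFactors` principal
#' component scores of the standardized submatrix are returned instead (with
#' a warning); if fewer than `nFactors` non-constant genes remain, zero
#' columns pad the output (with a warning), so pathway bookkeeping stays
#' consistent.
#'
#' @param sub numeric matrix, cells in rows, matched pathway genes in
#'   columns.
#' @param nFactors number of factors (default 2).
#' @param seed integer seed (kept for contract symmetry; extraction is
#'   deterministic).
#' @return Numeric matrix, cells x `nFactors`, row names preserved.
#' @export
factorizePathway <- function(sub, nFactors = 2L, seed = 1L) {
  nFactors <- as.integer(nFactors)
  if (nFactors < 1L) stop("nFactors must be >= 1", call. = FALSE)
  n <- nrow(sub)
  keep <- apply(sub, 2, stats::sd) > 0
  if (sum(keep) < nFactors) {
    warning("pathway has fewer than ", nFactors,
            " non-constant genes; returning zero factor columns",
            call. = FALSE)
    out <- matrix(0, n, nFactors, dimnames = list(rownames(sub), NULL))
    return(out)
  }
  std <- scale(sub[, keep, drop = FALSE])
  scores <- tryCatch({
    fit <- stats::factanal(std, factors = nFactors, rotation = "none",
                           scores = "regression")
    .fixSigns(unclass(fit$scores), unclass(fit$loadings))
  }, error = function(e) {
    warning("factor fit failed for a pathway (", conditionMessage(e),
            "); falling back to principal-component scores", call. = FALSE)
    .pcaScores(std, nFactors)
  })
  rownames(scores) <- rownames(sub)
  colnames(scores) <- NULL
  scores
}

#' Assemble and clip per-pathway factor scores
#'
#' Horizontally concatenates per-pathway score matrices (in pathway order)
#' and clips every entry to `[-clipBound, clipBound]`.
#'
#' @param perPathway named list of cells x nFactors score matrices sharing
#'   row count and order.
#' @param clipBound positive clipping bound (default 5).
#' @return A [PathwayFactors-class] object.
#' @export
assembleFactors <- function(perPathway, clipBound = 5) {
  if (!length(perPathway)) stop("no score matrices supplied", call. = FALSE)
  nr <- vapply(perPathway, nrow, integer(1))
  if (length(unique(nr)) != 1L)
    stop("inconsistent row counts across pathway score matrices",
         call. = FALSE)
  nf <- unique(vapply(perPathway, ncol, integer(1)))
  if (length(nf) != 1L)
    stop("inconsistent factor counts across pathways", call. = FALSE)
  scores <- do.call(cbind, perPathway)
  scores <- pmin(pmax(scores, -clipBound), clipBound)
  colnames(scores) <- NULL
  new("PathwayFactors", scores = scores,
      pathwayNames = names(perPathway),
      nFactors = as.integer(nf), clipBound = clipBound)
}

.pathwayFactorsImpl <- function(m, geneSets, minPathwayGenes, nFactors,
                                clipBound, seed) {
  subs <- .intersectPathwaysMatrix(m, geneSets, minPathwayGenes)
  scores <- lapply(subs, factorizePathway, nFactors = nFactors, seed = seed)
  assembleFactors(scores, clipBound = clipBound)
}

#' @rdname pathwayFactors
#' @export
setMethod("pathwayFactors", "matrix",
  function(x, geneSets, minPathwayGenes = 10L, nFactors = 2L,
           clipBound = 5, seed = 1L) {
    .pathwayFactorsImpl(x, geneSets, minPathwayGenes, nFactors,
                        clipBound, seed)
  })

#' @rdname pathwayFactors
#' @export
setMethod("pathwayFactors", "SingleCellExperiment",
  function(x, geneSets, minPathwayGenes = 10L, nFactors = 2L,
           clipBound = 5, seed = 1L) {
    .pathwayFactorsImpl(.cellsByGenes(x), geneSets, minPathwayGenes,
                        nFactors, clipBound, seed)
  })
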