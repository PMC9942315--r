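## Evaluation: correlation between inferred pseudotime and ground-truth
## developmental stages (encoded by their ordinal index).

#' Correlation of pseudotime with developmental stages
#'
#' Correlates per-cell pseudotime with the ordinal stage index of each
#' cell. Spearman (the default) is invariant under any strictly increasing
#' transform of the pseudotime and handles ties by midranks; Pearson is
#' available by flag.
#'
#' @param pt named numeric vector of per-cell pseudotime.
#' @param stages named (ordered) factor or named integer vector of
#'   per-cell stages; cell sets must match `pt`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pt <- c(a = 0, b = 1, c = 2)
#' st <- factor(c(a = "S1", b = "S2", c = "S3"), ordered = TRUE)
#' stageCorrelation(pt, st)  # 1
#' @export
stageCorrelation <- function(pt, stages,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(names(pt)) || is.null(names(stages)))
    stop("pseudotime and stages must be named by cell identifiers",
         call. = FALSE)
  if (!setequal(names(pt), names(stages)))
    stop("cell sets of pseudotime and stages do not match", call. = FALSE)
  stages <- stages[names(pt)]
  idx <- if (is.factor(stages)) as.integer(stages) - 1L
         else as.integer(stages)
  if (length(unique(idx)) < 2L || length(unique(pt)) < 2L)
    stop("correlation undefined: constant input", call. = FALSE)
  stats::cor(unname(pt), idx, method = method)
}
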