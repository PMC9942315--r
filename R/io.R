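## External representations: dense CSV/TSV and Matrix Market expression
## matrices, GMT gene sets, start-cell / stage-label text files, and the
## pipeline's output bundle (TSV + GraphML + JSON).

.validateExpression <- function(values, cellIds, geneIds) {
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  if (any(values < 0))
    stop("negative expression values are not allowed", call. = FALSE)
  if (anyDuplicated(cellIds))
    stop("duplicate cell identifiers", call. = FALSE)
  if (anyDuplicated(geneIds))
    stop("duplicate gene identifiers", call. = FALSE)
  if (nrow(values) != length(cellIds) || ncol(values) != length(geneIds))
    stop("dimension/name-count mismatch", call. = FALSE)
  invisible(TRUE)
}

.asSCE <- function(cellsByGenes, cellIds, geneIds) {
  .validateExpression(cellsByGenes, cellIds, geneIds)
  counts <- t(cellsByGenes)
  dimnames(counts) <- list(geneIds, cellIds)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

#' Read an expression matrix
#'
#' Reads a cells-by-genes expression matrix from dense CSV/TSV (header row =
#' gene names, first column = cell names) or Matrix Market triplet format
#' with sibling gene/cell name files, and returns it as a
#' [SingleCellExperiment::SingleCellExperiment-class] with a `counts` assay
#' (genes in rows, cells in columns, Bioconductor orientation).
#'
#' For MTX input the triplet matrix may store cells in rows or genes in
#' rows; the orientation is auto-detected by matching the dimensions against
#' the name-file lengths. A square matrix with equal name counts is
#' ambiguous and requires an explicit `orientation`.
#'
#' @param path path to the matrix file.
#' @param format one of `"auto"` (from extension), `"csv"`, `"tsv"`,
#'   `"mtx"`.
#' @param genesFile,cellsFile name files for MTX input (one identifier per
#'   line); default `<path minus .mtx>.genes.txt` / `.cells.txt`.
#' @param orientation for MTX: `"auto"`, `"cells"` (cells in rows) or
#'   `"genes"` (genes in rows).
#' @param transpose for CSV/TSV: set `TRUE` if the file stores genes in
#'   rows (header = cell names, first column = gene names).
#' @return A `SingleCellExperiment` with assay `counts`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("g1,g2", "c1,0,5", "c2,1,0", "c3,2,2"), f)
#' sce <- readExpression(f)
#' dim(sce)  # 2 genes x 3 cells
#' @export
readExpression <- function(path,
                           format = c("auto", "csv", "tsv", "mtx"),
                           genesFile = NULL, cellsFile = NULL,
                           orientation = c("auto", "cells", "genes"),
                           transpose = FALSE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx",
                     stop("cannot infer format from extension: ", ext,
                          call. = FALSE))
  }
  if (format %in% c("csv", "tsv")) {
    df <- if (format == "csv") {
      utils::read.csv(path, header = TRUE, row.names = 1,
                      check.names = FALSE)
    } else {
      utils::read.delim(path, header = TRUE, row.names = 1,
                        check.names = FALSE)
    }
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    if (transpose) m <- t(m)
    return(.asSCE(m, rownames(m), colnames(m)))
  }
  ## Matrix Market triplets + sibling name files
  stem <- sub("\\.mtx$", "", path)
  if (is.null(genesFile)) genesFile <- paste0(stem, ".genes.txt")
  if (is.null(cellsFile)) cellsFile <- paste0(stem, ".cells.txt")
  for (f in c(genesFile, cellsFile))
    if (!file.exists(f)) stop("name file not found: ", f, call. = FALSE)
  genes <- readLines(genesFile)
  cells <- readLines(cellsFile)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  m <- as.matrix(Matrix::readMM(path))
  storage.mode(m) <- "double"
  fitsCells <- nrow(m) == length(cells) && ncol(m) == length(genes)
  fitsGenes <- nrow(m) == length(genes) && ncol(m) == length(cells)
  if (orientation == "auto") {
    if (fitsCells && fitsGenes)
      stop("square matrix with equal name counts: orientation is ",
           "ambiguous, pass orientation = \"cells\" or \"genes\"",
           call. = FALSE)
    if (fitsCells) orientation <- "cells"
    else if (fitsGenes) orientation <- "genes"
    else stop("matrix dimensions (", nrow(m), " x ", ncol(m),
              ") match neither name-file orientation (", length(cells),
              " cells, ", length(genes), " genes)", call. = FALSE)
  } else {
    ok <- if (orientation == "cells") fitsCells else fitsGenes
    if (!ok) stop("matrix dimensions do not match the requested ",
                  "orientation", call. = FALSE)
  }
  if (orientation == "genes") m <- t(m)
  .asSCE(m, cells, genes)
}

#' Read a GMT gene-set collection
#'
#' Parses a tab-separated GMT file (pathway name, description, then gene
#' identifiers). Line order is preserved; duplicate genes within one line
#' are deduplicated; a duplicated pathway name or a line with fewer than
#' three fields is an error.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors (one per pathway, in file
#'   order) with a `"description"` attribute carrying the per-set free text.
#'   An empty file yields an empty list.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line (fewer than 3 tab-separated fields): ",
           substr(ln, 1, 60), call. = FALSE)
    name <- fields[1]
    if (name %in% names(sets))
      stop("duplicate pathway name: ", name, call. = FALSE)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("pathway with no genes: ", name, call. = FALSE)
    sets[[name]] <- genes
    descs[name] <- fields[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write a GMT gene-set collection
#'
#' Inverse of [readGeneSets()].
#'
#' @param geneSets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(geneSets, path) {
  descs <- attr(geneSets, "description")
  lines <- vapply(names(geneSets), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, geneSets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read start-cell identifiers
#'
#' One identifier per line; blank lines ignored.
#'
#' @param path path to a plain-text file.
#' @return Nonempty character vector of cell identifiers.
#' @export
readStartCells <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("start-cell list is empty", call. = FALSE)
  ids
}

#' Read per-cell stage labels
#'
#' Two-column TSV (cell identifier, stage label; no header). Stage labels
#' become the levels of an ordered factor: numeric labels are ordered
#' numerically, otherwise by first appearance in the file.
#'
#' @param path path to a TSV file.
#' @return Named ordered factor: names are cell ids, levels the ordered
#'   stage names.
#' @export
readStageLabels <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("stage file must have two tab-separated columns", call. = FALSE)
  lab <- df[[2]]
  lv <- unique(lab)
  if (!anyNA(suppressWarnings(as.numeric(lv))))
    lv <- lv[order(as.numeric(lv))]
  stats::setNames(factor(lab, levels = lv, ordered = TRUE), df[[1]])
}

#' Write stage labels
#'
#' Inverse of [readStageLabels()].
#'
#' @param stages named (ordered) factor or named vector of stage labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStageLabels <- function(stages, path) {
  utils::write.table(
    data.frame(cell = names(stages), stage = as.character(stages)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## 10 significant digits: round-trip stable through text
.fmtNum <- function(x) formatC(x, digits = 10, format = "g")

#' Write the pipeline's output bundle
#'
#' Writes `pseudotime.tsv` (cell, ensemble pseudotime), `clusters.tsv`
#' (cell, cluster index), `trajectory.tsv` (directed edge list: parent
#' cluster, child cluster, edge weight), `trajectory.graphml` (the same
#' edges with vertex attributes: center coordinates and mean pseudotime)
#' and `run_meta.json` (parameters, seed, k range, backend name).
#' Floats are serialized with 10 significant digits.
#'
#' @param outdir output directory (created if needed).
#' @param pseudotime named numeric vector of per-cell ensemble pseudotime.
#' @param tree a [TrajectoryTree-class].
#' @param labels named integer vector of per-cell cluster labels.
#' @param meta named list of run metadata for `run_meta.json`.
#' @return `outdir`, invisibly.
#' @export
writeTrajectoryOutputs <- function(outdir, pseudotime, tree, labels,
                                   meta = list()) {
  if (!length(pseudotime))
    stop("empty pseudotime vector", call. = FALSE)
  if (is.null(names(pseudotime)))
    stop("pseudotime must be named by cell identifiers", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("cannot create output directory: ", outdir, call. = FALSE)

  utils::write.table(
    data.frame(cell = names(pseudotime),
               pseudotime = .fmtNum(unname(pseudotime))),
    file.path(outdir, "pseudotime.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(
    data.frame(cell = names(labels), cluster = unname(labels)),
    file.path(outdir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  parent <- treeParents(tree)
  cidx <- treeClusters(tree)
  child <- which(!is.na(parent))
  edges <- data.frame(
    parent_cluster = cidx[parent[child]],
    child_cluster = cidx[child],
    weight = .fmtNum(treeEdgeWeights(tree)[child]))
  if (!nrow(edges))  # single-vertex tree: header-only file
    edges <- edges[0, , drop = FALSE]
  utils::write.table(edges, file.path(outdir, "trajectory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  g <- .treeToIgraph(tree)
  igraph::write_graph(g, file.path(outdir, "trajectory.graphml"),
                      format = "graphml")

  jsonlite::write_json(meta, file.path(outdir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}

.treeToIgraph <- function(tree) {
  parent <- treeParents(tree)
  cidx <- treeClusters(tree)
  n <- length(parent)
  child <- which(!is.na(parent))
  el <- cbind(parent[child], child)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (nrow(el))
    g <- igraph::add_edges(g, t(el),
                           weight = treeEdgeWeights(tree)[child])
  igraph::V(g)$name <- as.character(cidx)
  igraph::V(g)$meanPseudotime <- treePseudotime(tree)
  igraph::V(g)$center <- vapply(seq_len(n), function(i)
    paste(.fmtNum(treeCenters(tree)[i, ]), collapse = " "), character(1))
  g
}

#' Read a trajectory edge list
#'
#' Reads the `trajectory.tsv` written by [writeTrajectoryOutputs()].
#'
#' @param path path to the edge-list TSV.
#' @return data.frame with columns `parent_cluster`, `child_cluster`
#'   (integer) and `weight` (numeric).
#' @export
readTrajectoryEdges <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE)
  if (!nrow(df))
    return(data.frame(parent_cluster = integer(), child_cluster = integer(),
                      weight = numeric()))
  data.frame(parent_cluster = as.integer(df$parent_cluster),
             child_cluster = as.integer(df$child_cluster),
             weight = as.numeric(df$weight))
}

#' Write an expression matrix as dense CSV
#'
#' Cells in rows, genes in columns; header row = gene names, first column =
#' cell names (the canonical dense dialect read by [readExpression()]).
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment-class] or a
#'   cells-by-genes matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionCSV <- function(x, path) {
  m <- if (methods::is(x, "SingleCellExperiment"))
    t(SummarizedExperiment::assay(x, "counts")) else x
  df <- data.frame(m, check.names = FALSE)
  utils::write.table(cbind(cell = rownames(m), df), path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
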