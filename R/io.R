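# Readers and writers for the pipeline's plain-text interchange formats:
# delimited expression/phenotype tables, GMT gene sets, edge lists, GraphML.

.sepFromPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Sample-count guidance for co-expression analysis
#'
#' Correlation networks computed on very few samples are unstable. Fewer than
#' 3 samples cannot support a correlation at all; around 20 samples is the
#' usual minimum recommendation, and 100 or more gives robust networks.
#'
#' @param nSamples number of samples.
#' @return A list with `nSamples` and `level`, one of `"error"` (< 3),
#'   `"warn"` (< 20), `"ok"` (>= 20), `"robust"` (>= 100).
#' @examples
#' sampleSizeAdvice(25)
#' @export
sampleSizeAdvice <- function(nSamples) {
  level <- if (nSamples < 3) "error"
  else if (nSamples < 20) "warn"
  else if (nSamples < 100) "ok"
  else "robust"
  list(nSamples = as.integer(nSamples), level = level)
}

.adviseSampleSize <- function(n) {
  adv <- sampleSizeAdvice(n)
  msg <- sprintf("dataset has %d samples (%s)", n, switch(adv$level,
    error = "too few for correlation analysis",
    warn = "below the ~20-sample recommendation; networks may be unstable",
    ok = "adequate; 100+ samples give more robust networks",
    robust = "robust sample size"))
  if (adv$level %in% c("error", "warn")) warning(msg, call. = FALSE)
  else message(msg)
  invisible(adv)
}

.readTable <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected one id column plus data columns: ", path)
  if (anyDuplicated(colnames(df))) stop("duplicate column ids in ", path)
  if (anyDuplicated(df[[1]])) stop("duplicate row ids in ", path)
  rownames(df) <- as.character(df[[1]])
  df[-1]
}

#' Read an expression matrix from a delimited text file
#'
#' Reads a TSV/CSV table with one header row and one id column into an
#' [ExpressionDataset-class], normalizing orientation to samples x genes.
#' The delimiter is inferred from the file extension (`.csv` -> comma,
#' otherwise tab) unless `sep` is given. A sample-count advisory is emitted
#' (a warning below 20 samples, a message otherwise).
#'
#' @param path file path.
#' @param orientation `"samples_by_genes"` (rows are samples, the stored
#'   convention) or `"genes_by_samples"` (table is transposed on read).
#' @param naPolicy `"fail"` (default: any missing value is an error) or
#'   `"drop_genes"` (remove every gene column containing a missing value).
#' @param sep optional field separator overriding the extension rule.
#' @return An [ExpressionDataset-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(simulateExpression(simulationConfig(5, nBackground = 4))$dataset, tf)
#' readExpression(tf)
#' @export
readExpression <- function(path,
                           orientation = c("samples_by_genes", "genes_by_samples"),
                           naPolicy = c("fail", "drop_genes"), sep = NULL) {
  orientation <- match.arg(orientation)
  naPolicy <- match.arg(naPolicy)
  df <- .readTable(path, .sepFromPath(path, sep))
  nonNum <- !vapply(df, is.numeric, logical(1))
  if (any(nonNum))
    stop("non-numeric cells in column(s): ",
         paste(utils::head(colnames(df)[nonNum], 5), collapse = ", "))
  m <- as.matrix(df)
  if (orientation == "genes_by_samples") m <- t(m)
  if (anyNA(m)) {
    if (naPolicy == "fail")
      stop("missing values present; use naPolicy = 'drop_genes' to remove them")
    bad <- colSums(is.na(m)) > 0
    message("dropping ", sum(bad), " gene(s) with missing values")
    m <- m[, !bad, drop = FALSE]
  }
  ds <- ExpressionDataset(m)
  .adviseSampleSize(nrow(m))
  ds
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: samples as rows, genes as columns, the
#' sample id in the first column. Values round-trip at full double precision.
#'
#' @param ds an [ExpressionDataset-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeExpression <- function(ds, path) {
  m <- exprValues(ds)
  df <- data.frame(sample = rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample", colnames(m))
  .writeTsv(df, path)
}

#' Read a phenotype table
#'
#' One row per sample (first column = sample id), one column per phenotype
#' variable; numeric columns are treated as quantitative and character
#' columns as categorical.
#'
#' @param path file path (TSV/CSV, delimiter from extension).
#' @param sep optional separator override.
#' @return A data.frame with sample ids as rownames.
#' @export
readPhenotypes <- function(path, sep = NULL) {
  .readTable(path, .sepFromPath(path, sep))
}

#' Read a GMT gene set collection
#'
#' Standard Gene Matrix Transposed format: one term per line, tab-separated
#' fields `term_id`, `description`, then gene ids. Duplicate genes within a
#' line are deduplicated; duplicate term ids are an error.
#'
#' @param path file path.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(utils::head(which(short), 5), collapse = ", "))
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- ids
  descriptions <- stats::setNames(vapply(fields, `[[`, character(1), 2), ids)
  GeneSetCollection(genes, descriptions)
}

.edgeTable <- function(tom, edgeMin) {
  g <- colnames(tom)
  idx <- which(upper.tri(tom) & tom >= edgeMin, arr.ind = TRUE)
  a <- g[idx[, 1]]; b <- g[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(gene_a = a, gene_b = b,
                   weight = tom[idx], stringsAsFactors = FALSE)
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

#' Export a network to an edge list or GraphML
#'
#' Writes the undirected TOM network of a build, keeping only edges with
#' weight at least `edgeMin`. The edge list has columns `gene_a`, `gene_b`,
#' `weight` with `gene_a < gene_b` lexicographically; GraphML carries the
#' weight as an edge attribute (and retains isolated vertices).
#'
#' @param build a [NetworkBuild-class].
#' @param path output path.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @param edgeMin minimum TOM weight in [0, 1].
#' @return The path, invisibly.
#' @export
writeNetwork <- function(build, path, format = c("edge_list_tsv", "graphml"),
                         edgeMin = 0) {
  format <- match.arg(format)
  if (edgeMin < 0 || edgeMin > 1) stop("edgeMin must lie in [0, 1]")
  edges <- .edgeTable(tomMatrix(build), edgeMin)
  if (format == "edge_list_tsv") return(.writeTsv(edges, path))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = geneIds(build)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
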