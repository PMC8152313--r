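# Internal helpers shared across the pipeline.

# lower-triangle (off-diagonal) values of a square matrix, column-major
.lowerTri <- function(m) m[lower.tri(m)]

.isSquare <- function(m) is.matrix(m) && nrow(m) == ncol(m)

.checkSymmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!.isSquare(m)) stop(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol) stop(what, " must be symmetric")
  invisible(TRUE)
}

# force exact symmetry and clamp to [lo, hi]; used after floating-point ops
.symClamp <- function(m, lo = 0, hi = 1) {
  m <- (m + t(m)) / 2
  m[m < lo] <- lo
  m[m > hi] <- hi
  m
}

# correlation that returns NaN (not an error/warning) on zero-variance input
.corQuiet <- function(x, y = NULL, method = "pearson") {
  r <- suppressWarnings(stats::cor(x, y, method = method))
  r[is.na(r)] <- NaN
  r
}

# z-score columns of a matrix; errors naming zero-variance columns
.zscore <- function(x, what = "gene") {
  sds <- apply(x, 2, stats::sd)
  bad <- colnames(x)[sds == 0]
  if (length(bad) > 0) {
    stop("zero-variance ", what, "(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  }
  scale(x)
}

# deterministic relabeling: modules 1..M by decreasing size, ties broken by
# the lexicographically smallest member gene id; 0 stays 0 (unassigned)
.relabelBySize <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  firstGene <- vapply(ids, function(i) min(names(labels)[labels == i]), character(1))
  ord <- ids[order(-sizes, firstGene)]
  out <- labels
  for (newId in seq_along(ord)) out[labels == ord[newId]] <- newId
  out
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeMatrixTsv <- function(m, path, idCol = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- idCol
  .writeTsv(df, path)
}
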