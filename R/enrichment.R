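# Biological integration: local over-representation analysis against GMT
# collections and eigengene-phenotype association.

#' Over-representation analysis of modules against gene sets
#'
#' Hypergeometric upper-tail test of each real module (id >= 1; module 0 is
#' the false module of unassigned genes and is never tested) against each
#' term of a GMT collection, restricted to a background universe (the network
#' genes by default). With universe size N, background-restricted term size
#' K, module size n and overlap x, the p-value is
#' P(X >= x) for X ~ Hypergeometric(N, K, n). Benjamini-Hochberg adjustment
#' is applied jointly across all tested (module, term) pairs.
#'
#' @param partition a [ModulePartition-class].
#' @param sets a [GeneSetCollection-class] sharing the identifier namespace.
#' @param background `NULL` for the network genes, or a custom character
#'   vector. A custom background that misses module genes triggers a warning
#'   and modules are intersected with it.
#' @param minTerm,maxTerm term-size bounds (background-restricted) for a term
#'   to be tested (defaults 5 and 1000).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return A data.frame with columns module, term_id, term_size,
#'   overlap_count, overlap_genes, p_value, adjusted_p, significant.
#' @export
oraEnrich <- function(partition, sets, background = NULL, minTerm = 5,
                      maxTerm = 1000, alpha = 0.05) {
  labels <- moduleLabels(partition)
  if (is.null(background)) background <- names(labels)
  background <- unique(as.character(background))
  if (length(background) == 0) stop("empty background")
  ids <- sort(unique(labels[labels > 0]))
  N <- length(background)
  termBg <- lapply(geneSets(sets), intersect, background)
  K <- lengths(termBg)
  testable <- which(K >= minTerm & K <= maxTerm)
  rows <- list()
  for (mod in ids) {
    modGenes <- names(labels)[labels == mod]
    outside <- setdiff(modGenes, background)
    if (length(outside) > 0)
      warning("module ", mod, ": ", length(outside),
              " gene(s) outside the background were dropped", call. = FALSE)
    modBg <- intersect(modGenes, background)
    n <- length(modBg)
    if (n == 0) next
    for (t in testable) {
      ov <- intersect(modBg, termBg[[t]])
      x <- length(ov)
      p <- stats::phyper(x - 1, K[t], N - K[t], n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, term_id = names(termBg)[t], term_size = K[t],
        overlap_count = x,
        overlap_genes = paste(sort(ov), collapse = ","),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(module = integer(0), term_id = character(0),
               term_size = integer(0), overlap_count = integer(0),
               overlap_genes = character(0), p_value = numeric(0))
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha
  rownames(out) <- NULL
  out
}

#' Dummy (one-vs-rest) encoding of a categorical variable
#'
#' Expands a categorical column into one binary indicator per level, named
#' `variable=level`. All levels are kept (no reference level is dropped)
#' because each indicator is tested marginally by correlation, not jointly in
#' a regression. A numeric column that is already binary (values in {0, 1})
#' is returned unchanged as a single column.
#'
#' @param column vector (character/factor, or numeric 0/1).
#' @param name variable name used as the column-name prefix.
#' @return A numeric matrix of indicator columns.
#' @export
dummyEncode <- function(column, name = "x") {
  if (is.numeric(column)) {
    if (all(column %in% c(0, 1)))
      return(matrix(column, ncol = 1, dimnames = list(NULL, name)))
    stop("numeric non-binary column; dummy encoding is for categorical data")
  }
  f <- factor(column)
  if (nlevels(f) < 2) stop("categorical column must have >= 2 observed levels")
  m <- vapply(levels(f), function(l) as.numeric(f == l),
              numeric(length(column)))
  colnames(m) <- paste0(name, "=", levels(f))
  m
}

# expand a phenotype data.frame into numeric test columns, tracking
# (variable, level) provenance per column
.phenoColumns <- function(pheno) {
  cols <- list(); varOf <- character(0); levelOf <- character(0)
  for (v in colnames(pheno)) {
    x <- pheno[[v]]
    if (is.numeric(x)) {
      cols[[length(cols) + 1L]] <- x
      varOf <- c(varOf, v); levelOf <- c(levelOf, NA_character_)
    } else {
      m <- dummyEncode(x, v)
      for (j in seq_len(ncol(m))) {
        cols[[length(cols) + 1L]] <- m[, j]
        varOf <- c(varOf, v)
        levelOf <- c(levelOf, sub("^.*=", "", colnames(m)[j]))
      }
    }
  }
  list(cols = cols, variable = varOf, level = levelOf)
}

#' Eigengene-phenotype association
#'
#' Correlates every module eigengene with every phenotype variable
#' (quantitative variables directly; categorical variables through one-vs-rest
#' dummy indicators) over the samples shared by expression and phenotype
#' data. Two-sided p-values use the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom
#' (|r| = 1 gives p = 0); Benjamini-Hochberg adjustment is joint across all
#' (module, variable) pairs.
#'
#' @param partition a [ModulePartition-class] with >= 1 module.
#' @param pheno data.frame of phenotypes with sample ids as rownames (see
#'   [readPhenotypes()]).
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance level for the `significant` flag.
#' @return A data.frame with columns module, variable, level, r, p_value,
#'   adjusted_p, n, significant.
#' @export
associatePhenotypes <- function(partition, pheno,
                                method = c("pearson", "spearman"),
                                alpha = 0.05) {
  method <- match.arg(method)
  E <- eigengenes(partition)
  if (ncol(E) == 0) stop("partition has no modules")
  shared <- intersect(rownames(E), rownames(pheno))
  if (length(shared) < 3) stop("sample overlap must be >= 3 after inner join")
  E <- E[shared, , drop = FALSE]
  pheno <- pheno[shared, , drop = FALSE]
  px <- .phenoColumns(pheno)
  n <- length(shared)
  rows <- list()
  for (j in seq_along(px$cols)) {
    v <- px$cols[[j]]
    if (stats::sd(v) == 0) {
      warning("skipping zero-variance variable: ", px$variable[j],
              if (!is.na(px$level[j])) paste0("=", px$level[j]) else "",
              call. = FALSE)
      next
    }
    for (me in colnames(E)) {
      r <- .corQuiet(E[, me], v, method = method)
      p <- if (is.nan(r)) NaN
      else if (abs(r) >= 1) 0
      else 2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)
      rows[[length(rows) + 1L]] <- data.frame(
        module = as.integer(sub("^ME", "", me)), variable = px$variable[j],
        level = px$level[j], r = r, p_value = p, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(module = integer(0), variable = character(0),
               level = character(0), r = numeric(0), p_value = numeric(0),
               n = integer(0))
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha
  rownames(out) <- NULL
  out
}

#' Plot enrichment results
#'
#' Static scatter of -log10 adjusted p per term, grouped by module.
#'
#' @param enrichment data.frame from [oraEnrich()].
#' @param alpha significance line (default 0.05).
#' @return Invisibly, the enrichment table.
#' @export
plotEnrichment <- function(enrichment, alpha = 0.05) {
  if (nrow(enrichment) == 0) stop("empty enrichment table")
  graphics::plot(jitter(enrichment$module), -log10(enrichment$adjusted_p),
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "module", ylab = "-log10 adjusted p")
  graphics::abline(h = -log10(alpha), lty = 2, col = "red3")
  invisible(enrichment)
}
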