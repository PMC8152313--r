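# Co-expression network construction: correlation -> soft-threshold power
# selection against scale-free topology -> adjacency |r|^beta -> topological
# overlap matrix (TOM), the pipeline's final co-expression score.

#' Gene-gene correlation matrix
#'
#' Pearson or Spearman correlation between all gene pairs. Spearman (rank)
#' correlation captures monotone relationships and is less sensitive to
#' outliers. Zero-variance genes make correlation undefined and are an error.
#'
#' @param ds an [ExpressionDataset-class] with at least 3 samples.
#' @param method `"pearson"` (default) or `"spearman"` (average ranks on
#'   ties).
#' @return A symmetric gene x gene correlation matrix with unit diagonal.
#' @export
correlateExpression <- function(ds, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- exprValues(ds)
  if (nrow(m) < 3) stop("correlation needs >= 3 samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(colnames(m)[sds == 0], 5), collapse = ", "))
  r <- stats::cor(m, method = method)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power beta the unsigned adjacency `|r|^beta` is formed
#' and the connectivity distribution k_i = sum_j a_ij is tested for
#' approximate scale-free topology: connectivities are discretized into
#' `nBins` equal-width bins, and log10(mean frequency) is regressed on
#' log10(mean connectivity) over non-empty bins with positive mean
#' connectivity. The signed fit index is `-sign(slope) * R^2`, so only
#' decreasing (power-law-like) relationships can pass. The smallest beta
#' whose signed R^2 reaches `r2Cut` is returned.
#'
#' @param correlation a correlation matrix over at least 10 genes.
#' @param candidatePowers integer powers to try (default 1:30).
#' @param r2Cut required signed R^2 (default 0.85).
#' @param nBins number of equal-width connectivity bins (default 10).
#' @return A list with `power` (chosen beta) and `fitTable` (data.frame with
#'   columns power, r2_signed, slope, mean_k, n_bins_used).
#' @section Aberrant power: if no candidate reaches `r2Cut`, an error of
#'   class `"coexpnet_aberrant_power"` is signalled; its `fitTable` field
#'   carries the full fit table for inspection.
#' @export
fitSoftPower <- function(correlation, candidatePowers = 1:30, r2Cut = 0.85,
                         nBins = 10) {
  .checkSymmetric(correlation, "correlation")
  n <- nrow(correlation)
  if (n < 10) stop("power fit needs >= 10 genes")
  candidatePowers <- sort(unique(as.integer(candidatePowers)))
  if (any(candidatePowers < 1)) stop("candidate powers must be >= 1")
  absr <- abs(correlation)
  rows <- lapply(candidatePowers, function(beta) {
    a <- absr^beta
    diag(a) <- 0
    k <- rowSums(a)
    fit <- .scaleFreeFit(k, nBins)
    data.frame(power = beta, r2_signed = fit$r2Signed, slope = fit$slope,
               mean_k = mean(k), n_bins_used = fit$nBinsUsed)
  })
  tab <- do.call(rbind, rows)
  usable <- !is.na(tab$r2_signed)
  if (!any(usable))
    stop("degenerate connectivity distribution: fewer than 3 usable bins ",
         "for every candidate power")
  pass <- usable & tab$r2_signed >= r2Cut
  if (!any(pass)) {
    stop(errorCondition(
      sprintf(paste0("aberrant power: no candidate power reaches signed R^2 ",
                     ">= %.3g (best %.3g at power %d); inspect the fitTable ",
                     "field of this condition"),
              r2Cut, max(tab$r2_signed, na.rm = TRUE),
              tab$power[which.max(tab$r2_signed)]),
      fitTable = tab, class = "coexpnet_aberrant_power"))
  }
  list(power = tab$power[which(pass)[1]], fitTable = tab)
}

# binned log-log regression of the connectivity distribution;
# returns NA r2 when fewer than 3 usable bins exist
.scaleFreeFit <- function(k, nBins) {
  out <- list(r2Signed = NA_real_, slope = NA_real_, nBinsUsed = 0L)
  if (max(k) == min(k)) return(out)
  breaks <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nBins)
  meanK <- vapply(seq_len(nBins),
                  function(b) if (counts[b] > 0) mean(k[as.integer(bin) == b]) else NA_real_,
                  numeric(1))
  freq <- counts / length(k)
  use <- counts > 0 & !is.na(meanK) & meanK > 0
  if (sum(use) < 3) return(out)
  x <- log10(meanK[use]); y <- log10(freq[use])
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r2Signed = -sign(slope) * r2, slope = slope,
       nBinsUsed = as.integer(sum(use)))
}

#' Unsigned adjacency from a correlation matrix
#'
#' `a_ij = |r_ij|^beta`, with the diagonal forced to 1.
#'
#' @param correlation correlation matrix.
#' @param power soft-threshold exponent beta (>= 1).
#' @return The adjacency matrix in [0, 1].
#' @export
adjacencyFromCor <- function(correlation, power) {
  if (power < 1) stop("power must be >= 1")
  a <- abs(correlation)^power
  diag(a) <- 1
  .symClamp(a)
}

#' Topological overlap matrix (TOM)
#'
#' Combines direct adjacency with shared-neighbor agreement. For i != j, with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`:
#' `T_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, and `T_ii = 1`.
#' Genes sharing many strong neighbors score high even when their direct
#' adjacency is moderate.
#'
#' @param adjacency symmetric adjacency in [0, 1] with unit diagonal.
#' @return The TOM, symmetric in [0, 1] with unit diagonal.
#' @export
tomFromAdjacency <- function(adjacency) {
  .checkSymmetric(adjacency, "adjacency")
  if (min(adjacency) < -1e-12 || max(adjacency) > 1 + 1e-12)
    stop("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a                       # L_ij = sum_u a_iu a_uj (u != i, j as diag(a)=0)
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  .symClamp(tom)
}

#' Build a co-expression network
#'
#' Composes [correlateExpression()], [fitSoftPower()], [adjacencyFromCor()]
#' and [tomFromAdjacency()] into a [NetworkBuild-class], recording every
#' parameter in the metadata for provenance.
#'
#' @param ds an [ExpressionDataset-class].
#' @param corMethod `"pearson"` or `"spearman"`.
#' @param candidatePowers,r2Cut,nBins passed to [fitSoftPower()].
#' @param power optional explicit beta; skips the scale-free fit.
#' @return A [NetworkBuild-class].
#' @examples
#' sim <- simulateExpression(simulationConfig(40, moduleSizes = c(20, 20),
#'                                            nBackground = 20, seed = 7))
#' net <- buildNet(sim$dataset, power = 6)
#' softPower(net)
#' @export
buildNet <- function(ds, corMethod = c("pearson", "spearman"),
                     candidatePowers = 1:30, r2Cut = 0.85, nBins = 10,
                     power = NULL) {
  corMethod <- match.arg(corMethod)
  r <- correlateExpression(ds, corMethod)
  if (is.null(power)) {
    fit <- fitSoftPower(r, candidatePowers, r2Cut, nBins)
    power <- fit$power
    fitTab <- fit$fitTable
  } else {
    if (power < 1) stop("power must be >= 1")
    fitTab <- data.frame()
  }
  adj <- adjacencyFromCor(r, power)
  tom <- tomFromAdjacency(adj)
  new("NetworkBuild", geneIds = colnames(r), corMethod = corMethod,
      networkType = "unsigned", correlation = r, power = as.numeric(power),
      fitTable = fitTab, adjacency = adj, tom = tom,
      metadata = list(cor_method = corMethod, network_type = "unsigned",
                      power = as.numeric(power), r2_cut = r2Cut,
                      n_bins = nBins,
                      candidate_powers = range(candidatePowers),
                      power_fitted = is.null(fitTab) || nrow(fitTab) > 0,
                      n_samples = nrow(exprValues(ds)),
                      n_genes = ncol(exprValues(ds)),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}
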