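# Optional gene filters applied before network construction. Over-filtering
# can remove informative signal and distort the scale-free property, so both
# filters are conservative by default.

.filterResult <- function(ds, keep, kind, params) {
  m <- exprValues(ds)
  removed <- colnames(m)[!keep]
  out <- ExpressionDataset(m[, keep, drop = FALSE])
  report <- new("FilterReport", nIn = ncol(m), nOut = as.integer(sum(keep)),
                removedIds = removed, filterKind = kind, parameters = params)
  list(dataset = out, report = report)
}

#' Filter genes with low counts
#'
#' Removes genes whose (count-like, non-negative) expression never reaches a
#' threshold, to avoid mistaking technical background noise for expression.
#' The default mode `"at_least_one"` keeps a gene if any sample reaches the
#' threshold — the most permissive rule, since over-filtering can remove
#' informative signal.
#'
#' @param ds an [ExpressionDataset-class] of count-like values.
#' @param threshold count threshold (default 5).
#' @param mode `"at_least_one"` (max over samples >= threshold), `"mean"`
#'   (mean >= threshold) or `"all"` (min >= threshold).
#' @return A list with `dataset` (filtered [ExpressionDataset-class]) and
#'   `report` (a [FilterReport-class]).
#' @examples
#' ds <- asCounts(simulateExpression(simulationConfig(10, nBackground = 20))$dataset,
#'                scale = 20)
#' filterLowCounts(ds, threshold = 5)$report
#' @export
filterLowCounts <- function(ds, threshold = 5,
                            mode = c("at_least_one", "mean", "all")) {
  mode <- match.arg(mode)
  if (threshold < 0) stop("threshold must be >= 0")
  m <- exprValues(ds)
  if (min(m) < 0) stop("negative values present; low-count filter expects counts")
  stat <- switch(mode,
                 at_least_one = apply(m, 2, max),
                 mean = colMeans(m),
                 all = apply(m, 2, min))
  .filterResult(ds, stat >= threshold, "low_count",
                list(threshold = threshold, mode = mode))
}

#' Filter genes with low variation
#'
#' Removes genes whose expression is too similar across samples: genes that
#' barely vary cannot be meaningfully co-clustered and add noise to module
#' detection. The per-gene dispersion (MAD by default, for outlier
#' robustness) is computed and genes strictly below the `quantileCut`
#' empirical quantile of the dispersion distribution are removed; ties at the
#' quantile are kept.
#'
#' @param ds an [ExpressionDataset-class].
#' @param dispersion `"mad"`, `"variance"` or `"cv"` (coefficient of
#'   variation; errors if any gene mean is 0).
#' @param quantileCut fraction in [0, 1); genes below this dispersion
#'   quantile are removed (default 0.10; 0 removes nothing).
#' @return A list with `dataset` and `report`, as [filterLowCounts()].
#' @export
filterLowVariation <- function(ds, dispersion = c("mad", "variance", "cv"),
                               quantileCut = 0.10) {
  dispersion <- match.arg(dispersion)
  if (quantileCut < 0 || quantileCut >= 1) stop("quantileCut must lie in [0, 1)")
  m <- exprValues(ds)
  if (nrow(m) < 2) stop("low-variation filter needs >= 2 samples")
  disp <- switch(dispersion,
                 mad = apply(m, 2, stats::mad),
                 variance = apply(m, 2, stats::var),
                 cv = {
                   mu <- colMeans(m)
                   if (any(mu == 0)) stop("cv undefined: gene(s) with mean 0")
                   apply(m, 2, stats::sd) / mu
                 })
  cut <- stats::quantile(disp, quantileCut, names = FALSE)
  .filterResult(ds, disp >= cut, "low_variation",
                list(dispersion = dispersion, quantile_cut = quantileCut,
                     dispersion_cut = cut))
}
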