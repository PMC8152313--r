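# Synthetic expression generator: a single-factor-per-module model with
# planted modules, background noise genes, and controlled per-module
# perturbations for condition comparison. The test bed for every other stage.

.simGeneIds <- function(total) sprintf("g%04d", seq_len(total))
.simSampleIds <- function(n, prefix = "S") sprintf("%s%03d", prefix, seq_len(n))

# draw one dataset from the factor model; perturb[m] in none/rewire/destroy
# applies to module m ("rewire" replaces a leading fraction of member genes
# by fresh independent noise, "destroy" all of them)
.simDraw <- function(cfg, perturb, samplePrefix) {
  n <- cfg@nSamples
  sizes <- cfg@moduleSizes
  total <- sum(sizes) + cfg@nBackground
  genes <- .simGeneIds(total)
  labels <- stats::setNames(rep(0L, total), genes)
  x <- matrix(NA_real_, n, total,
              dimnames = list(.simSampleIds(n, samplePrefix), genes))
  factors <- matrix(numeric(0), n, 0)
  if (length(sizes) > 0) {
    factors <- vapply(seq_along(sizes), function(m) stats::rnorm(n), numeric(n))
    colnames(factors) <- paste0("F", seq_along(sizes))
    rownames(factors) <- rownames(x)
  }
  pos <- 0L
  for (m in seq_along(sizes)) {
    beta <- cfg@coherence[m]
    idx <- pos + seq_len(sizes[m])
    labels[idx] <- m
    nNoise <- switch(perturb[m],
                     none = 0L,
                     destroy = sizes[m],
                     rewire = as.integer(ceiling(cfg@rewireFraction[m] * sizes[m])))
    for (j in seq_along(idx)) {
      if (j <= nNoise) {
        x[, idx[j]] <- stats::rnorm(n)
      } else {
        x[, idx[j]] <- beta * factors[, m] +
          sqrt(1 - beta^2) * stats::rnorm(n) +
          cfg@noiseSd * stats::rnorm(n)
      }
    }
    pos <- pos + sizes[m]
  }
  for (j in (pos + seq_len(cfg@nBackground))) x[, j] <- stats::rnorm(n)
  list(dataset = ExpressionDataset(x), labels = labels, factors = factors)
}

#' Simulate expression with planted co-expression modules
#'
#' Draws from the factor model of the [SimulationConfig-class]: per module a
#' latent factor f ~ N(0,1) over samples, member genes
#' `x = beta*f + sqrt(1 - beta^2)*eps + noiseSd*eta` with independent
#' standard-normal eps and eta, and pure-noise background genes. Without
#' extra noise the expected within-module gene-pair correlation is beta^2.
#' Fully deterministic under the config seed.
#'
#' @param cfg a [SimulationConfig-class].
#' @return A list with `dataset` ([ExpressionDataset-class]), `labels`
#'   (named integer truth, 0 = background) and `factors` (samples x modules
#'   matrix of the planted factors).
#' @examples
#' sim <- simulateExpression(simulationConfig(30, moduleSizes = 20,
#'                                            nBackground = 10, seed = 3))
#' table(sim$labels)
#' @export
simulateExpression <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed)
  k <- length(cfg@moduleSizes)
  .simDraw(cfg, perturb = rep("none", k), samplePrefix = "S")
}

#' Simulate a discovery/test condition pair
#'
#' The discovery condition is a draw from the config with perturbations
#' ignored. The test condition is an independent draw (fresh factors and
#' noise — new samples from the same population) in which each module's
#' perturbation is applied: `"none"` keeps the generative law, `"rewire"`
#' replaces a fraction of member genes by independent noise, `"destroy"`
#' replaces all of them (the module's structure is absent in the test
#' condition).
#'
#' @param cfg a [SimulationConfig-class].
#' @return A list with `discovery`, `test` (each as the list returned by
#'   [simulateExpression()]) and `truth` (labels, perturbation per module,
#'   rewire fractions, seed).
#' @export
simulateConditionPair <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  k <- length(cfg@moduleSizes)
  set.seed(cfg@seed)
  discovery <- .simDraw(cfg, perturb = rep("none", k), samplePrefix = "D")
  set.seed(cfg@seed + 1000003L)
  test <- .simDraw(cfg, perturb = cfg@perturbation, samplePrefix = "T")
  list(discovery = discovery, test = test,
       truth = list(labels = discovery$labels,
                    perturbation = cfg@perturbation,
                    rewire_fraction = cfg@rewireFraction,
                    seed = cfg@seed))
}

#' Simulate a phenotype correlated with a planted factor
#'
#' `y = effectR * f + sqrt(1 - effectR^2) * noise`; a binary phenotype is the
#' median split of the quantitative one (levels "low"/"high").
#'
#' @param ds the [ExpressionDataset-class] the factor belongs to (supplies
#'   sample ids).
#' @param factor numeric vector over samples (a column of the simulation's
#'   `factors`).
#' @param effectR target correlation in [-1, 1].
#' @param kind `"quantitative"` or `"binary"`.
#' @param seed optional RNG seed.
#' @return A one-column data.frame (`phenotype`) with sample ids as
#'   rownames.
#' @export
simulatePhenotype <- function(ds, factor, effectR,
                              kind = c("quantitative", "binary"),
                              seed = NULL) {
  kind <- match.arg(kind)
  if (abs(effectR) > 1) stop("effectR must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(exprValues(ds))
  stopifnot(length(factor) == n)
  y <- effectR * factor + sqrt(1 - effectR^2) * stats::rnorm(n)
  out <- data.frame(phenotype = if (kind == "binary")
    ifelse(y > stats::median(y), "high", "low") else y,
    row.names = sampleIds(ds), stringsAsFactors = FALSE)
  out
}

#' Count-like transform of simulated expression
#'
#' `round(scale * exp(x))`: maps the Gaussian factor-model output onto
#' non-negative integers so the low-count filter has realistic input. Not a
#' sequencing noise model.
#'
#' @param ds an [ExpressionDataset-class].
#' @param scale positive multiplier before rounding (default 1).
#' @return An [ExpressionDataset-class] of counts.
#' @export
asCounts <- function(ds, scale = 1) {
  if (scale <= 0) stop("scale must be > 0")
  ExpressionDataset(round(scale * exp(exprValues(ds))))
}
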