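# End-to-end pipeline runner: stages are chained through plain TSV/JSON
# files so any stage can be replaced by an external tool producing the same
# format. Every run writes a JSON manifest for provenance.

#' Rebuild a module partition from labels
#'
#' Recomputes eigengenes and kME for a label vector (e.g. read back from a
#' `modules.tsv` produced by an earlier run, or planted simulation truth) so
#' that downstream stages (association, preservation) can run standalone.
#' Labels are renumbered 1..M by decreasing size.
#'
#' @param ds the [ExpressionDataset-class] the labels refer to.
#' @param labels named integer vector (0 = unassigned).
#' @return A [ModulePartition-class] (no dendrogram, empty merge history).
#' @export
partitionFromLabels <- function(ds, labels) {
  labels <- labels[names(labels) %in% geneIds(ds)]
  if (length(labels) == 0) stop("no labels match the dataset's genes")
  storage.mode(labels) <- "integer"
  labels <- .relabelBySize(labels)
  E <- .moduleEigengenes(ds, labels)
  km <- if (ncol(E) > 0) .corQuiet(exprValues(ds), E) else
    matrix(numeric(0), nrow = ncol(exprValues(ds)), ncol = 0,
           dimnames = list(geneIds(ds), NULL))
  new("ModulePartition", labels = labels, labelsPremerge = labels,
      dendrogram = NULL, eigengenes = E, kme = km,
      mergeHistory = data.frame(absorbed = integer(0),
                                surviving = integer(0),
                                eigengene_cor = numeric(0)))
}

#' Read module labels from TSV
#'
#' Expects at least columns `gene` and `module` (as written by
#' [runPipeline()]).
#'
#' @param path file path.
#' @return Named integer vector.
#' @export
readModuleLabels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "module") %in% colnames(df)))
    stop("expected columns 'gene' and 'module' in ", path)
  stats::setNames(as.integer(df$module), df$gene)
}

.writeModulesTsv <- function(partition, path) {
  labels <- moduleLabels(partition)
  .writeTsv(data.frame(gene = names(labels), module = as.integer(labels),
                       module_premerge = as.integer(moduleLabelsPremerge(partition)),
                       stringsAsFactors = FALSE), path)
}

.writeNumMatrixTsv <- function(m, path, idCol) {
  df <- data.frame(rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idCol, colnames(m))
  .writeTsv(df, path)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.writeManifest <- function(outDir, subcommand, parameters, seed, inputs,
                           outputs) {
  digests <- if (length(inputs) > 0)
    as.list(tools::md5sum(unlist(inputs))) else list()
  .writeJson(list(tool = "coexpnet",
                  version = as.character(utils::packageVersion("coexpnet")),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  subcommand = subcommand, parameters = parameters,
                  seed = seed, input_digests = digests,
                  outputs = as.list(outputs)),
             file.path(outDir, "manifest.json"))
}

.cfgGet <- function(cfg, key, default = NULL) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages enabled in the configuration (a YAML file path or an
#' equivalent nested list): input or simulation, optional filters, network
#' construction, module detection, then — when configured — enrichment,
#' phenotype association, hub detection, sub-modules and condition
#' comparison. Each stage writes its results as TSV/JSON into `outDir`, and
#' the run ends with a `manifest.json` capturing every parameter, input
#' digest and output file. Reruns with identical configuration and seed are
#' byte-identical except for the manifest timestamp.
#'
#' @param config path to a YAML configuration, or a named list.
#' @param outDir output directory (created if needed).
#' @param seed optional integer overriding the configured seed.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(seed)) seed <- .cfgGet(cfg, "seed", 1L)
  seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  if (is.character(config)) inputs$config <- config
  outputs <- character(0)
  results <- list(seed = seed)

  # --- input -----------------------------------------------------------
  simTruth <- NULL
  if (!is.null(cfg$input$expression)) {
    inputs$expression <- cfg$input$expression
    ds <- readExpression(cfg$input$expression,
                         orientation = .cfgGet(cfg$input, "orientation",
                                               "samples_by_genes"),
                         naPolicy = .cfgGet(cfg$input, "na_policy", "fail"))
  } else if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    simCfg <- simulationConfig(
      nSamples = sc$n_samples,
      moduleSizes = unlist(.cfgGet(sc, "module_sizes", integer(0))),
      nBackground = .cfgGet(sc, "n_background", 0L),
      coherence = .cfgGet(sc, "coherence", 0.8),
      noiseSd = .cfgGet(sc, "noise_sd", 0.2),
      perturbation = .cfgGet(sc, "perturbation", "none"),
      rewireFraction = .cfgGet(sc, "rewire_fraction", 0),
      seed = seed)
    sim <- simulateExpression(simCfg)
    ds <- sim$dataset
    simTruth <- sim$labels
    writeExpression(ds, file.path(outDir, "expression.tsv"))
    .writeTsv(data.frame(gene = names(simTruth),
                         module = as.integer(simTruth)),
              file.path(outDir, "labels_truth.tsv"))
    outputs <- c(outputs, "expression.tsv", "labels_truth.tsv")
  } else stop("config must provide input$expression or simulate")
  results$dataset <- ds

  # --- filters ---------------------------------------------------------
  filterReports <- list()
  fl <- cfg$filter
  if (!is.null(fl$min_count)) {
    fc <- filterLowCounts(ds, threshold = fl$min_count,
                          mode = .cfgGet(fl, "count_mode", "at_least_one"))
    ds <- fc$dataset
    filterReports$low_count <- fc$report
  }
  if (!is.null(fl$var_quantile) && fl$var_quantile > 0) {
    fv <- filterLowVariation(ds,
                             dispersion = .cfgGet(fl, "dispersion", "mad"),
                             quantileCut = fl$var_quantile)
    ds <- fv$dataset
    filterReports$low_variation <- fv$report
  }
  if (length(filterReports) > 0) {
    .writeJson(lapply(filterReports, function(r)
      list(kind = r@filterKind, n_in = r@nIn, n_out = r@nOut,
           removed = as.list(r@removedIds), parameters = r@parameters)),
      file.path(outDir, "filter_report.json"))
    outputs <- c(outputs, "filter_report.json")
  }
  results$filtered <- ds

  # --- network ---------------------------------------------------------
  nw <- .cfgGet(cfg, "network", list())
  build <- buildNet(ds,
                    corMethod = .cfgGet(nw, "cor_method", "pearson"),
                    candidatePowers = seq(.cfgGet(nw, "power_min", 1),
                                          .cfgGet(nw, "power_max", 30)),
                    r2Cut = .cfgGet(nw, "r2_cut", 0.85),
                    nBins = .cfgGet(nw, "n_bins", 10),
                    power = nw$power)
  if (nrow(fitTable(build)) > 0) {
    .writeTsv(fitTable(build), file.path(outDir, "fit_table.tsv"))
    outputs <- c(outputs, "fit_table.tsv")
  }
  edgeMin <- .cfgGet(.cfgGet(cfg, "graph", list()), "edge_min", 0.5)
  writeNetwork(build, file.path(outDir, "network_edges.tsv"),
               "edge_list_tsv", edgeMin = edgeMin)
  outputs <- c(outputs, "network_edges.tsv")
  results$build <- build

  # --- modules ---------------------------------------------------------
  md <- .cfgGet(cfg, "modules", list())
  partition <- detectModules(ds, build,
                             minModuleSize = .cfgGet(md, "min_module_size", 20),
                             staticCutFraction = .cfgGet(md, "static_cut_fraction", 0.99),
                             kmeAssignThreshold = .cfgGet(md, "kme_threshold", 0.30),
                             mergeCut = .cfgGet(md, "merge_cut", 0.25))
  .writeModulesTsv(partition, file.path(outDir, "modules.tsv"))
  if (ncol(eigengenes(partition)) > 0) {
    .writeNumMatrixTsv(eigengenes(partition),
                       file.path(outDir, "eigengenes.tsv"), "sample")
    .writeNumMatrixTsv(kme(partition), file.path(outDir, "kme.tsv"), "gene")
    outputs <- c(outputs, "eigengenes.tsv", "kme.tsv")
  }
  sizes <- moduleSizes(partition)
  .writeJson(list(power = softPower(build),
                  cor_method = build@corMethod,
                  n_modules = sum(names(sizes) != "0"),
                  n_modules_premerge =
                    length(unique(moduleLabelsPremerge(partition)[
                      moduleLabelsPremerge(partition) > 0])),
                  module_sizes = as.list(sizes),
                  merge_history = mergeHistory(partition)),
             file.path(outDir, "module_summary.json"))
  outputs <- c(outputs, "modules.tsv", "module_summary.json")
  results$partition <- partition

  # --- hubs ------------------------------------------------------------
  hb <- .cfgGet(cfg, "hubs", list())
  hubMethod <- .cfgGet(hb, "method", "connectivity")
  hub <- switch(hubMethod,
                connectivity = hubsConnectivity(build,
                  .cfgGet(hb, "top_fraction", 0.05)),
                degree = hubsDegree(graphFrom(build, edgeMin),
                  .cfgGet(hb, "top_fraction", 0.05)),
                kleinberg = hubsKleinberg(build,
                  .cfgGet(hb, "score_floor", 0.90)),
                stop("unknown hub method: ", hubMethod))
  sc <- hubScores(hub)
  .writeTsv(data.frame(gene = names(sc), score = sprintf("%.17g", sc),
                       is_hub = names(sc) %in% hubGenes(hub),
                       stringsAsFactors = FALSE),
            file.path(outDir, "hubs.tsv"))
  outputs <- c(outputs, "hubs.tsv")
  results$hubs <- hub

  # --- sub-modules -----------------------------------------------------
  sm <- cfg$submodules
  if (!is.null(sm$module)) {
    sub <- detectSubmodules(build, partition, moduleId = sm$module,
                            silhouetteFloor = .cfgGet(sm, "silhouette_floor", 0.20))
    lbl <- subModuleLabels(sub)
    .writeTsv(data.frame(gene = names(lbl), submodule = as.integer(lbl)),
              file.path(outDir, "submodules.tsv"))
    outputs <- c(outputs, "submodules.tsv")
    results$submodules <- sub
  }

  # --- enrichment ------------------------------------------------------
  if (!is.null(cfg$enrich$gmt)) {
    inputs$gmt <- cfg$enrich$gmt
    enr <- oraEnrich(partition, readGMT(cfg$enrich$gmt),
                     minTerm = .cfgGet(cfg$enrich, "min_term", 5),
                     maxTerm = .cfgGet(cfg$enrich, "max_term", 1000),
                     alpha = .cfgGet(cfg$enrich, "alpha", 0.05))
    .writeTsv(enr, file.path(outDir, "enrichment.tsv"))
    outputs <- c(outputs, "enrichment.tsv")
    results$enrichment <- enr
  }

  # --- phenotype association ------------------------------------------
  if (!is.null(cfg$associate$phenotypes)) {
    inputs$phenotypes <- cfg$associate$phenotypes
    assoc <- associatePhenotypes(partition,
                                 readPhenotypes(cfg$associate$phenotypes),
                                 method = .cfgGet(cfg$associate, "method",
                                                  "pearson"),
                                 alpha = .cfgGet(cfg$associate, "alpha", 0.05))
    .writeTsv(assoc, file.path(outDir, "associations.tsv"))
    outputs <- c(outputs, "associations.tsv")
    results$associations <- assoc
  }

  # --- condition comparison -------------------------------------------
  cp <- cfg$compare
  if (!is.null(cp$test_expression)) {
    inputs$test_expression <- cp$test_expression
    dsT <- readExpression(cp$test_expression,
                          orientation = .cfgGet(cp, "orientation",
                                                "samples_by_genes"))
    buildT <- buildNet(dsT, corMethod = .cfgGet(nw, "cor_method", "pearson"),
                       r2Cut = .cfgGet(nw, "r2_cut", 0.85),
                       nBins = .cfgGet(nw, "n_bins", 10), power = nw$power)
    pair <- conditionPair(ds, build, dsT, buildT)
    rep <- compareConditions(pair, partition,
                             nPerm = .cfgGet(cp, "n_perm", 1000),
                             alpha = .cfgGet(cp, "alpha", 0.05),
                             alternative = .cfgGet(cp, "alternative",
                                                   "greater"),
                             seed = seed)
    .writePreservation(rep, outDir)
    diffM <- coexpDifference(pair, partition = partition)
    .writeNumMatrixTsv(diffM, file.path(outDir, "difference_matrix.tsv"),
                       "gene")
    outputs <- c(outputs, "preservation.tsv", "preservation.json",
                 "difference_matrix.tsv")
    results$preservation <- rep
    results$difference <- diffM
  }

  .writeManifest(outDir, "pipeline", cfg, seed, inputs, outputs)
  invisible(results)
}

.writePreservation <- function(rep, outDir) {
  df <- data.frame(module = rownames(rep@observed),
                   status = rep@status,
                   z_summary = sprintf("%.17g", rep@zSummary),
                   z_density = sprintf("%.17g", rep@zDensity),
                   z_connectivity = sprintf("%.17g", rep@zConnectivity),
                   stringsAsFactors = FALSE)
  for (s in rep@statNames) {
    df[[paste0("p.", s)]] <- sprintf("%.17g", rep@pValues[, s])
    df[[paste0("obs.", s)]] <- sprintf("%.17g", rep@observed[, s])
  }
  .writeTsv(df, file.path(outDir, "preservation.tsv"))
  .writeJson(list(n_perm = rep@nPerm, alpha = rep@alpha,
                  alternative = rep@alternative, seed = rep@seed,
                  status = as.list(rep@status),
                  z_summary = as.list(rep@zSummary),
                  p_values = as.data.frame(rep@pValues),
                  observed = as.data.frame(rep@observed)),
             file.path(outDir, "preservation.json"))
}
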