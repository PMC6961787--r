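#' @include synthdata.R preprocess.R diffexpr.R integration.R enrichment.R
NULL

.defaultThresholds <- list(de_alpha = 0.05, corr_threshold = 1.0,
                           interaction_p = 0.001, missing_threshold = 0.80,
                           low_mean_fraction = 0.10, enrich_alpha = 0.05)
.defaultMethods <- list(moderated_t = TRUE, correlation = "rank",
                        universe_policy = "measured")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or an equivalent nested list and returns the
#' canonical configuration, reporting every violated invariant with its
#' field name. Exactly one of an \code{inputs} block (paths to the four
#' tables) or a \code{synth} block (arguments for [synthConfig()]) must
#' be present. Thresholds and method switches are filled with their
#' defaults when omitted; the canonical echo re-validates to itself.
#'
#' @param config path to a YAML file, or a list.
#' @return the canonical configuration list (class
#'   \code{"omipairConfig"}).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  errs <- character()
  hasInputs <- !is.null(config$inputs)
  hasSynth <- !is.null(config$synth)
  if (hasInputs == hasSynth)
    errs <- c(errs, "exactly one of 'inputs' and 'synth' must be present")
  if (hasInputs) {
    need <- c("expression", "metabolites", "design", "annotation")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      errs <- c(errs, paste0("inputs is missing: ",
                             paste(miss, collapse = ", ")))
  }
  thr <- utils::modifyList(.defaultThresholds,
                           if (is.null(config$thresholds)) list()
                           else config$thresholds)
  unknown <- setdiff(names(thr), names(.defaultThresholds))
  if (length(unknown))
    errs <- c(errs, paste0("unknown threshold(s): ",
                           paste(unknown, collapse = ", ")))
  chk <- function(name, lo, hi, loOpen = FALSE) {
    v <- thr[[name]]
    bad <- !is.numeric(v) || length(v) != 1L || is.na(v) ||
      v < lo || v > hi || (loOpen && v == lo)
    if (bad) sprintf("%s must lie in %s%g, %g]", name,
                     if (loOpen) "(" else "[", lo, hi) else NULL
  }
  errs <- c(errs,
            chk("de_alpha", 0, 1, loOpen = TRUE),
            chk("corr_threshold", 0, 2),
            chk("interaction_p", 0, 1, loOpen = TRUE),
            chk("missing_threshold", 0, 1, loOpen = TRUE),
            chk("low_mean_fraction", 0, 1 - 1e-12),
            chk("enrich_alpha", 0, 1, loOpen = TRUE))
  met <- utils::modifyList(.defaultMethods,
                           if (is.null(config$methods)) list()
                           else config$methods)
  if (!isTRUE(met$moderated_t) && !isFALSE(met$moderated_t))
    errs <- c(errs, "moderated_t must be TRUE or FALSE")
  if (!met$correlation %in% c("rank", "linear"))
    errs <- c(errs, "correlation must be 'rank' or 'linear'")
  if (!met$universe_policy %in% c("measured", "annotated"))
    errs <- c(errs, "universe_policy must be 'measured' or 'annotated'")
  seed <- if (is.null(config$seed)) 1L else config$seed
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed))
    errs <- c(errs, "seed must be a single integer")
  if (hasSynth) {
    sc <- try(do.call(synthConfig, config$synth), silent = TRUE)
    if (inherits(sc, "try-error")) {
      errs <- c(errs, paste0("synth block invalid: ",
                             attr(sc, "condition")$message))
    } else {
      v <- validObject(sc, test = TRUE)
      if (!isTRUE(v)) errs <- c(errs, paste0("synth: ", v))
    }
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  out <- list(inputs = config$inputs, synth = config$synth,
              thresholds = thr, methods = met,
              seed = as.integer(seed), outdir = config$outdir)
  out[vapply(out, is.null, logical(1L))] <- NULL
  class(out) <- "omipairConfig"
  out
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full integration pipeline
#'
#' Executes the five stages in order — input loading (or synthesis),
#' differential expression, filtering and PCA, gene-metabolite pair
#' screening, metabolite pathway enrichment — and writes every stage
#' table, a machine-readable run manifest and a human-readable summary
#' into the output directory. Differential-expression testing runs on
#' the full gene matrix; the low-mean filter and the DEG restriction are
#' applied before pair screening only. On any stage failure, partial
#' outputs are retained next to a \code{FAILED} marker naming the stage.
#'
#' @param config a validated configuration ([validateConfig()]), a list,
#'   or a YAML path.
#' @param outdir output directory, overriding \code{config$outdir}.
#' @return invisibly, a list with the stage results and the summary
#'   counts.
#' @export
runPipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "omipairConfig")) config <- validateConfig(config)
  outdir <- if (!is.null(outdir)) outdir else config$outdir
  if (is.null(outdir)) stop("an output directory is required")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stage <- "setup"
  tryCatch(
    .runPipelineStages(config, outdir, function(s) stage <<- s),
    error = function(e) {
      writeLines(c(paste("stage:", stage), conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("pipeline failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
}

.runPipelineStages <- function(config, outdir, setStage) {
  thr <- config$thresholds
  met <- config$methods
  checksums <- NULL

  setStage("load")
  if (!is.null(config$synth)) {
    synthArgs <- config$synth
    if (is.null(synthArgs$seed)) synthArgs$seed <- config$seed
    ds <- generatePairedDataset(do.call(synthConfig, synthArgs))
    expression <- ds$expression
    metabolites <- ds$metabolites
    design <- ds$design
    metIdsAll <- featureIds(metabolites)
    annotation <- generatePathwayAnnotation(
      nPathways = max(5L, ceiling(length(metIdsAll) / 5)),
      metaboliteIds = metIdsAll,
      sizeRange = c(3L, min(8L, length(metIdsAll))),
      seed = config$seed)
    writeSyntheticTruth(ds$truth, outdir)
  } else {
    paths <- unlist(config$inputs)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    checksums <- as.list(tools::md5sum(paths))
    expression <- readFeatureTable(config$inputs$expression,
                                   scaleTag = "log2")
    metabolites <- readFeatureTable(config$inputs$metabolites)
    design <- readSampleDesign(config$inputs$design)
    annotation <- readPathwayAnnotation(config$inputs$annotation)
    if (!is.null(config$inputs$probe_map))
      expression <- collapseProbes(expression,
                                   readProbeMap(config$inputs$probe_map))
  }
  writeFeatureTable(expression, file.path(outdir, "expression_genes.tsv"))
  writeSampleDesign(design, file.path(outdir, "design.tsv"))

  setStage("diffexpr")
  de <- twoGroupTest(expression, design, moderated = met$moderated_t)
  degs <- selectDegs(de, alpha = thr$de_alpha)
  .writeTsv(de, file.path(outdir, "de_results.tsv"))
  writeLines(degs$up, file.path(outdir, "degs_up.txt"))
  writeLines(degs$down, file.path(outdir, "degs_down.txt"))
  degIds <- c(degs$up, degs$down)
  if (length(degIds) >= 2L) {
    vDeg <- OmicsMatrix(
      omicsValues(expression)[degIds, , drop = FALSE], scaleTag = "log2")
    writeLines(hierarchicalClusterOrder(vDeg, "features"),
               file.path(outdir, "deg_cluster_feature_order.txt"))
    writeLines(hierarchicalClusterOrder(vDeg, "samples"),
               file.path(outdir, "deg_cluster_sample_order.txt"))
  }

  setStage("preprocess")
  exprKept <- filterLowMeanGenes(expression,
                                 fraction = thr$low_mean_fraction)
  metKept <- filterMissingMetabolites(metabolites,
                                      threshold = thr$missing_threshold)
  screenIds <- intersect(featureIds(exprKept), degIds)
  exprScreen <- OmicsMatrix(
    omicsValues(exprKept)[screenIds, , drop = FALSE], scaleTag = "log2")
  for (side in list(list(m = exprScreen, name = "genes"),
                    list(m = metKept, name = "metabolites"))) {
    if (nrow(omicsValues(side$m)) >= 2L) {
      pc <- pcaScores(side$m, nComponents = 2L)
      sc <- data.frame(sample_id = rownames(pc$scores), pc$scores)
      .writeTsv(sc, file.path(outdir,
                              sprintf("pca_%s_scores.tsv", side$name)))
    }
  }
  writeFeatureTable(metKept, file.path(outdir, "metabolites_filtered.tsv"))

  setStage("integration")
  if (length(screenIds) == 0L)
    stop("no genes left to screen after DEG selection and filtering")
  pairs <- screenAllPairs(exprScreen, metKept, design,
                          corrThreshold = thr$corr_threshold,
                          pThreshold = thr$interaction_p,
                          method = met$correlation)
  .writeTsv(pairs, file.path(outdir, "pair_associations.tsv"))
  .writeTsv(pairPValueHistogram(pairs),
            file.path(outdir, "pair_pvalue_histogram.tsv"))
  .writeTsv(pairs[, c("gene_id", "metabolite_id", "diff_corr",
                      "p_interaction")],
            file.path(outdir, "pair_volcano.tsv"))

  setStage("enrichment")
  selMet <- unique(pairs$metabolite_id[pairs$selected])
  enr <- NULL
  if (length(selMet) > 0L) {
    enr <- tryCatch(
      enrichMetabolites(selMet, annotation,
                        measured = featureIds(metKept),
                        universePolicy = met$universe_policy,
                        alpha = thr$enrich_alpha),
      error = function(e) {
        message("enrichment skipped: ", conditionMessage(e))
        NULL
      })
  }
  if (!is.null(enr)) {
    .writeTsv(enr, file.path(outdir, "enrichment.tsv"))
    .writeTsv(data.frame(pathway_id = enr$pathway_id,
                         gene_ratio = enr$k / enr$n,
                         p_value = enr$p_value),
              file.path(outdir, "enrichment_dotplot.tsv"))
  }

  setStage("summary")
  counts <- list(
    genes_total = nrow(omicsValues(expression)),
    degs_up = length(degs$up),
    degs_down = length(degs$down),
    metabolites_retained = nrow(omicsValues(metKept)),
    genes_screened = length(screenIds),
    pairs_screened = nrow(pairs),
    pairs_selected = sum(pairs$selected),
    selected_metabolites = length(selMet),
    selected_genes = length(unique(pairs$gene_id[pairs$selected])),
    pathways_tested = if (is.null(enr)) 0L else nrow(enr),
    pathways_significant = if (is.null(enr)) 0L else sum(enr$significant))
  writeLines(sprintf("%s\t%d", names(counts), unlist(counts)),
             file.path(outdir, "summary.tsv"))
  manifest <- list(
    package = "omipair",
    version = as.character(utils::packageVersion("omipair")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_checksums = checksums,
    counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(de = de, degs = degs, pairs = pairs, enrichment = enr,
                 counts = counts))
}
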