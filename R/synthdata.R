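#' @include AllClasses.R
NULL

#' Create a validated synthetic-data configuration
#'
#' Defaults emulate a small two-group microarray/NMR study: 8 + 8
#' samples, log2-scale expression with per-gene baselines drawn from
#' Uniform(4, 12) and unit residual standard deviation, and metabolite
#' abundances generated from the phenotype-interaction model
#' \eqn{m = \beta_1 + \beta_2 g + \beta_3 p + \beta_4 (g \cdot p) + \epsilon}
#' with \eqn{p \in \{0, 1\}} and homoscedastic Gaussian
#' \eqn{\epsilon}. The default \code{beta2 = -1} makes a planted
#' \code{beta4 = 2} flip the sign of the gene-metabolite slope between
#' groups (slope \eqn{-1} in group 1, \eqn{+1} in group 2), the regime
#' the differential-correlation screen is designed to detect.
#'
#' @param nGroup1,nGroup2 samples per group.
#' @param nGenes,nMetabolites feature counts.
#' @param nDeGenes planted differentially expressed genes.
#' @param deEffect log2 mean shift of planted DE genes.
#' @param nInteractingPairs planted gene-metabolite pairs (at most one
#'   per metabolite).
#' @param beta4 planted interaction coefficient.
#' @param beta2 baseline gene-metabolite slope.
#' @param beta3 group offset on metabolite abundance.
#' @param noiseSd residual standard deviation of the metabolite model.
#' @param missingRate metabolite missing-at-random rate in [0, 0.8).
#' @param seed master seed; every stage of the generator derives its own
#'   sub-stream from it.
#' @return a [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(nGenes = 50, nMetabolites = 10, seed = 7)
#' @export
synthConfig <- function(nGroup1 = 8L, nGroup2 = 8L, nGenes = 200L,
                        nMetabolites = 50L, nDeGenes = 40L, deEffect = 1,
                        nInteractingPairs = 10L, beta4 = 2, beta2 = -1,
                        beta3 = 1, noiseSd = 0.5, missingRate = 0.1,
                        seed = 1L) {
  asCount <- function(x) {
    if (length(x) == 1L && is.finite(x) && x == round(x)) as.integer(x)
    else NA_integer_
  }
  new("SynthConfig",
      nGroup1 = asCount(nGroup1), nGroup2 = asCount(nGroup2),
      nGenes = asCount(nGenes), nMetabolites = asCount(nMetabolites),
      nDeGenes = asCount(nDeGenes), deEffect = as.numeric(deEffect),
      nInteractingPairs = asCount(nInteractingPairs),
      beta4 = as.numeric(beta4), beta2 = as.numeric(beta2),
      beta3 = as.numeric(beta3), noiseSd = as.numeric(noiseSd),
      missingRate = as.numeric(missingRate), seed = asCount(seed))
}

# Named sub-stream seeds derived from the master seed, so each stage of
# the generator is individually reproducible.
.stageSeeds <- function(seed, stages) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ss <- sample.int(2147483646L, length(stages))
  names(ss) <- stages
  ss
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a paired expression/metabolite dataset with planted effects
#'
#' Draws log2-scale gene expression (per-gene baseline Uniform(4, 12),
#' unit residual standard deviation), shifts planted DE genes by
#' \code{deEffect} in group 2 with alternating sign, and generates every
#' metabolite from the phenotype-interaction model with its assigned
#' driver gene: planted pairs use the configured \code{beta4}, all other
#' metabolites use \code{beta4 = 0}. Per-metabolite intercepts are drawn
#' Uniform(2, 8). Missing values are injected completely at random at
#' \code{missingRate}. Samples are matched one-to-one across assays by
#' sample id.
#'
#' @param config a [SynthConfig-class] (see [synthConfig()]).
#' @return a list with elements \code{expression} and \code{metabolites}
#'   ([OmicsMatrix-class]), \code{design} ([SampleDesign-class]) and
#'   \code{truth} ([SyntheticTruth-class]).
#' @examples
#' d <- generatePairedDataset(synthConfig(nGenes = 30, nMetabolites = 10,
#'   nDeGenes = 5, nInteractingPairs = 3, seed = 2))
#' dim(omicsValues(d$expression))
#' @export
generatePairedDataset <- function(config) {
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) stop("invalid SynthConfig: ", paste(v, collapse = "; "))
  nS <- config@nGroup1 + config@nGroup2
  geneIds <- sprintf("gene_%03d", seq_len(config@nGenes))
  # NMR-style feature names: unique compound stem + positional suffix
  metIds <- sprintf("met%03d_%d", seq_len(config@nMetabolites),
                    seq_len(config@nMetabolites))
  sampIds <- sprintf("S%02d", seq_len(nS))
  p <- rep(c(0, 1), c(config@nGroup1, config@nGroup2))
  design <- SampleDesign(sampIds,
                         factor(ifelse(p == 0, "group1", "group2"),
                                levels = c("group1", "group2")))

  ss <- .stageSeeds(config@seed,
                    c("expression", "de", "pairs", "metabolites", "missing"))

  expr <- .withSeed(ss[["expression"]], {
    baseline <- stats::runif(config@nGenes, 4, 12)
    baseline + matrix(stats::rnorm(config@nGenes * nS), config@nGenes, nS)
  })

  deTruth <- .withSeed(ss[["de"]], {
    idx <- if (config@nDeGenes > 0) sort(sample.int(config@nGenes, config@nDeGenes)) else integer()
    eff <- if (length(idx)) config@deEffect * rep_len(c(1, -1), length(idx)) else numeric()
    data.frame(gene_id = geneIds[idx], effect = eff,
               stringsAsFactors = FALSE)
  })
  if (nrow(deTruth)) {
    idx <- match(deTruth$gene_id, geneIds)
    expr[idx, p == 1] <- expr[idx, p == 1, drop = FALSE] + deTruth$effect
  }

  # driver gene per metabolite; planted pairs get distinct metabolites
  # (and distinct genes, when enough exist) so truth is unambiguous.
  # Planted pairs draw their genes from the planted DE genes when there
  # are enough of them: only differential genes enter pair screening
  # downstream, so an interaction planted on a non-DE gene would be
  # unrecoverable by construction.
  deIdx <- match(deTruth$gene_id, geneIds)
  plant <- .withSeed(ss[["pairs"]], {
    metIdx <- if (config@nInteractingPairs > 0)
      sort(sample.int(config@nMetabolites, config@nInteractingPairs)) else integer()
    pool <- if (length(deIdx) >= config@nInteractingPairs) deIdx
            else seq_len(config@nGenes)
    geneIdx <- if (config@nInteractingPairs <= length(pool))
      pool[sample.int(length(pool), config@nInteractingPairs)]
    else sample(pool, config@nInteractingPairs, replace = TRUE)
    driver <- sample.int(config@nGenes, config@nMetabolites, replace = TRUE)
    driver[metIdx] <- geneIdx
    list(metIdx = metIdx, driver = driver)
  })
  b4 <- numeric(config@nMetabolites)
  b4[plant$metIdx] <- config@beta4

  metab <- .withSeed(ss[["metabolites"]], {
    beta1 <- stats::runif(config@nMetabolites, 2, 8)
    eps <- matrix(stats::rnorm(config@nMetabolites * nS, 0, config@noiseSd),
                  config@nMetabolites, nS)
    g <- expr[plant$driver, , drop = FALSE]
    beta1 + config@beta2 * g + config@beta3 * rep(p, each = config@nMetabolites) +
      b4 * g * rep(p, each = config@nMetabolites) + eps
  })

  expression <- OmicsMatrix(expr, featureIds = geneIds, sampleIds = sampIds,
                            scaleTag = "log2")
  metabolites <- OmicsMatrix(metab, featureIds = metIds,
                             sampleIds = sampIds, scaleTag = "raw")
  if (config@missingRate > 0)
    metabolites <- injectMissingness(metabolites, config@missingRate,
                                     seed = ss[["missing"]])

  truth <- new("SyntheticTruth",
               deGenes = deTruth,
               interactingPairs = data.frame(
                 gene_id = geneIds[plant$driver[plant$metIdx]],
                 metabolite_id = metIds[plant$metIdx],
                 beta4 = rep(config@beta4, length(plant$metIdx)),
                 stringsAsFactors = FALSE),
               groupLabels = stats::setNames(
                 ifelse(p == 0, "group1", "group2"), sampIds))
  list(expression = expression, metabolites = metabolites,
       design = design, truth = truth)
}

#' Set matrix cells missing completely at random
#'
#' Each cell is independently set to \code{NA} with probability
#' \code{rate}; identifiers and all other cells are untouched. A fixed
#' seed yields an identical missingness mask.
#'
#' @param x an [OmicsMatrix-class].
#' @param rate missingness probability in [0, 1).
#' @param seed integer seed for the mask.
#' @return an [OmicsMatrix-class] with injected missing values.
#' @export
injectMissingness <- function(x, rate, seed = 1L) {
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)")
  v <- omicsValues(x)
  if (rate > 0) {
    mask <- .withSeed(seed,
      matrix(stats::runif(length(v)) < rate, nrow(v), ncol(v)))
    v[mask] <- NA_real_
  }
  OmicsMatrix(v, scaleTag = scaleTag(x))
}

#' Generate a synthetic pathway annotation
#'
#' Builds a pathway-to-metabolite membership map for enrichment testing:
#' each pathway draws a uniformly sampled member-set size within
#' \code{sizeRange} and samples that many distinct metabolite ids.
#'
#' @param nPathways number of pathways.
#' @param metaboliteIds pool of metabolite ids to draw members from.
#' @param sizeRange integer vector \code{c(min, max)} of members per
#'   pathway; \code{max} must not exceed the pool size.
#' @param seed integer seed.
#' @return a named list of character vectors (class
#'   \code{"PathwayAnnotation"}), pathway id to member metabolite ids.
#' @export
generatePathwayAnnotation <- function(nPathways, metaboliteIds,
                                      sizeRange = c(3L, 8L), seed = 1L) {
  if (length(metaboliteIds) == 0L) stop("metaboliteIds must be non-empty")
  if (length(sizeRange) != 2L || sizeRange[1L] > sizeRange[2L])
    stop("sizeRange must be c(min, max) with min <= max")
  if (sizeRange[2L] > length(metaboliteIds))
    stop("max pathway size exceeds the number of metabolites")
  ann <- .withSeed(seed, {
    sizes <- sample(seq(sizeRange[1L], sizeRange[2L]), nPathways,
                    replace = TRUE)
    lapply(sizes, function(k) sort(sample(metaboliteIds, k)))
  })
  names(ann) <- sprintf("pathway_%02d", seq_len(nPathways))
  class(ann) <- "PathwayAnnotation"
  ann
}

#' Write the planted truth of a synthetic dataset as TSV sidecars
#'
#' @param truth a [SyntheticTruth-class].
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths, invisibly.
#' @export
writeSyntheticTruth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "truth_de_genes.tsv")
  p2 <- file.path(dir, "truth_interacting_pairs.tsv")
  utils::write.table(truth@deGenes, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth@interactingPairs, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d planted DE genes, %d planted pairs, %d samples\n",
              nrow(object@deGenes), nrow(object@interactingPairs),
              length(object@groupLabels)))
  invisible(NULL)
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0(
    "SynthConfig: %d+%d samples, %d genes (%d DE, effect %g), ",
    "%d metabolites (%d planted pairs, beta4 %g)\n",
    "  beta2 %g, beta3 %g, noiseSd %g, missingRate %g, seed %d\n"),
    object@nGroup1, object@nGroup2, object@nGenes, object@nDeGenes,
    object@deEffect, object@nMetabolites, object@nInteractingPairs,
    object@beta4, object@beta2, object@beta3, object@noiseSd,
    object@missingRate, object@seed))
  invisible(NULL)
})
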