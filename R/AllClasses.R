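#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

#' OmicsMatrix: a features x samples measurement table
#'
#' The common carrier for both gene-expression and metabolite-abundance
#' data. Extends \linkS4class{SummarizedExperiment} with a single assay
#' named \code{"values"} and a scale tag recording whether the values are
#' raw intensities or log2-scale measurements. Missing values are allowed
#' (metabolite tables routinely contain them); operations that cannot
#' handle missingness check for it explicitly.
#'
#' @slot scaleTag character, either \code{"raw"} or \code{"log2"}.
#'
#' @seealso [OmicsMatrix()] for the constructor, [readFeatureTable()] for
#'   the TSV reader.
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  representation(scaleTag = "character"),
  prototype(scaleTag = "raw")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@scaleTag) != 1L || !object@scaleTag %in% c("raw", "log2"))
    msg <- c(msg, "scaleTag must be one of 'raw', 'log2'")
  if (length(SummarizedExperiment::assays(object)) != 1L)
    msg <- c(msg, "OmicsMatrix carries exactly one assay")
  fid <- rownames(object)
  sid <- colnames(object)
  if (is.null(fid) || anyDuplicated(fid))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(sid) || anyDuplicated(sid))
    msg <- c(msg, "sample ids must be present and unique")
  v <- SummarizedExperiment::assay(object, 1L)
  if (!is.numeric(v))
    msg <- c(msg, "values must be numeric")
  if (identical(object@scaleTag, "log2") && any(is.infinite(v) & v < 0, na.rm = TRUE))
    msg <- c(msg, "log2-tagged matrix contains negative infinities")
  if (length(msg)) msg else TRUE
})

#' SampleDesign: sample-to-group assignment
#'
#' Assigns each sample to one of two phenotype groups and optionally
#' carries a pairing key that links a sample across assays (for studies
#' where the transcriptome and metabolome were measured on distinct but
#' paired specimens).
#'
#' @slot sampleId character vector of unique sample identifiers.
#' @slot group factor with exactly two levels; level order defines
#'   group 1 and group 2 throughout the package.
#' @slot pairingId character vector linking samples across assays;
#'   defaults to the sample id itself (matched samples).
#'
#' @seealso [SampleDesign()] for the constructor.
#' @exportClass SampleDesign
setClass("SampleDesign",
  representation(sampleId = "character", group = "factor",
                 pairingId = "character")
)

setValidity("SampleDesign", function(object) {
  msg <- character()
  n <- length(object@sampleId)
  if (anyDuplicated(object@sampleId))
    msg <- c(msg, "sample ids must be unique")
  if (length(object@group) != n || length(object@pairingId) != n)
    msg <- c(msg, "sampleId, group and pairingId must have equal length")
  if (nlevels(object@group) != 2L)
    msg <- c(msg, "exactly two group levels are required")
  if (n > 0 && any(table(object@group) == 0L))
    msg <- c(msg, "both groups must be non-empty")
  if (length(msg)) msg else TRUE
})

#' SynthConfig: parameters of the synthetic paired-omics generator
#'
#' Holds the generative conditions for [generatePairedDataset()]: group
#' sizes, matrix dimensions, the number and size of planted effects, the
#' coefficients of the metabolite model
#' \eqn{m = \beta_1 + \beta_2 g + \beta_3 p + \beta_4 (g \cdot p) + \epsilon},
#' the residual standard deviation, the missing-at-random rate, and the
#' master seed.
#'
#' @slot nGroup1,nGroup2 samples per phenotype group.
#' @slot nGenes,nMetabolites matrix dimensions (features).
#' @slot nDeGenes planted differentially expressed genes.
#' @slot deEffect mean shift of planted DE genes on the log2 scale
#'   (applied to group 2, with alternating sign across planted genes).
#' @slot nInteractingPairs planted gene-metabolite pairs with a nonzero
#'   interaction coefficient.
#' @slot beta4 planted interaction coefficient (difference in
#'   gene-metabolite slope between groups, abundance units per
#'   log2-expression unit).
#' @slot beta2 baseline gene-metabolite slope shared by both groups.
#' @slot beta3 additive group offset on metabolite abundance.
#' @slot noiseSd residual standard deviation of the metabolite model.
#' @slot missingRate fraction of metabolite cells set missing at random;
#'   must be below 0.8 so no metabolite is expected to be auto-dropped by
#'   the downstream missingness filter.
#' @slot seed integer master seed; fixed seed implies byte-identical
#'   output.
#'
#' @seealso [synthConfig()] for the validated constructor with defaults.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(nGroup1 = "integer", nGroup2 = "integer",
                 nGenes = "integer", nMetabolites = "integer",
                 nDeGenes = "integer", deEffect = "numeric",
                 nInteractingPairs = "integer", beta4 = "numeric",
                 beta2 = "numeric", beta3 = "numeric",
                 noiseSd = "numeric", missingRate = "numeric",
                 seed = "integer")
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  chkCount <- function(slot, positive = TRUE) {
    v <- slot(object, slot)
    if (length(v) != 1L || is.na(v)) return(sprintf("%s must be a single value", slot))
    if (positive && v < 1L) return(sprintf("%s must be a positive count", slot))
    if (!positive && v < 0L) return(sprintf("%s must be a non-negative count", slot))
    NULL
  }
  for (s in c("nGroup1", "nGroup2", "nGenes", "nMetabolites"))
    msg <- c(msg, chkCount(s))
  for (s in c("nDeGenes", "nInteractingPairs"))
    msg <- c(msg, chkCount(s, positive = FALSE))
  chkScalar <- function(slot) {
    v <- slot(object, slot)
    if (length(v) != 1L || is.na(v)) sprintf("%s must be a single finite value", slot) else NULL
  }
  for (s in c("deEffect", "beta4", "beta2", "beta3", "noiseSd", "missingRate"))
    msg <- c(msg, chkScalar(s))
  if (!length(msg)) {
    if (object@nDeGenes > object@nGenes)
      msg <- c(msg, "nDeGenes must not exceed nGenes")
    if (object@nInteractingPairs > object@nMetabolites)
      msg <- c(msg, paste("nInteractingPairs must not exceed nMetabolites",
                          "(at most one planted pair per metabolite)"))
    if (object@nInteractingPairs > object@nGenes * object@nMetabolites)
      msg <- c(msg, "nInteractingPairs must not exceed nGenes * nMetabolites")
    if (object@noiseSd < 0)
      msg <- c(msg, "noiseSd must be non-negative")
    if (object@missingRate < 0 || object@missingRate >= 0.8)
      msg <- c(msg, "missingRate must lie in [0, 0.8)")
    if (length(object@seed) != 1L || is.na(object@seed))
      msg <- c(msg, "seed must be a single integer")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: the planted effects of a synthetic dataset
#'
#' Records which genes were planted as differentially expressed (with
#' their signed log2 effect), which gene-metabolite pairs carry a nonzero
#' interaction coefficient, and the group label of every sample — the
#' ground truth against which recovery is measured.
#'
#' @slot deGenes data.frame with columns \code{gene_id}, \code{effect}.
#' @slot interactingPairs data.frame with columns \code{gene_id},
#'   \code{metabolite_id}, \code{beta4}.
#' @slot groupLabels named character vector, sample id to group label.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(deGenes = "data.frame", interactingPairs = "data.frame",
                 groupLabels = "character")
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (!all(c("gene_id", "effect") %in% names(object@deGenes)))
    msg <- c(msg, "deGenes needs columns gene_id, effect")
  if (!all(c("gene_id", "metabolite_id", "beta4") %in% names(object@interactingPairs)))
    msg <- c(msg, "interactingPairs needs columns gene_id, metabolite_id, beta4")
  if (nrow(object@interactingPairs) && any(object@interactingPairs$beta4 == 0))
    msg <- c(msg, "planted beta4 values must be nonzero")
  if (is.null(names(object@groupLabels)))
    msg <- c(msg, "groupLabels must be named by sample id")
  if (length(msg)) msg else TRUE
})

#' PairModelFit: one gene-metabolite pair's interaction-model fit
#'
#' The ordinary-least-squares fit of the phenotype-interaction model
#' \eqn{m = \beta_1 + \beta_2 g + \beta_3 p + \beta_4 (g \cdot p) + \epsilon}
#' for a single pair, where \eqn{p \in \{0, 1\}} encodes the phenotype
#' group. \code{beta4} is the between-group difference in the
#' gene-metabolite slope; its two-sided t-test P-value drives the
#' interaction screen.
#'
#' @slot beta1,beta2,beta3,beta4 fitted coefficients.
#' @slot seBeta4,tBeta4 standard error and t-statistic of \code{beta4}.
#' @slot pInteraction two-sided P-value of the interaction term
#'   (\code{NA} for degenerate fits).
#' @slot nUsed samples entering the fit after missing-value removal.
#' @slot residualDf residual degrees of freedom (\code{nUsed - 4}).
#' @slot flag \code{"ok"} or the degeneracy reason
#'   (\code{"insufficient_samples"}, \code{"rank_deficient"},
#'   \code{"zero_residual_variance"}).
#'
#' @seealso [fitPairInteractionModel()]
#' @exportClass PairModelFit
setClass("PairModelFit",
  representation(beta1 = "numeric", beta2 = "numeric", beta3 = "numeric",
                 beta4 = "numeric", seBeta4 = "numeric", tBeta4 = "numeric",
                 pInteraction = "numeric", nUsed = "integer",
                 residualDf = "integer", flag = "character")
)

setValidity("PairModelFit", function(object) {
  msg <- character()
  if (!is.na(object@pInteraction) &&
      (object@pInteraction < 0 || object@pInteraction > 1))
    msg <- c(msg, "pInteraction must lie in [0, 1]")
  if (!object@flag %in% c("ok", "insufficient_samples", "rank_deficient",
                          "zero_residual_variance"))
    msg <- c(msg, "unknown flag")
  if (length(msg)) msg else TRUE
})
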