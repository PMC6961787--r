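#' @include omicsmatrix.R
NULL

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to the common reference distribution,
#' defined as the across-column mean of sorted values; ties within a
#' column receive the mean of the reference values at their tied ranks.
#' Idempotent: a second application changes nothing.
#'
#' @param x an [OmicsMatrix-class] without missing values.
#' @return an [OmicsMatrix-class] on the same scale.
#' @export
quantileNormalize <- function(x) {
  v <- omicsValues(x)
  if (anyNA(v))
    stop("quantileNormalize requires a complete matrix; ",
         "filter or impute the metabolite table instead")
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  OmicsMatrix(out, scaleTag = scaleTag(x))
}

#' Log2-transform a raw-scale matrix
#'
#' Applies \code{log2(v + offset)} cell-wise and re-tags the matrix as
#' log2 scale.
#'
#' @param x a raw-scale [OmicsMatrix-class].
#' @param offset pseudo-count added before the logarithm (default 1).
#' @return a log2-tagged [OmicsMatrix-class].
#' @export
log2Transform <- function(x, offset = 1) {
  if (scaleTag(x) != "raw")
    stop("matrix is already log2-tagged")
  v <- omicsValues(x)
  if (any(v + offset <= 0, na.rm = TRUE))
    stop("values + offset must be positive for log2 transformation")
  OmicsMatrix(log2(v + offset), scaleTag = "log2")
}

#' Read a probe-to-symbol map
#'
#' Two-column TSV with header columns \code{probe_id} and \code{symbol}.
#'
#' @param path path to the TSV.
#' @return named character vector, probe id to symbol.
#' @export
readProbeMap <- function(path) {
  if (!file.exists(path)) stop("probe map not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "symbol") %in% names(df)))
    stop("probe map must have columns probe_id, symbol")
  if (any(!nzchar(df$symbol) | is.na(df$symbol)))
    stop("probe map contains empty symbols")
  stats::setNames(df$symbol, df$probe_id)
}

#' Collapse probe-level rows to one row per mapped symbol
#'
#' Replaces each symbol's probes by their arithmetic mean, computed on
#' the matrix's current scale. Probes absent from the map are dropped
#' with a message stating the count. Output rows are ordered
#' lexicographically by symbol.
#'
#' @param x an [OmicsMatrix-class] whose feature ids are probe ids.
#' @param map named character vector (probe id -> symbol), e.g. from
#'   [readProbeMap()].
#' @return an [OmicsMatrix-class] with one row per symbol.
#' @export
collapseProbes <- function(x, map) {
  v <- omicsValues(x)
  hit <- rownames(v) %in% names(map)
  if (!any(hit))
    stop("no probe of the matrix is present in the map")
  dropped <- sum(!hit)
  if (dropped > 0)
    message(dropped, " probe(s) absent from the map were dropped")
  v <- v[hit, , drop = FALSE]
  sym <- unname(map[rownames(v)])
  agg <- rowsum(v, group = sym, reorder = TRUE)
  counts <- as.vector(table(sym)[rownames(agg)])
  out <- agg / counts
  OmicsMatrix(out, scaleTag = scaleTag(x))
}

#' Drop the lowest-mean fraction of genes
#'
#' Computes each gene's mean across samples and removes the
#' \code{floor(fraction * n)} genes with the lowest means; ties are
#' broken by lexicographic feature id, the lexicographically larger id
#' being dropped first. Survivors keep their original relative order.
#'
#' @param x an [OmicsMatrix-class] without missing values.
#' @param fraction fraction of genes to drop, in [0, 1); default 0.10.
#' @return the filtered [OmicsMatrix-class].
#' @export
filterLowMeanGenes <- function(x, fraction = 0.10) {
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 ||
      fraction >= 1)
    stop("fraction must lie in [0, 1)")
  v <- omicsValues(x)
  if (anyNA(v)) stop("filterLowMeanGenes requires a complete matrix")
  nDrop <- floor(fraction * nrow(v))
  if (nDrop == 0L) return(x)
  m <- rowMeans(v)
  # ascending mean; ties: lexicographically larger id first
  ord <- order(m, -rank(rownames(v)))
  drop <- rownames(v)[ord[seq_len(nDrop)]]
  keep <- !(rownames(v) %in% drop)
  OmicsMatrix(v[keep, , drop = FALSE], scaleTag = scaleTag(x))
}

#' Drop metabolites with excessive missingness
#'
#' Removes metabolite rows whose fraction of missing cells is strictly
#' greater than \code{threshold}; a row at exactly the threshold is
#' retained.
#'
#' @param x an [OmicsMatrix-class].
#' @param threshold missingness threshold in (0, 1]; default 0.80.
#' @return the filtered [OmicsMatrix-class].
#' @export
filterMissingMetabolites <- function(x, threshold = 0.80) {
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 ||
      threshold > 1)
    stop("threshold must lie in (0, 1]")
  v <- omicsValues(x)
  frac <- rowMeans(is.na(v))
  OmicsMatrix(v[frac <= threshold, , drop = FALSE],
              scaleTag = scaleTag(x))
}

#' Principal-component scores of the samples
#'
#' Centers each feature across samples (no unit scaling) and computes
#' the sample scores of the leading principal components. Components are
#' ordered by decreasing explained variance; each component's sign is
#' fixed by making its largest-magnitude loading positive. Missing cells
#' (metabolite matrices) are imputed by the feature's observed mean for
#' the decomposition only.
#'
#' @param x an [OmicsMatrix-class].
#' @param nComponents number of components to return; must not exceed
#'   \code{min(n_features, n_samples - 1)}.
#' @return a list with \code{scores} (samples x components),
#'   \code{explainedVariance} (fractions, non-increasing, summing to at
#'   most 1) and \code{loadings} (features x components).
#' @export
pcaScores <- function(x, nComponents = 2L) {
  v <- omicsValues(x)
  if (anyNA(v)) {
    rm <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- rm[idx[, 1L]]
  }
  maxComp <- min(nrow(v), ncol(v) - 1L)
  if (nComponents > maxComp)
    stop("nComponents exceeds min(n_features, n_samples - 1) = ", maxComp)
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  k <- seq_len(nComponents)
  rot <- pc$rotation[, k, drop = FALSE]
  sco <- pc$x[, k, drop = FALSE]
  for (j in k) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sco, explainedVariance = ev[k], loadings = rot)
}
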