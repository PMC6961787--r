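#' @include omicsmatrix.R sampledesign.R
NULL

#' Two-group differential-expression test
#'
#' Per-feature two-sample comparison between the design's two groups.
#' With \code{moderated = FALSE}, a pooled-variance two-sample t-test
#' with \code{n1 + n2 - 2} degrees of freedom and a two-sided P-value.
#' With \code{moderated = TRUE} (default), the empirical-Bayes moderated
#' t-statistic: each feature's variance is shrunk toward a common prior
#' via \code{limma}'s scaled-F moment estimator and tested on the
#' augmented degrees of freedom.
#'
#' A zero-variance feature with identical group means yields
#' \code{t = 0, p = 1} (not an error). \code{log2_fold_change} is
#' \code{mean_group2 - mean_group1}; \code{direction} gives the feature's
#' regulation in group 1 relative to group 2, so \code{"up"} corresponds
#' to a negative fold change.
#'
#' @param x a log2-scale [OmicsMatrix-class] without missing values.
#' @param design a [SampleDesign-class]; both groups need at least two
#'   samples.
#' @param moderated use the empirical-Bayes moderated statistic.
#' @param adjust apply Benjamini-Hochberg adjustment and report it in an
#'   extra \code{p_adjusted} column (selection still uses raw P unless
#'   you pass adjusted values to [selectDegs()] yourself).
#' @return a data.frame with columns \code{feature_id},
#'   \code{mean_group1}, \code{mean_group2}, \code{log2_fold_change},
#'   \code{t_statistic}, \code{p_value}, \code{direction} (and
#'   \code{p_adjusted} if requested).
#' @export
twoGroupTest <- function(x, design, moderated = TRUE, adjust = FALSE) {
  v <- omicsValues(x)
  if (anyNA(v)) stop("twoGroupTest requires a complete matrix")
  gi <- .groupIndex(design)
  ids <- lapply(gi, intersect, x = colnames(v))
  n1 <- length(ids[[1L]]); n2 <- length(ids[[2L]])
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least two samples present in the matrix")
  v1 <- v[, ids[[1L]], drop = FALSE]
  v2 <- v[, ids[[2L]], drop = FALSE]
  m1 <- rowMeans(v1); m2 <- rowMeans(v2)
  lfc <- m2 - m1
  if (moderated) {
    grp <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))
    dm <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(cbind(v1, v2), dm))
    tstat <- fit$t[, 2L]
    pval <- fit$p.value[, 2L]
    # a feature with zero pooled variance and equal means carries no
    # evidence whatever the prior: report t = 0, P = 1
    df <- n1 + n2 - 2L
    s2 <- ((n1 - 1L) * .rowVars(v1) + (n2 - 1L) * .rowVars(v2)) / df
    zero <- (s2 == 0 | !is.finite(tstat)) &
      abs(lfc) < .Machine$double.eps^0.5
    tstat[zero] <- 0; pval[zero] <- 1
  } else {
    df <- n1 + n2 - 2L
    s2 <- ((n1 - 1L) * .rowVars(v1) + (n2 - 1L) * .rowVars(v2)) / df
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    tstat <- lfc / se
    tstat[se == 0 & lfc == 0] <- 0
    pval <- 2 * stats::pt(-abs(tstat), df)
  }
  res <- data.frame(
    feature_id = rownames(v),
    mean_group1 = m1, mean_group2 = m2,
    log2_fold_change = lfc,
    t_statistic = unname(tstat), p_value = unname(pval),
    direction = ifelse(lfc < 0, "up", ifelse(lfc > 0, "down", "none")),
    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust)
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res
}

.rowVars <- function(m) {
  n <- ncol(m)
  (rowSums(m^2) - n * rowMeans(m)^2) / (n - 1L)
}

#' Select differentially expressed genes
#'
#' Splits features with \code{p_value < alpha} (strict) by the sign of
#' the log2 fold change. A significant feature with exactly zero fold
#' change belongs to neither list and is reported via a message.
#'
#' @param results data.frame from [twoGroupTest()].
#' @param alpha raw P-value threshold (default 0.05, strict).
#' @return a list with character vectors \code{up} and \code{down}
#'   (feature ids, following the \code{direction} convention of
#'   [twoGroupTest()]: "up" means higher in group 1).
#' @export
selectDegs <- function(results, alpha = 0.05) {
  if (nrow(results) == 0L) stop("empty result table")
  sig <- results$p_value < alpha
  zero <- sig & results$direction == "none"
  if (any(zero))
    message(sum(zero), " significant feature(s) with zero fold change ",
            "assigned to neither direction")
  list(up = results$feature_id[sig & results$direction == "up"],
       down = results$feature_id[sig & results$direction == "down"])
}

#' Dendrogram leaf order from Euclidean hierarchical clustering
#'
#' Agglomerative clustering with Euclidean distance and complete
#' linkage, for heat-map row/column ordering. A single item returns the
#' identity order.
#'
#' @param x an [OmicsMatrix-class] without missing values.
#' @param axis cluster the \code{"features"} (rows) or \code{"samples"}
#'   (columns).
#' @return character vector of ids in dendrogram leaf order.
#' @export
hierarchicalClusterOrder <- function(x, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  v <- omicsValues(x)
  if (anyNA(v)) stop("clustering requires a complete matrix")
  m <- if (axis == "features") v else t(v)
  if (nrow(m) < 2L) return(rownames(m))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  rownames(m)[hc$order]
}
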