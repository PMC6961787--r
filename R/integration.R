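#' @include omicsmatrix.R sampledesign.R
NULL

#' Fit the phenotype-interaction model for one gene-metabolite pair
#'
#' Ordinary least squares on the design columns
#' \code{(1, g, p, g*p)} for the model
#' \eqn{m = \beta_1 + \beta_2 g + \beta_3 p + \beta_4 (g \cdot p) + \epsilon},
#' where \eqn{p \in \{0, 1\}} encodes the two phenotype groups.
#' \code{beta4} is the between-group slope difference; its two-sided
#' t-test on \code{nUsed - 4} residual degrees of freedom gives the
#' interaction P-value. Samples with a missing metabolite value are
#' excluded pairwise.
#'
#' Degenerate situations (too few complete samples per group, a
#' rank-deficient design such as constant expression within a group, or
#' zero residual variance from an exact fit) are not errors: the fit is
#' returned with \code{pInteraction = NA} and an explanatory flag, and
#' such pairs are never selected by the screen.
#'
#' @param g numeric vector of per-sample expression values.
#' @param m numeric vector of per-sample metabolite abundances, aligned
#'   with \code{g}; may contain \code{NA}.
#' @param p per-sample phenotype: a 0/1 numeric vector or a two-level
#'   factor (first level = group 1 = 0).
#' @param minPerGroup minimum complete samples required per group
#'   (default 5).
#' @return a [PairModelFit-class].
#' @examples
#' set.seed(1)
#' g <- rnorm(16); p <- rep(0:1, each = 8)
#' m <- 1 - g + p + 2 * g * p + rnorm(16, 0, 0.5)
#' fitPairInteractionModel(g, m, p)
#' @export
fitPairInteractionModel <- function(g, m, p, minPerGroup = 5L) {
  if (is.factor(p)) p <- as.numeric(p) - 1
  if (length(g) != length(m) || length(g) != length(p))
    stop("g, m and p must have equal length")
  if (!all(p %in% c(0, 1))) stop("p must be binary (0/1 or two-level factor)")
  keep <- !is.na(m) & !is.na(g)
  g <- g[keep]; m <- m[keep]; p <- p[keep]
  n1 <- sum(p == 0); n2 <- sum(p == 1)
  nUsed <- n1 + n2
  empty <- function(flag) new("PairModelFit",
    beta1 = NA_real_, beta2 = NA_real_, beta3 = NA_real_,
    beta4 = NA_real_, seBeta4 = NA_real_, tBeta4 = NA_real_,
    pInteraction = NA_real_, nUsed = as.integer(nUsed),
    residualDf = as.integer(max(nUsed - 4L, 0L)), flag = flag)
  if (n1 < minPerGroup || n2 < minPerGroup || nUsed < 5L)
    return(empty("insufficient_samples"))
  X <- cbind(1, g, p, g * p)
  qrX <- qr(X)
  if (qrX$rank < 4L) return(empty("rank_deficient"))
  beta <- unname(qr.coef(qrX, m))
  res <- m - X %*% beta
  rss <- sum(res^2)
  df <- nUsed - 4L
  tss <- sum((m - mean(m))^2)
  XtXinv <- chol2inv(qr.R(qrX))
  if (rss <= 1e-10 * max(tss, .Machine$double.eps)) {
    return(new("PairModelFit",
      beta1 = beta[1L], beta2 = beta[2L], beta3 = beta[3L],
      beta4 = beta[4L], seBeta4 = 0,
      tBeta4 = if (abs(beta[4L]) < sqrt(.Machine$double.eps)) 0 else
        sign(beta[4L]) * Inf,
      pInteraction = NA_real_, nUsed = as.integer(nUsed),
      residualDf = as.integer(df), flag = "zero_residual_variance"))
  }
  s2 <- rss / df
  se4 <- sqrt(s2 * XtXinv[4L, 4L])
  t4 <- beta[4L] / se4
  new("PairModelFit",
      beta1 = unname(beta[1L]), beta2 = unname(beta[2L]),
      beta3 = unname(beta[3L]), beta4 = unname(beta[4L]),
      seBeta4 = se4, tBeta4 = unname(t4),
      pInteraction = 2 * stats::pt(-abs(unname(t4)), df),
      nUsed = as.integer(nUsed), residualDf = as.integer(df), flag = "ok")
}

setMethod("show", "PairModelFit", function(object) {
  cat(sprintf(
    "PairModelFit [%s]: beta4 = %.4g (se %.4g, t %.3g), p = %.3g, n = %d\n",
    object@flag, object@beta4, object@seBeta4, object@tBeta4,
    object@pInteraction, object@nUsed))
  invisible(NULL)
})

#' Within-group gene-metabolite correlation
#'
#' Spearman's rank correlation by default (with no ties equal to
#' \eqn{1 - 6\sum d^2 / (n(n^2-1))}); Pearson's linear correlation via
#' \code{method = "linear"}. Pairs with a missing value are dropped; a
#' zero-variance input yields \code{NA}.
#'
#' @param g,m numeric vectors, aligned by sample.
#' @param method \code{"rank"} (Spearman, default) or \code{"linear"}
#'   (Pearson).
#' @return correlation in [-1, 1], or \code{NA} for zero variance.
#' @examples
#' groupCorrelation(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))  # Sum d^2 = 8
#' @export
groupCorrelation <- function(g, m, method = c("rank", "linear")) {
  method <- match.arg(method)
  keep <- !is.na(g) & !is.na(m)
  g <- g[keep]; m <- m[keep]
  if (length(g) < 3L)
    stop("at least 3 complete pairs are required")
  if (stats::sd(g) == 0 || stats::sd(m) == 0) return(NA_real_)
  stats::cor(g, m, method = if (method == "rank") "spearman" else "pearson")
}

#' Signed differential correlation
#'
#' The signed difference \code{rGroup2 - rGroup1} between a pair's
#' within-group correlations; pair selection applies the absolute value.
#'
#' @param rGroup1,rGroup2 within-group correlations.
#' @return signed difference in [-2, 2], \code{NA} if either input is
#'   missing.
#' @examples
#' diffCorrelation(0.905, -0.857)  # -1.762
#' @export
diffCorrelation <- function(rGroup1, rGroup2) {
  ifelse(is.na(rGroup1) | is.na(rGroup2), NA_real_, rGroup2 - rGroup1)
}

# Align expression and metabolite samples through the design.
# Matched sample ids take priority; otherwise the explicit pairing key is
# used; sorted-id alignment of equal-sized groups is opt-in and loud.
.alignAssays <- function(expression, metabolites, design,
                         allowSorted = FALSE) {
  ve <- omicsValues(expression)
  vm <- omicsValues(metabolites)
  grp <- groupLabels(design)
  se <- intersect(colnames(ve), names(grp))
  sm <- intersect(colnames(vm), names(grp))
  if (length(se) == 0L || length(sm) == 0L)
    stop("no samples shared between the matrices and the design")
  done <- function(eIds, mIds) {
    p <- as.numeric(grp[eIds]) - 1
    list(g = ve[, eIds, drop = FALSE], m = vm[, mIds, drop = FALSE],
         p = p, sampleIds = eIds)
  }
  if (setequal(se, sm)) {
    ids <- names(grp)[names(grp) %in% se]
    return(done(ids, ids))
  }
  pid <- pairingIds(design)
  keys <- intersect(pid[se], pid[sm])
  if (length(keys) > 0L) {
    eByKey <- se[match(keys, pid[se])]
    mByKey <- sm[match(keys, pid[sm])]
    if (anyDuplicated(pid[se]) || anyDuplicated(pid[sm]))
      stop("pairing ids are not unique within an assay")
    bad <- grp[eByKey] != grp[mByKey]
    if (any(bad))
      stop("pairing key(s) link samples of different groups: ",
           paste(keys[bad], collapse = ", "))
    ord <- order(as.numeric(grp[eByKey]), eByKey)
    return(done(eByKey[ord], mByKey[ord]))
  }
  if (allowSorted) {
    eg <- split(sort(se), grp[sort(se)])
    mg <- split(sort(sm), grp[sort(sm)])
    if (!all(lengths(eg) == lengths(mg)))
      stop("sorted alignment impossible: group sizes differ across assays")
    warning("no pairing keys link the assays; aligning equal-sized ",
            "groups by sorted sample id - verify this matches the study")
    return(done(unlist(eg, use.names = FALSE),
                unlist(mg, use.names = FALSE)))
  }
  stop("expression and metabolite samples are not matched by id and no ",
       "pairing key links them; supply pairing ids or set ",
       "allowSortedAlignment = TRUE")
}

#' Screen every gene-metabolite pair for differential association
#'
#' Fits the phenotype-interaction model to each (gene, metabolite) pair,
#' computes the within-group correlations and their signed difference,
#' and flags pairs passing the conjunction rule
#' \code{|diff_corr| > corrThreshold} and
#' \code{p_interaction < pThreshold} (both strict). The expression
#' matrix is expected to be restricted to the genes of interest (e.g.
#' DEGs after low-mean filtering) and the metabolite matrix to features
#' surviving the missingness filter.
#'
#' The per-pair algebra uses the exact identity that \code{beta4} of the
#' joint fit equals the within-group-2 slope minus the within-group-1
#' slope, which vectorizes across all genes for each metabolite; results
#' are identical to [fitPairInteractionModel()] applied pairwise.
#'
#' @param expression,metabolites [OmicsMatrix-class] objects; metabolite
#'   values may contain \code{NA} (excluded pairwise).
#' @param design a [SampleDesign-class] linking the samples.
#' @param corrThreshold minimum absolute differential correlation
#'   (default 1.0).
#' @param pThreshold maximum interaction P-value (default 0.001).
#' @param method correlation method, \code{"rank"} (default) or
#'   \code{"linear"}.
#' @param minPerGroup minimum complete samples per group (default 5).
#' @param allowSortedAlignment permit last-resort sorted-id alignment of
#'   equal-sized groups when no pairing key links the assays (off by
#'   default; emits a warning when used).
#' @return a data.frame with one row per pair and columns
#'   \code{gene_id}, \code{metabolite_id}, \code{beta1}..\code{beta4},
#'   \code{se_beta4}, \code{t_beta4}, \code{p_interaction},
#'   \code{n_used}, \code{r_group1}, \code{r_group2}, \code{diff_corr},
#'   \code{selected}, \code{flag}; sorted by decreasing
#'   \code{|diff_corr|}, then increasing \code{p_interaction}, then ids.
#' @export
screenAllPairs <- function(expression, metabolites, design,
                           corrThreshold = 1.0, pThreshold = 0.001,
                           method = c("rank", "linear"),
                           minPerGroup = 5L,
                           allowSortedAlignment = FALSE) {
  method <- match.arg(method)
  al <- .alignAssays(expression, metabolites, design,
                     allowSorted = allowSortedAlignment)
  E <- al$g; M <- al$m; p <- al$p
  G <- nrow(E); K <- nrow(M)
  if (G == 0L || K == 0L) stop("empty feature set")
  i1 <- which(p == 0); i2 <- which(p == 1)
  eps <- .Machine$double.eps

  out <- vector("list", K)
  for (j in seq_len(K)) {
    mj <- M[j, ]
    obs <- !is.na(mj)
    idx1 <- i1[obs[i1]]; idx2 <- i2[obs[i2]]
    n1 <- length(idx1); n2 <- length(idx2)
    nUsed <- n1 + n2; df <- nUsed - 4L
    blank <- data.frame(
      gene_id = rownames(E), metabolite_id = rownames(M)[j],
      beta1 = NA_real_, beta2 = NA_real_, beta3 = NA_real_,
      beta4 = NA_real_, se_beta4 = NA_real_, t_beta4 = NA_real_,
      p_interaction = NA_real_, n_used = nUsed,
      r_group1 = NA_real_, r_group2 = NA_real_, diff_corr = NA_real_,
      selected = FALSE, flag = "insufficient_samples",
      stringsAsFactors = FALSE)
    if (n1 < minPerGroup || n2 < minPerGroup || df < 1L) {
      out[[j]] <- blank
      next
    }
    grpStats <- function(idx) {
      Ek <- E[, idx, drop = FALSE]
      mk <- mj[idx]
      nk <- length(idx)
      gbar <- rowMeans(Ek)
      Sxx <- rowSums(Ek^2) - nk * gbar^2
      Sxy <- as.vector(Ek %*% mk) - nk * gbar * mean(mk)
      Syy <- sum((mk - mean(mk))^2)
      slope <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
      rssg <- Syy - ifelse(Sxx > 0, Sxy^2 / Sxx, 0)
      r <- if (method == "rank") {
        Rk <- t(apply(Ek, 1L, rank))
        rmk <- rank(mk)
        rSxx <- rowSums(Rk^2) - nk * rowMeans(Rk)^2
        rSxy <- as.vector(Rk %*% rmk) - nk * rowMeans(Rk) * mean(rmk)
        rSyy <- sum((rmk - mean(rmk))^2)
        ifelse(rSxx > eps & rSyy > eps, rSxy / sqrt(rSxx * rSyy), NA_real_)
      } else {
        ifelse(Sxx > eps & Syy > eps, Sxy / sqrt(Sxx * Syy), NA_real_)
      }
      list(gbar = gbar, Sxx = Sxx, slope = slope, rss = pmax(rssg, 0),
           Syy = Syy, mbar = mean(mk), r = r)
    }
    g1 <- grpStats(idx1); g2 <- grpStats(idx2)
    beta2 <- g1$slope
    beta4 <- g2$slope - g1$slope
    beta1 <- g1$mbar - g1$slope * g1$gbar
    beta3 <- (g2$mbar - g2$slope * g2$gbar) - beta1
    rss <- g1$rss + g2$rss
    s2 <- rss / df
    se4 <- sqrt(s2 * (1 / g1$Sxx + 1 / g2$Sxx))
    t4 <- beta4 / se4
    pint <- 2 * stats::pt(-abs(t4), df)
    tss <- g1$Syy + g2$Syy
    flag <- rep("ok", G)
    flag[g1$Sxx <= eps | g2$Sxx <= eps] <- "rank_deficient"
    zeroRes <- flag == "ok" & rss <= 1e-10 * max(tss, eps)
    flag[zeroRes] <- "zero_residual_variance"
    pint[flag != "ok"] <- NA_real_
    se4[flag == "zero_residual_variance"] <- 0
    t4[zeroRes] <- ifelse(abs(beta4[zeroRes]) < sqrt(eps), 0,
                          sign(beta4[zeroRes]) * Inf)
    dc <- diffCorrelation(g1$r, g2$r)
    blank$beta1 <- beta1; blank$beta2 <- beta2
    blank$beta3 <- beta3; blank$beta4 <- beta4
    blank$se_beta4 <- se4; blank$t_beta4 <- t4
    blank$p_interaction <- pint
    blank$r_group1 <- g1$r; blank$r_group2 <- g2$r
    blank$diff_corr <- dc
    blank$flag <- flag
    out[[j]] <- blank
  }
  tbl <- do.call(rbind, out)
  tbl <- selectAssociations(tbl, corrThreshold, pThreshold)
  ord <- order(-abs(tbl$diff_corr), tbl$p_interaction, tbl$gene_id,
               tbl$metabolite_id, na.last = TRUE)
  tbl <- tbl[ord, , drop = FALSE]
  rownames(tbl) <- NULL
  tbl
}

#' Apply the differential-association selection rule
#'
#' Recomputes the \code{selected} flag of a pair-association table:
#' a pair is selected iff its fit is non-degenerate,
#' \code{|diff_corr| > corrThreshold} and
#' \code{p_interaction < pThreshold} (both strict).
#'
#' @param tbl data.frame with columns \code{diff_corr},
#'   \code{p_interaction} and optionally \code{flag}.
#' @param corrThreshold,pThreshold selection thresholds.
#' @return \code{tbl} with an updated logical \code{selected} column.
#' @export
selectAssociations <- function(tbl, corrThreshold = 1.0,
                               pThreshold = 0.001) {
  ok <- if ("flag" %in% names(tbl)) tbl$flag == "ok" else TRUE
  tbl$selected <- ok &
    !is.na(tbl$diff_corr) & abs(tbl$diff_corr) > corrThreshold &
    !is.na(tbl$p_interaction) & tbl$p_interaction < pThreshold
  tbl
}

#' Histogram summary of interaction P-values
#'
#' Fixed-width bins over [0, 1] (default width 0.05); degenerate pairs
#' with missing P are excluded.
#'
#' @param tbl pair-association table from [screenAllPairs()].
#' @param binWidth bin width (must divide 1 evenly).
#' @return data.frame with columns \code{bin_low}, \code{bin_high},
#'   \code{count}.
#' @export
pairPValueHistogram <- function(tbl, binWidth = 0.05) {
  nb <- round(1 / binWidth)
  if (abs(nb * binWidth - 1) > 1e-9)
    stop("binWidth must divide 1 evenly")
  p <- tbl$p_interaction
  p <- p[!is.na(p)]
  breaks <- seq(0, 1, length.out = nb + 1L)
  cnt <- tabulate(pmin(findInterval(p, breaks, rightmost.closed = TRUE),
                       nb), nbins = nb)
  data.frame(bin_low = breaks[-(nb + 1L)], bin_high = breaks[-1L],
             count = cnt)
}
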