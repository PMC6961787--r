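#' @include omicsmatrix.R
NULL

#' Upper tail of the hypergeometric distribution
#'
#' Exact over-representation probability \eqn{P(X \ge k)} for \eqn{X}
#' hypergeometric with \code{N} items of which \code{K} are successes
#' and \code{n} are drawn. Computed by exact summation of the
#' hypergeometric mass (no normal approximation).
#'
#' @param k observed successes in the draw.
#' @param K successes in the population.
#' @param n draw size.
#' @param N population size.
#' @return the exact tail probability.
#' @examples
#' hypergeometricTail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeometricTail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (anyNA(c(k, K, n, N)) || k < 0 || K < 0 || n < 0 ||
      k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n), K, n <= N)")
  if (k == 0) return(1.0)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Read a pathway annotation
#'
#' Two-column TSV with header columns \code{pathway_id} and
#' \code{metabolite_id}, one row per membership.
#'
#' @param path path to the TSV.
#' @return a named list of character vectors (class
#'   \code{"PathwayAnnotation"}).
#' @export
readPathwayAnnotation <- function(path) {
  if (!file.exists(path)) stop("pathway annotation not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "metabolite_id") %in% names(df)))
    stop("annotation must have columns pathway_id, metabolite_id")
  ann <- lapply(split(df$metabolite_id, df$pathway_id), unique)
  class(ann) <- "PathwayAnnotation"
  ann
}

#' Write a pathway annotation
#'
#' @param annotation named list, pathway id to member metabolite ids.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePathwayAnnotation <- function(annotation, path) {
  df <- data.frame(
    pathway_id = rep(names(annotation), lengths(annotation)),
    metabolite_id = unlist(annotation, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# NMR feature names carry a positional suffix ("ethanol_13") that no
# annotation contains; matching is case-insensitive after stripping it.
.normalizeMetaboliteId <- function(ids) {
  tolower(sub("_[0-9]+$", "", ids))
}

#' Metabolite-set over-representation analysis
#'
#' One-sided hypergeometric test of the selected metabolites against
#' each pathway of the annotation. Metabolite ids are matched to the
#' annotation case-insensitively after stripping a trailing
#' \code{"_<number>"} feature index. The universe is, per
#' \code{universePolicy}, the annotated metabolites that were measured
#' (default; requires \code{measured}) or all annotated metabolites.
#'
#' @param selected character vector of selected metabolite ids.
#' @param annotation a \code{"PathwayAnnotation"} (named list, pathway id
#'   to member ids), e.g. from [readPathwayAnnotation()] or
#'   [generatePathwayAnnotation()].
#' @param measured character vector of all measured metabolite ids
#'   (required for the default universe policy).
#' @param universePolicy \code{"measured"} (annotated and measured,
#'   default) or \code{"annotated"} (all annotated).
#' @param alpha significance threshold on the raw P-value (default 0.05,
#'   strict).
#' @param adjust add a Benjamini-Hochberg \code{p_adjusted} column.
#' @return a data.frame with one row per pathway having at least one
#'   universe member: \code{pathway_id}, \code{k} (selected in pathway),
#'   \code{K} (universe in pathway), \code{n} (selected in universe),
#'   \code{N} (universe size), \code{p_value}, \code{significant},
#'   \code{hit_ids} (comma-joined); sorted by increasing P then pathway
#'   id.
#' @export
enrichMetabolites <- function(selected, annotation, measured = NULL,
                              universePolicy = c("measured", "annotated"),
                              alpha = 0.05, adjust = FALSE) {
  universePolicy <- match.arg(universePolicy)
  annNorm <- lapply(annotation, .normalizeMetaboliteId)
  allAnnotated <- unique(unlist(annNorm, use.names = FALSE))
  selNorm <- .normalizeMetaboliteId(selected)
  universe <- if (universePolicy == "measured") {
    if (is.null(measured))
      stop("universePolicy = 'measured' requires the measured ids")
    intersect(allAnnotated, unique(.normalizeMetaboliteId(measured)))
  } else allAnnotated
  selU <- unique(selNorm[selNorm %in% universe])
  if (length(selU) == 0L)
    stop("no selected metabolite maps into the universe; unmatched ids: ",
         paste(unique(selected), collapse = ", "))
  N <- length(universe)
  n <- length(selU)
  rows <- lapply(sort(names(annotation)), function(pw) {
    members <- intersect(annNorm[[pw]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    hits <- intersect(selU, members)
    k <- length(hits)
    data.frame(pathway_id = pw, k = k, K = K, n = n, N = N,
               p_value = hypergeometricTail(k, K, n, N),
               hit_ids = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no pathway has members in the universe")
  res$significant <- res$p_value < alpha
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("pathway_id", "k", "K", "n", "N", "p_value", "significant",
          if (adjust) "p_adjusted", "hit_ids")]
}
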