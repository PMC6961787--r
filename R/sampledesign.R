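#' @include AllGenerics.R
NULL

#' Construct a SampleDesign
#'
#' @param sampleId character vector of unique sample ids.
#' @param group group assignment, coercible to a two-level factor. The
#'   level order defines which group is "group 1" (the reference for all
#'   signed quantities); pass a factor to control it explicitly.
#' @param pairingId cross-assay pairing keys; defaults to the sample ids
#'   (samples matched one-to-one across assays).
#' @return a [SampleDesign-class].
#' @examples
#' SampleDesign(paste0("S", 1:6), rep(c("group1", "group2"), each = 3))
#' @export
SampleDesign <- function(sampleId, group, pairingId = sampleId) {
  sampleId <- as.character(sampleId)
  if (!is.factor(group)) group <- factor(group)
  group <- droplevels(group)
  new("SampleDesign", sampleId = sampleId, group = group,
      pairingId = as.character(pairingId))
}

#' @describeIn SampleDesign sample identifiers.
#' @param x a SampleDesign.
#' @export
setMethod("sampleIds", "SampleDesign", function(x) x@sampleId)

#' @describeIn SampleDesign group assignments (two-level factor named by
#'   sample id).
#' @export
setMethod("groupLabels", "SampleDesign", function(x) {
  g <- x@group
  names(g) <- x@sampleId
  g
})

#' @describeIn SampleDesign pairing keys (named by sample id).
#' @export
setMethod("pairingIds", "SampleDesign", function(x) {
  p <- x@pairingId
  names(p) <- x@sampleId
  p
})

setMethod("show", "SampleDesign", function(object) {
  tab <- table(object@group)
  cat(sprintf("SampleDesign: %d samples (%s)\n", length(object@sampleId),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(NULL)
})

#' Read a sample-design table
#'
#' Expects a TSV with a header and columns \code{sample_id},
#' \code{group} and optionally \code{pairing_id}.
#'
#' @param path path to the design TSV.
#' @param groupLevels optional character vector of length 2 fixing the
#'   group-level order (the first element becomes group 1).
#' @return a [SampleDesign-class].
#' @export
readSampleDesign <- function(path, groupLevels = NULL) {
  if (!file.exists(path)) stop("design table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  grp <- if (is.null(groupLevels)) factor(df$group)
         else factor(df$group, levels = groupLevels)
  if (anyNA(grp)) stop("group labels outside the stated groupLevels")
  pid <- if ("pairing_id" %in% names(df)) df$pairing_id else df$sample_id
  SampleDesign(df$sample_id, grp, pid)
}

#' Write a sample-design table
#'
#' @param design a [SampleDesign-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleDesign <- function(design, path) {
  df <- data.frame(sample_id = sampleIds(design),
                   group = as.character(groupLabels(design)),
                   pairing_id = unname(pairingIds(design)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# sample ids per group, in design order; group 1 first
.groupIndex <- function(design) {
  g <- groupLabels(design)
  split(names(g), g)[levels(g)]
}
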