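#' @include AllGenerics.R
NULL

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features in rows and samples in columns.
#'   Row and column names supply the identifiers unless overridden.
#' @param featureIds,sampleIds optional identifier vectors overriding the
#'   dimnames of \code{values}.
#' @param scaleTag \code{"raw"} or \code{"log2"}.
#' @return an [OmicsMatrix-class].
#' @examples
#' m <- OmicsMatrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2"))))
#' featureIds(m)
#' @export
OmicsMatrix <- function(values, featureIds = NULL, sampleIds = NULL,
                        scaleTag = c("raw", "log2")) {
  scaleTag <- match.arg(scaleTag)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(featureIds)) rownames(values) <- featureIds
  if (!is.null(sampleIds)) colnames(values) <- sampleIds
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature_%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%d", seq_len(ncol(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values))
  new("OmicsMatrix", se, scaleTag = scaleTag)
}

#' @describeIn OmicsMatrix feature (row) identifiers.
#' @param x an OmicsMatrix.
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) rownames(x))

#' @describeIn OmicsMatrix sample (column) identifiers.
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x))

#' @describeIn OmicsMatrix the scale tag.
#' @export
setMethod("scaleTag", "OmicsMatrix", function(x) x@scaleTag)

#' @describeIn OmicsMatrix the measurements as a plain numeric matrix.
#' @export
setMethod("omicsValues", "OmicsMatrix",
          function(x) SummarizedExperiment::assay(x, "values"))

setMethod("show", "OmicsMatrix", function(object) {
  v <- omicsValues(object)
  cat(sprintf("OmicsMatrix: %d features x %d samples [%s scale]\n",
              nrow(v), ncol(v), scaleTag(object)))
  nmiss <- sum(is.na(v))
  if (nmiss > 0)
    cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
                100 * nmiss / length(v)))
  cat("  features: ", paste(utils::head(rownames(v), 4L), collapse = ", "),
      if (nrow(v) > 4L) ", ..." else "", "\n", sep = "")
  cat("  samples:  ", paste(utils::head(colnames(v), 4L), collapse = ", "),
      if (ncol(v) > 4L) ", ..." else "", "\n", sep = "")
  invisible(NULL)
})

.defaultMissingTokens <- c("", "NA", "NaN")

#' Read a tab-delimited feature table
#'
#' Parses a features x samples TSV whose first column holds feature ids
#' and whose header row holds sample ids. Cells equal to one of
#' \code{missingTokens} become \code{NA}; any other non-numeric cell is an
#' error that names the offending row and column.
#'
#' @param path path to the TSV file.
#' @param missingTokens character vector of cell values parsed as missing.
#' @param scaleTag scale tag to attach to the result.
#' @return an [OmicsMatrix-class].
#' @export
readFeatureTable <- function(path, missingTokens = .defaultMissingTokens,
                             scaleTag = c("raw", "log2")) {
  scaleTag <- match.arg(scaleTag)
  if (!file.exists(path)) stop("feature table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("feature table is empty or lacks data rows: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sampleIds <- header[-1L]
  if (length(sampleIds) == 0L) stop("no sample columns in ", path)
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != length(header)))
    stop("row ", which(nc != length(header))[1L],
         " has a different number of fields than the header")
  featureIds <- vapply(cells, `[[`, character(1L), 1L)
  if (anyDuplicated(featureIds))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(featureIds[duplicated(featureIds)]), collapse = ", "))
  raw <- matrix(unlist(lapply(cells, `[`, -1L), use.names = FALSE),
                nrow = length(cells), byrow = TRUE)
  isMissing <- matrix(raw %in% missingTokens, nrow = nrow(raw))
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !isMissing, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 raw[bad[1L, 1L], bad[1L, 2L]],
                 featureIds[bad[1L, 1L]], sampleIds[bad[1L, 2L]]))
  vals[isMissing] <- NA_real_
  OmicsMatrix(vals, featureIds = featureIds, sampleIds = sampleIds,
              scaleTag = scaleTag)
}

#' Write a feature table as tab-delimited text
#'
#' Emits the format read by [readFeatureTable()]: a header line
#' \code{feature_id<TAB>sample ids...}, one row per feature, missing
#' values written as \code{NA}, \code{"."} as decimal separator and full
#' double precision so that a write/read round trip is lossless.
#'
#' @param x an [OmicsMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  v <- omicsValues(x)
  fmt <- function(row) {
    s <- formatC(row, format = "g", digits = 17)
    s[is.na(row)] <- "NA"
    s
  }
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"), character(1L))
  writeLines(c(paste(c("feature_id", colnames(v)), collapse = "\t"), body),
             path)
  invisible(path)
}
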