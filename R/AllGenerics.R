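#' @include AllClasses.R
NULL

#' Feature identifiers of an object
#' @param x an object with features (rows).
#' @return character vector of feature ids.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Sample identifiers of an object
#' @param x an object with samples.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Scale tag of a measurement matrix
#' @param x an [OmicsMatrix-class].
#' @return \code{"raw"} or \code{"log2"}.
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' Measurement values as a base matrix
#' @param x an [OmicsMatrix-class].
#' @return numeric matrix, features in rows, samples in columns.
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' Group labels of a sample design
#' @param x a [SampleDesign-class].
#' @return factor of group assignments, one per sample, two levels.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Cross-assay pairing keys of a sample design
#' @param x a [SampleDesign-class].
#' @return character vector of pairing keys, one per sample.
#' @export
setGeneric("pairingIds", function(x) standardGeneric("pairingIds"))
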