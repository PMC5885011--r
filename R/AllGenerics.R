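#' Accessor generics
#'
#' Small family of accessors used across the package's S4 classes, so that
#' downstream code never touches slots directly.
#'
#' @param x An object of one of the package's S4 classes.
#' @param ... Passed on to methods.
#' @return The corresponding component of \code{x}; see the class
#'   documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("readSequences", function(x, ...) standardGeneric("readSequences"))

#' @rdname accessors
#' @export
setGeneric("readQualities", function(x, ...) standardGeneric("readQualities"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x, ...) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("processLog", function(x, ...) standardGeneric("processLog"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x, ...) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("sampleCounts", function(x, ...) standardGeneric("sampleCounts"))

#' @rdname accessors
#' @export
setGeneric("entropyValues", function(x, ...) standardGeneric("entropyValues"))

#' @rdname accessors
#' @export
setGeneric("oligotypeLabels", function(x, ...) standardGeneric("oligotypeLabels"))

#' @rdname accessors
#' @export
setGeneric("oligoComponents", function(x, ...) standardGeneric("oligoComponents"))

#' @rdname accessors
#' @export
setGeneric("representatives", function(x, ...) standardGeneric("representatives"))

#' @rdname accessors
#' @export
setGeneric("noiseCounts", function(x, ...) standardGeneric("noiseCounts"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("haplotypeCounts", function(x, ...) standardGeneric("haplotypeCounts"))
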