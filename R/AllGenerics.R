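#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("tumorIndex", function(x) standardGeneric("tumorIndex"))

#' @rdname accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname accessors
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname accessors
#' @export
setGeneric("vaf", function(x) standardGeneric("vaf"))

#' @rdname accessors
#' @export
setGeneric("armStatesOf", function(x) standardGeneric("armStatesOf"))

#' @rdname accessors
#' @export
setGeneric("spectrumCounts", function(x) standardGeneric("spectrumCounts"))
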