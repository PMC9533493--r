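#' Accessors for package containers
#'
#' Small accessor generics for the S4 containers: ids, value matrices and
#' per-part metadata. Prefer these over direct slot access.
#'
#' @param x a package object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("partIds", function(x) standardGeneric("partIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("meanRA", function(x) standardGeneric("meanRA"))

#' @rdname accessors
#' @export
setGeneric("traitIds", function(x) standardGeneric("traitIds"))

#' @rdname accessors
#' @export
setGeneric("sigmaG", function(x) standardGeneric("sigmaG"))

#' @rdname accessors
#' @export
setGeneric("sigmaE", function(x) standardGeneric("sigmaE"))

#' @rdname accessors
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))
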