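#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return The slot content the accessor names (see the class pages).
#' @name viscnet-generics
#' @keywords internal
NULL

#' @rdname viscnet-generics
#' @export
setGeneric("tacs", function(x, ...) standardGeneric("tacs"))

#' @rdname viscnet-generics
#' @export
setGeneric("amounts", function(x, ...) standardGeneric("amounts"))

#' @rdname viscnet-generics
#' @export
setGeneric("kineticRates", function(x, ...) standardGeneric("kineticRates"))

#' @rdname viscnet-generics
#' @export
setGeneric("subjects", function(x, ...) standardGeneric("subjects"))

#' @rdname viscnet-generics
#' @export
setGeneric("histology", function(x, ...) standardGeneric("histology"))

#' @rdname viscnet-generics
#' @export
setGeneric("densities", function(x, ...) standardGeneric("densities"))

#' @rdname viscnet-generics
#' @export
setGeneric("taxa", function(x, ...) standardGeneric("taxa"))

#' @rdname viscnet-generics
#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))

#' @rdname viscnet-generics
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname viscnet-generics
#' @export
setGeneric("deliveredPreSystemic", function(x, tMax = 10) standardGeneric("deliveredPreSystemic"))
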