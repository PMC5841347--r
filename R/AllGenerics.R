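#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers, so user code
#' never touches slots directly.
#'
#' @param object an object of the relevant class.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("surfaceValues", function(object, ...) standardGeneric("surfaceValues"))

#' @rdname accessors
#' @export
setGeneric("variableName", function(object, ...) standardGeneric("variableName"))

#' @rdname accessors
#' @export
setGeneric("gridOf", function(object, ...) standardGeneric("gridOf"))

#' @rdname accessors
#' @export
setGeneric("cellCentroids", function(object, ...) standardGeneric("cellCentroids"))

#' @rdname accessors
#' @export
setGeneric("neighborCounts", function(object, ...) standardGeneric("neighborCounts"))

#' @rdname accessors
#' @export
setGeneric("weightsStyle", function(object, ...) standardGeneric("weightsStyle"))

#' @rdname accessors
#' @export
setGeneric("totalWeight", function(object, ...) standardGeneric("totalWeight"))

#' @rdname accessors
#' @export
setGeneric("lambdaHat", function(object, ...) standardGeneric("lambdaHat"))

#' @rdname accessors
#' @export
setGeneric("pseudoR2", function(object, ...) standardGeneric("pseudoR2"))

#' @rdname accessors
#' @export
setGeneric("innovations", function(object, ...) standardGeneric("innovations"))
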