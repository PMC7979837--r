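#' @title Generics for spotcells classes
#' @description Accessor generics shared by the spatial/expression classes.
#' @name spotcells-generics
#' @keywords internal
NULL

#' @rdname spotcells-generics
#' @param x an object
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname spotcells-generics
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname spotcells-generics
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname spotcells-generics
#' @export
setGeneric("neighbourCounts", function(x) standardGeneric("neighbourCounts"))

#' @rdname spotcells-generics
#' @param id a single cell identifier
#' @export
setGeneric("neighboursOf", function(x, id) standardGeneric("neighboursOf"))

#' @rdname spotcells-generics
#' @export
setGeneric("degenerateCells", function(x) standardGeneric("degenerateCells"))

#' @rdname spotcells-generics
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname spotcells-generics
#' @export
setGeneric("polygonOf", function(x, id) standardGeneric("polygonOf"))

#' @rdname spotcells-generics
#' @export
setGeneric("graphMethod", function(x) standardGeneric("graphMethod"))

#' @rdname spotcells-generics
#' @export
setGeneric("trueAdjacency", function(x) standardGeneric("trueAdjacency"))

#' @rdname spotcells-generics
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))

#' @rdname spotcells-generics
#' @export
setGeneric("membraneSpots", function(x) standardGeneric("membraneSpots"))

#' @rdname spotcells-generics
#' @export
setGeneric("mrnaSpots", function(x) standardGeneric("mrnaSpots"))
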