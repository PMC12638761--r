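#' @include BrainNetMed-package.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Accessors are the
#' supported way to read object contents; slots are internal.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("netWeights", function(x, ...) standardGeneric("netWeights"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x, ...) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("bandName", function(x, ...) standardGeneric("bandName"))

#' @rdname accessors
#' @export
setGeneric("sessionTag", function(x, ...) standardGeneric("sessionTag"))

#' @rdname accessors
#' @export
setGeneric("globalEfficiency", function(x, ...) standardGeneric("globalEfficiency"))

#' @rdname accessors
#' @export
setGeneric("nodalEfficiency", function(x, ...) standardGeneric("nodalEfficiency"))

#' @rdname accessors
#' @export
setGeneric("globalClustering", function(x, ...) standardGeneric("globalClustering"))

#' @rdname accessors
#' @export
setGeneric("localClustering", function(x, ...) standardGeneric("localClustering"))

#' @rdname accessors
#' @export
setGeneric("nodeDegree", function(x, ...) standardGeneric("nodeDegree"))

#' @rdname accessors
#' @export
setGeneric("gScores", function(x, ...) standardGeneric("gScores"))

#' @rdname accessors
#' @export
setGeneric("fitIndices", function(x, ...) standardGeneric("fitIndices"))

#' @rdname accessors
#' @export
setGeneric("selectionTable", function(x, ...) standardGeneric("selectionTable"))

#' @rdname accessors
#' @export
setGeneric("selectedRois", function(x, ...) standardGeneric("selectedRois"))

#' @rdname accessors
#' @export
setGeneric("iccValue", function(x, ...) standardGeneric("iccValue"))
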