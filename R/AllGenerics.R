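#' @rdname accessors
#' @export
setGeneric("centerline", function(x) standardGeneric("centerline"))

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))

#' @rdname accessors
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @rdname accessors
#' @export
setGeneric("opticDisc", function(x) standardGeneric("opticDisc"))

#' @rdname accessors
#' @export
setGeneric("trees", function(x) standardGeneric("trees"))

#' @rdname accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname accessors
#' @export
setGeneric("featureVector", function(x) standardGeneric("featureVector"))

#' @rdname accessors
#' @export
setGeneric("leftChild", function(x) standardGeneric("leftChild"))

#' @rdname accessors
#' @export
setGeneric("rightChild", function(x) standardGeneric("rightChild"))

#' @rdname accessors
#' @export
setGeneric("segmentPath", function(x) standardGeneric("segmentPath"))

#' @rdname accessors
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))

#' @rdname accessors
#' @export
setGeneric("segmentWidth", function(x) standardGeneric("segmentWidth"))

#' @rdname accessors
#' @export
setGeneric("isFinalized", function(x) standardGeneric("isFinalized"))
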