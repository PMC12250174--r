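#' @name neomotion-generics
#' @title Accessor generics for neomotion classes
#'
#' @description Small accessor generics used across the package's S4
#' classes. All return simple base types; slots are never accessed
#' directly by user code.
#'
#' @param x an object.
#' @return See the individual methods.
NULL

#' @rdname neomotion-generics
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname neomotion-generics
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname neomotion-generics
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname neomotion-generics
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname neomotion-generics
#' @export
setGeneric("nLandmarks", function(x) standardGeneric("nLandmarks"))

#' @rdname neomotion-generics
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))

#' @rdname neomotion-generics
#' @export
setGeneric("motionValue", function(x) standardGeneric("motionValue"))

#' @rdname neomotion-generics
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @rdname neomotion-generics
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname neomotion-generics
#' @export
setGeneric("windowValues", function(x) standardGeneric("windowValues"))
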