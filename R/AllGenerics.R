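#' @rdname volData
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname voxelPitch
#' @export
setGeneric("voxelPitch", function(x) standardGeneric("voxelPitch"))

#' @rdname centerIndex
#' @export
setGeneric("centerIndex", function(x) standardGeneric("centerIndex"))

#' @rdname lagMode
#' @export
setGeneric("lagMode", function(x) standardGeneric("lagMode"))

#' @rdname ViewSet-accessors
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))

#' @rdname ViewSet-accessors
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))

#' @rdname ViewSet-accessors
#' @export
setGeneric("trueShifts", function(x) standardGeneric("trueShifts"))

#' @rdname ViewSet-accessors
#' @export
setGeneric("getView", function(x, i) standardGeneric("getView"))

#' @rdname ViewSet-accessors
#' @export
setGeneric("referenceView", function(x) standardGeneric("referenceView"))

#' @rdname ViewSet-accessors
#' @export
setGeneric("viewFrame", function(x) standardGeneric("viewFrame"))

#' @rdname SolverState-accessors
#' @export
setGeneric("divergenceTrace", function(x) standardGeneric("divergenceTrace"))

#' @rdname autocorrelate
#' @export
setGeneric("autocorrelate",
  function(a, mode = c("circular", "linear-padded"), ...)
    standardGeneric("autocorrelate"))

#' @rdname flipVol
#' @export
setGeneric("flipVol", function(a) standardGeneric("flipVol"))
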