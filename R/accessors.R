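#' Raw array of a volume
#'
#' @param x an \linkS4class{ObjectVolume} or \linkS4class{LagVolume}.
#' @return the underlying 3D numeric array.
#' @rdname volData
#' @export
setMethod("volData", "ObjectVolume", function(x) x@data)

#' @rdname volData
#' @export
setMethod("volData", "LagVolume", function(x) x@data)

#' Voxel pitch of a volume
#'
#' @param x an \linkS4class{ObjectVolume}.
#' @return micrometres per voxel along (z, y, x).
#' @rdname voxelPitch
#' @export
setMethod("voxelPitch", "ObjectVolume", function(x) x@voxelPitch)

#' Zero-lag voxel of a lag volume
#'
#' @param x a \linkS4class{LagVolume}.
#' @return 1-based (z, y, x) index of the zero-lag voxel.
#' @rdname centerIndex
#' @export
setMethod("centerIndex", "LagVolume", function(x) x@centerIndex)

#' Correlation geometry of a lag volume
#'
#' @param x a \linkS4class{LagVolume}.
#' @return \code{"circular"} or \code{"linear-padded"}.
#' @rdname lagMode
#' @export
setMethod("lagMode", "LagVolume", function(x) x@mode)

#' @export
setMethod("dim", "ObjectVolume", function(x) dim(x@data))

#' @export
setMethod("dim", "LagVolume", function(x) dim(x@data))

#' ViewSet accessors
#'
#' @param x a \linkS4class{ViewSet}.
#' @param i view index.
#' @return \code{nViews}: number of views; \code{viewAngles}: angles in
#'   degrees; \code{trueShifts}: N x 3 shift matrix; \code{getView}: the i-th
#'   \linkS4class{ObjectVolume}; \code{referenceView}: the 0-degree view;
#'   \code{viewFrame}: the frame the views live in.
#' @name ViewSet-accessors
#' @rdname ViewSet-accessors
#' @export
setMethod("nViews", "ViewSet", function(x) length(x@views))

#' @rdname ViewSet-accessors
#' @export
setMethod("viewAngles", "ViewSet", function(x) x@angles)

#' @rdname ViewSet-accessors
#' @export
setMethod("trueShifts", "ViewSet", function(x) x@trueShifts)

#' @rdname ViewSet-accessors
#' @export
setMethod("getView", "ViewSet", function(x, i) x@views[[i]])

#' @rdname ViewSet-accessors
#' @export
setMethod("referenceView", "ViewSet", function(x) x@views[[x@referenceIndex]])

#' @rdname ViewSet-accessors
#' @export
setMethod("viewFrame", "ViewSet", function(x) x@frame)

#' SolverState accessors
#'
#' @param x a \linkS4class{SolverState}.
#' @return \code{divergenceTrace}: data.frame of per-checkpoint iteration,
#'   I-divergence and iterate mass.
#' @name SolverState-accessors
#' @rdname SolverState-accessors
#' @export
setMethod("divergenceTrace", "SolverState", function(x) x@trace)

setMethod("show", "ObjectVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ObjectVolume %d x %d x %d (z,y,x), pitch (%g, %g, %g) um\n",
              d[1], d[2], d[3], object@voxelPitch[1], object@voxelPitch[2],
              object@voxelPitch[3]))
  cat(sprintf("  range [%.4g, %.4g], sum %.6g\n",
              min(object@data), max(object@data), sum(object@data)))
})

setMethod("show", "LagVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LagVolume %d x %d x %d, zero lag at (%d, %d, %d), mode %s\n",
              d[1], d[2], d[3], object@centerIndex[1], object@centerIndex[2],
              object@centerIndex[3], object@mode))
  cat(sprintf("  value at zero lag %.6g, sum %.6g\n",
              object@data[object@centerIndex[1], object@centerIndex[2],
                          object@centerIndex[3]], sum(object@data)))
})

setMethod("show", "PSFModel", function(object) {
  cat(sprintf(
    "PSFModel: sigma (scan, transverse, lateral) = (%g, %g, %g) um, support %s\n",
    object@sigmaScan, object@sigmaTransverse, object@sigmaLateral,
    paste(object@support, collapse = " x ")))
})

setMethod("show", "ViewSet", function(object) {
  d <- dim(object@views[[1]]@data)
  cat(sprintf("ViewSet: %d views of %d x %d x %d, frame '%s'\n",
              length(object@views), d[1], d[2], d[3], object@frame))
  cat(sprintf("  angles: %s\n", paste(object@angles, collapse = ", ")))
})

setMethod("show", "SolverState", function(object) {
  cat(sprintf("SolverState (%s): t = %d, mode %s\n",
              object@scheme, object@t, object@mode))
  if (nrow(object@trace) > 0) {
    last <- object@trace[nrow(object@trace), ]
    cat(sprintf("  last checkpoint: iteration %d, I-divergence %.6g\n",
                last$iteration, last$idiv))
  }
})
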