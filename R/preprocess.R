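## Pre-processing: background subtraction, rotation back to the reference
## orientation, and sanitation of averaged auto-correlations. The pipeline
## order is fixed: background-subtract -> rotate-to-reference ->
## auto-correlate -> average -> absolute value.

#' Subtract the mean of a dark region
#'
#' Estimates the background as the mean intensity over a region where the
#' sample is not present and subtracts it from the whole view. Negative
#' values produced by the subtraction are kept; they are removed later, in
#' auto-correlation space, by \code{\link{sanitizeAcorr}}.
#'
#' @param view an \linkS4class{ObjectVolume}.
#' @param darkRegion list of three index ranges (z, y, x) defining the box;
#'   default is the 8x8x8 corner at the index origin.
#' @return the background-subtracted \linkS4class{ObjectVolume}; the mean of
#'   the dark region of the output is zero to float tolerance.
#' @export
subtractBackground <- function(view, darkRegion = NULL) {
  d <- dim(view@data)
  if (is.null(darkRegion))
    darkRegion <- lapply(pmin(d, 8L), seq_len)
  if (any(vapply(darkRegion, length, integer(1)) == 0L))
    .stop2("acorrtomo_validation_error", "empty dark region")
  for (ax in 1:3)
    if (any(darkRegion[[ax]] < 1L) || any(darkRegion[[ax]] > d[ax]))
      .stop2("acorrtomo_validation_error", "dark region outside the volume")
  bg <- mean(view@data[darkRegion[[1]], darkRegion[[2]], darkRegion[[3]]])
  ObjectVolume(view@data - bg, view@voxelPitch)
}

#' Rotate a view back to the reference orientation
#'
#' Applies \code{rotateVolume(view, -angle)}: the only geometric
#' pre-processing the auto-correlation route requires. A zero angle returns
#' the input unchanged.
#'
#' @param view an \linkS4class{ObjectVolume}.
#' @param angle the view's acquisition angle phi_i in degrees.
#' @param order interpolation order (1 or 3).
#' @return the re-oriented \linkS4class{ObjectVolume}.
#' @export
toReferenceFrame <- function(view, angle, order = 3) {
  if (angle %% 360 == 0) return(view)
  rotateVolume(view, -angle, order)
}

#' Pre-process a ViewSet
#'
#' Optionally background-subtracts every view, then rotates acquisition-frame
#' views back to the reference orientation. Views already in the reference
#' frame are only background-subtracted.
#'
#' @param views a \linkS4class{ViewSet}.
#' @param darkRegion passed to \code{\link{subtractBackground}}; \code{NULL}
#'   skips background subtraction.
#' @param order rotation interpolation order.
#' @return a reference-frame \linkS4class{ViewSet}.
#' @export
preprocessViews <- function(views, darkRegion = NULL, order = 3) {
  vs <- views@views
  if (!is.null(darkRegion))
    vs <- lapply(vs, subtractBackground, darkRegion = darkRegion)
  if (views@frame == "acquisition")
    vs <- mapply(function(v, a) toReferenceFrame(v, a, order), vs,
                 views@angles, SIMPLIFY = FALSE)
  ViewSet(vs, views@angles, trueShifts = views@trueShifts,
          referenceIndex = views@referenceIndex, frame = "reference")
}

#' Sanitize an averaged auto-correlation
#'
#' Takes the element-wise absolute value, removing the unwanted negative
#' values introduced by background subtraction and spectral round-off.
#' Idempotent; preserves the centro-symmetric structure.
#'
#' @param x a \linkS4class{LagVolume}.
#' @return a non-negative \linkS4class{LagVolume}.
#' @export
sanitizeAcorr <- function(x) {
  LagVolume(abs(x@data), mode = x@mode)
}
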