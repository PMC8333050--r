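## The two competing fused products: the registered direct-space average
## (the standard reconstruction baseline) and the inherently aligned
## auto-correlation average, plus the PSF averages.

#' Register one view against a reference by cross-correlation peak
#'
#' Returns the displacement m (lag relative to zero) maximizing
#' \code{correlateVol(reference, moving)}; the moving view is aligned by
#' translating it by \code{-m}. Integer-voxel precision only (the baseline
#' the auto-correlation route replaces). Ties are broken by smallest
#' Euclidean norm, then lexicographically on (z, y, x).
#'
#' @param reference,moving \linkS4class{ObjectVolume}s of identical shape.
#' @param mode correlation geometry.
#' @return integer length-3 displacement in voxels (z, y, x).
#' @export
registerPair <- function(reference, moving,
                         mode = c("circular", "linear-padded")) {
  mode <- match.arg(mode)
  if (all(reference@data == 0) || all(moving@data == 0))
    .stop2("acorrtomo_degenerate_error",
           "cannot register an all-zero volume")
  cc <- correlateVol(reference, moving, mode)
  arr <- cc@data
  mx <- max(arr)
  cand <- which(arr >= mx - .Machine$double.eps * 64 * abs(mx))
  d <- dim(arr)
  i0 <- cand - 1L
  z <- i0 %% d[1]; rest <- i0 %/% d[1]
  y <- rest %% d[2]; x <- rest %/% d[2]
  lag <- cbind(z + 1L, y + 1L, x + 1L) -
    matrix(cc@centerIndex, length(cand), 3, byrow = TRUE)
  ord <- order(rowSums(lag^2), lag[, 1], lag[, 2], lag[, 3])
  as.integer(lag[ord[1L], ])
}

#' Fuse views by direct-space averaging
#'
#' The standard multi-view reconstruction: each view is (optionally) aligned
#' against the reference view by \code{\link{registerPair}} and translated by
#' the negative of its displacement, then all views are averaged. With
#' \code{registered = FALSE} the raw average is taken, which smears
#' misaligned structure.
#'
#' @param views a reference-frame \linkS4class{ViewSet}.
#' @param registered align views before averaging?
#' @param mode registration correlation geometry.
#' @return the fused \linkS4class{ObjectVolume}.
#' @export
fuseDirect <- function(views, registered = TRUE,
                       mode = c("circular", "linear-padded")) {
  mode <- match.arg(mode)
  if (length(views@views) == 0L)
    .stop2("acorrtomo_validation_error", "empty ViewSet")
  if (views@frame != "reference")
    .stop2("acorrtomo_validation_error",
           "views must be pre-processed to the reference frame")
  ref <- views@views[[views@referenceIndex]]
  acc <- array(0, dim(ref@data))
  for (i in seq_along(views@views)) {
    v <- views@views[[i]]
    if (registered && i != views@referenceIndex) {
      m <- registerPair(ref, v, mode)
      v <- shiftVolume(v, -m)
    }
    acc <- acc + v@data
  }
  ObjectVolume(acc / length(views@views), ref@voxelPitch)
}

#' Fuse views by auto-correlation averaging
#'
#' The inherently aligned fusion: every view is auto-correlated (the
#' auto-correlations are centred in shift-space by definition), the
#' auto-correlations are averaged, and the average is sanitized by taking its
#' absolute value. No registration is performed or permitted; per-view rigid
#' shifts do not affect the result (exactly so in circular mode).
#'
#' @param views a reference-frame \linkS4class{ViewSet}.
#' @param mode correlation geometry.
#' @return the averaged, sanitized \linkS4class{LagVolume} (chi-bar).
#' @export
fuseAcorr <- function(views, mode = c("circular", "linear-padded")) {
  mode <- match.arg(mode)
  if (length(views@views) == 0L)
    .stop2("acorrtomo_validation_error", "empty ViewSet")
  if (views@frame != "reference")
    .stop2("acorrtomo_validation_error",
           "views must be pre-processed to the reference frame")
  acc <- NULL
  for (v in views@views) {
    a <- autocorrelate(v, mode)
    acc <- if (is.null(acc)) a@data else acc + a@data
  }
  sanitizeAcorr(LagVolume(acc / length(views@views), mode = mode))
}

#' Average PSF in direct and auto-correlation space
#'
#' Builds the direct-space average PSF \code{hbar = mean(h^{phi_i})}, the
#' auto-correlation-space average \code{Hbar = mean(A\{h^{phi_i}\})} that
#' blurs the averaged auto-correlation, and \code{A\{hbar\}} for comparison.
#' \code{A\{hbar\}} differs from \code{Hbar} whenever more than one view is
#' averaged: auto-correlation averaging discards the second-order cross-terms
#' between views, which is the origin of the sharper effective PSF.
#'
#' @param psfModel a \linkS4class{PSFModel}.
#' @param angles view angles in degrees.
#' @param voxelPitch micrometres per voxel.
#' @param mode correlation geometry for the auto-correlations.
#' @return a list with elements \code{hbar} (\linkS4class{ObjectVolume}),
#'   \code{Hbar} and \code{Ahbar} (\linkS4class{LagVolume}s).
#' @export
fusePsfAcorr <- function(psfModel, angles, voxelPitch = c(1, 1, 1),
                         mode = c("linear-padded", "circular")) {
  mode <- match.arg(mode)
  if (length(angles) < 1L)
    .stop2("acorrtomo_validation_error", "at least one angle required")
  hs <- lapply(angles, function(a) renderPSF(psfModel, a, voxelPitch))
  hbar <- Reduce(`+`, lapply(hs, slot, "data")) / length(hs)
  Hacc <- NULL
  for (h in hs) {
    A <- autocorrelate(h, mode, canonicalize = FALSE)
    Hacc <- if (is.null(Hacc)) A@data else Hacc + A@data
  }
  hbar_vol <- ObjectVolume(hbar, hs[[1]]@voxelPitch)
  list(hbar = hbar_vol,
       Hbar = LagVolume(Hacc / length(hs), mode = mode),
       Ahbar = autocorrelate(hbar_vol, mode, canonicalize = FALSE))
}
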