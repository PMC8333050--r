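## Resolution and quality metrics: effective PSF extraction, FWHM, line
## profiles, and the shift/flip-invariant recovery score used to compare
## reconstructions against ground truth.

#' Effective PSF implied by auto-correlation averaging
#'
#' Inverts the averaged auto-correlation-space PSF \code{Hbar} with
#' Schulz-Snyder iterations, starting from a centred isotropic Gaussian. The
#' result (\code{h_eff}) is the direct-space kernel that effectively blurs
#' the auto-correlation-average reconstruction; for more than one view it is
#' sharper than the direct-space average \code{hbar} because the cross-terms
#' between views are absent from \code{Hbar}. The output is re-centred on its
#' centroid and normalized to unit sum.
#'
#' @param Hbar a non-negative \linkS4class{LagVolume}.
#' @param nIter Schulz-Snyder iteration budget.
#' @param initSigma standard deviation (voxels) of the Gaussian initial
#'   guess.
#' @param voxelPitch micrometres per voxel for the returned kernel.
#' @return a unit-sum \linkS4class{ObjectVolume}.
#' @export
effectivePSF <- function(Hbar, nIter = 3000L, initSigma = 2,
                         voxelPitch = c(1, 1, 1)) {
  if (length(voxelPitch) == 1L) voxelPitch <- rep(voxelPitch, 3L)
  d <- dim(Hbar@data)
  ctr <- floor(d / 2) + 1
  z <- seq_len(d[1]) - ctr[1]
  y <- seq_len(d[2]) - ctr[2]
  x <- seq_len(d[3]) - ctr[3]
  g <- exp(-0.5 * outer(outer(z^2, y^2, "+"), x^2, "+") / initSigma^2)
  init <- ObjectVolume(g / sum(g), voxelPitch)
  chi <- sanitizeAcorr(Hbar)
  res <- solveAcorr(chi, "SS", init = init, nIter = nIter)
  arr <- res$recon@data
  ## re-centre on the intensity centroid (integer shift)
  w <- sum(arr)
  cz <- sum(arr * slice.index(arr, 1)) / w
  cy <- sum(arr * slice.index(arr, 2)) / w
  cx <- sum(arr * slice.index(arr, 3)) / w
  sh <- round(ctr - c(cz, cy, cx))
  arr <- .roll(arr, sh)
  ObjectVolume(arr / sum(arr), voxelPitch)
}

#' Full width at half maximum along an axis
#'
#' Measures the FWHM of the 1D profile through the global maximum along the
#' requested axis, locating the half-maximum crossings by linear
#' interpolation between voxels, and converts to micrometres via the voxel
#' pitch.
#'
#' @param v an \linkS4class{ObjectVolume} with a unique global maximum.
#' @param axis 1 (z), 2 (y) or 3 (x).
#' @return width in micrometres.
#' @export
fwhm <- function(v, axis) {
  arr <- v@data
  d <- dim(arr)
  i <- which.max(arr)
  i0 <- i - 1L
  pz <- i0 %% d[1] + 1L
  py <- (i0 %/% d[1]) %% d[2] + 1L
  px <- i0 %/% (d[1] * d[2]) + 1L
  prof <- switch(axis, arr[, py, px], arr[pz, , px], arr[pz, py, ])
  peak_at <- c(pz, py, px)[axis]
  half <- prof[peak_at] / 2
  cross <- function(idx_seq) {
    prev <- peak_at
    for (j in idx_seq) {
      if (prof[j] <= half) {
        ## linear interpolation between prev (above) and j (at/below)
        frac <- (prof[prev] - half) / (prof[prev] - prof[j])
        return(prev + frac * (j - prev))
      }
      prev <- j
    }
    NA_real_
  }
  left <- if (peak_at > 1) cross((peak_at - 1):1) else NA_real_
  right <- if (peak_at < length(prof)) cross((peak_at + 1):length(prof))
           else NA_real_
  if (is.na(left) || is.na(right))
    .stop2("acorrtomo_measurement_error",
           "profile never crosses half maximum on one side")
  (right - left) * v@voxelPitch[axis]
}

#' Interpolated line profile between two voxels
#'
#' Samples the volume at unit-voxel spacing along the segment from
#' \code{start} to \code{end} (1-based voxel coordinates, z/y/x order) with
#' trilinear interpolation.
#'
#' @param v an \linkS4class{ObjectVolume}.
#' @param start,end length-3 voxel coordinates inside the volume.
#' @return a data.frame with \code{position} (micrometres along the segment)
#'   and \code{intensity}.
#' @export
lineProfile <- function(v, start, end) {
  d <- dim(v@data)
  for (p in list(start, end))
    if (any(p < 1) || any(p > d))
      .stop2("acorrtomo_validation_error", "endpoint outside the volume")
  dv <- end - start
  len <- sqrt(sum(dv^2))
  npts <- max(2L, floor(len) + 1L)
  tseq <- seq(0, 1, length.out = npts)
  pitch_step <- sqrt(sum((dv * v@voxelPitch)^2)) / (npts - 1L)
  vals <- vapply(tseq, function(tt) .trilinear(v@data, start + tt * dv),
                 numeric(1))
  data.frame(position = (seq_len(npts) - 1L) * pitch_step, intensity = vals)
}

.trilinear <- function(arr, p) {
  d <- dim(arr)
  p0 <- pmin(pmax(floor(p), 1L), d - 1L)
  p0 <- pmin(p0, pmax(d - 1L, 1L))
  f <- p - p0
  f <- pmin(pmax(f, 0), 1)
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
         (if (dx) f[3] else 1 - f[3])
    if (w > 0) {
      idx <- pmin(p0 + c(dz, dy, dx), d)
      acc <- acc + w * arr[idx[1], idx[2], idx[3]]
    }
  }
  acc
}

#' Shift- and flip-invariant recovery score
#'
#' Maximum zero-mean normalized cross-correlation between a reconstruction
#' and the ground truth over all global circular integer shifts and over the
#' flip ambiguity (de-autocorrelation determines the object only up to a
#' global translation and inversion). Returns a value in [-1, 1]; 1 means
#' the reconstruction is a shifted/possibly flipped copy of the truth.
#'
#' @param recon,truth \linkS4class{ObjectVolume}s of identical shape.
#' @return a scalar in [-1, 1].
#' @export
recoveryScore <- function(recon, truth) {
  .check_same_shape(recon@data, truth@data)
  a <- recon@data - mean(recon@data)
  b <- truth@data - mean(truth@data)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    .stop2("acorrtomo_degenerate_error", "zero-variance input")
  best <- -Inf
  for (flip in c(FALSE, TRUE)) {
    aa <- if (flip) .flip_origin(a) else a
    cc <- .ifft3re(Conj(.fft3(aa)) * .fft3(b))
    best <- max(best, max(cc) / (na * nb))
  }
  best
}

#' Align a reconstruction onto the ground truth
#'
#' Applies the flip/shift combination maximizing the zero-mean normalized
#' cross-correlation (the ambiguity group of de-autocorrelation), returning
#' the aligned reconstruction. Useful before voxel-wise comparison or
#' FWHM measurements at known truth locations.
#'
#' @param recon,truth \linkS4class{ObjectVolume}s of identical shape.
#' @return the aligned \linkS4class{ObjectVolume}.
#' @export
alignToTruth <- function(recon, truth) {
  .check_same_shape(recon@data, truth@data)
  a0 <- recon@data - mean(recon@data)
  b <- truth@data - mean(truth@data)
  best <- NULL; best_v <- -Inf
  for (flip in c(FALSE, TRUE)) {
    aa <- if (flip) .flip_origin(a0) else a0
    cc <- .ifft3re(Conj(.fft3(aa)) * .fft3(b))
    mx <- max(cc)
    if (mx > best_v) {
      best_v <- mx
      i0 <- which.max(cc) - 1L
      d <- dim(cc)
      lag <- c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
      best <- list(flip = flip, lag = lag)
    }
  }
  arr <- if (best$flip) .flip_origin(recon@data) else recon@data
  ## cc peak at lag s means truth equals the flipped recon advanced by +s
  ObjectVolume(.roll(arr, best$lag), recon@voxelPitch)
}
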