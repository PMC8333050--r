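## Exact n-dimensional convolution/correlation algebra. Everything downstream
## (forward model, fusion, solvers) is built on these primitives.
##
## Conventions, fixed once and used everywhere:
##  * (a * b)(x)    = sum_y a(y) b(x - y)            (convolution)
##  * (a star b)(xi) = sum_y a(y) b(y + xi)          (correlation; lag sign)
##  * zero lag lives at floor(dim/2) per axis (0-based) of a LagVolume;
##  * ObjectVolume convolution is "same"-cropped so that a delta at the
##    central voxel is the identity element.

.stop2 <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

.fft3 <- function(x) fft(x)
.ifft3re <- function(X) Re(fft(X, inverse = TRUE)) / length(X)

## circular roll: content moves by +s (voxels) on each axis
.roll_perm <- function(n, s) {
  s <- ((s %% n) + n) %% n
  ((seq_len(n) - 1L - s) %% n) + 1L
}

.roll <- function(arr, s) {
  d <- dim(arr)
  arr[.roll_perm(d[1], s[1]), .roll_perm(d[2], s[2]), .roll_perm(d[3], s[3]),
      drop = FALSE]
}

## origin layout (lag 0 at [1,1,1]) <-> centred layout (lag 0 at floor(n/2))
.center0 <- function(d) floor(d / 2)
.fftshift <- function(arr) .roll(arr, .center0(dim(arr)))
.ifftshift <- function(arr) .roll(arr, -.center0(dim(arr)))

## index map p -> -p (mod n) in origin layout
.flip_origin <- function(arr) {
  d <- dim(arr)
  f <- function(n) if (n == 1L) 1L else c(1L, n:2L)
  arr[f(d[1]), f(d[2]), f(d[3]), drop = FALSE]
}

## circularly shift so the (unique) argmax voxel sits at the origin; makes the
## discrete circular auto-correlation exactly invariant to integer shifts of
## its input (shifted copies reduce to the same representative bitwise)
.canonicalize <- function(arr) {
  i <- which.max(arr)
  d <- dim(arr)
  i0 <- i - 1L
  z <- i0 %% d[1]; rest <- i0 %/% d[1]
  y <- rest %% d[2]; x <- rest %/% d[2]
  .roll(arr, -c(z, y, x))
}

.next_fast <- function(n) nextn(n, c(2, 3, 5))

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    .stop2("acorrtomo_geometry_error",
           "shape mismatch: %s vs %s", paste(dim(a), collapse = "x"),
           paste(dim(b), collapse = "x"))
}

## circular convolution in origin layout
.circ_conv <- function(a, b) .ifft3re(.fft3(a) * .fft3(b))

## linear (zero-padded) full convolution; returns the 2n-1 result per axis
.lin_conv_full <- function(a, b) {
  d <- dim(a)
  m <- vapply(2L * d - 1L, .next_fast, integer(1))
  pa <- array(0, m); pb <- array(0, m)
  pa[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  pb[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- b
  full <- .circ_conv(pa, pb)
  full[seq_len(2L * d[1] - 1L), seq_len(2L * d[2] - 1L),
       seq_len(2L * d[3] - 1L), drop = FALSE]
}

#' Convolve two volumes
#'
#' Spectral convolution \code{a * b}. For \linkS4class{ObjectVolume} inputs the
#' result is cropped to the input geometry such that a Dirac delta at the
#' central voxel \code{floor(dim/2)} is the identity element; with
#' \code{outSize = "full"} in linear-padded mode the uncropped
#' \code{2n - 1}-long result is returned (mass-conserving:
#' \code{sum(a*b) = sum(a) sum(b)}). Linear-padded mode zero-pads each axis to
#' the next fast transform length at or above \code{2n - 1} before spectral
#' multiplication. Commutative in all modes.
#'
#' For \linkS4class{LagVolume} inputs, convolution is performed about the zero
#' lag (a delta at zero lag is the identity) on the common lag grid.
#'
#' @param a,b volumes of identical shape (and class).
#' @param mode \code{"circular"} or \code{"linear-padded"}.
#' @param outSize \code{"same"} (default) or \code{"full"} (linear-padded
#'   ObjectVolume only).
#' @return a volume of the same class as the inputs.
#' @export
setGeneric("convolveVol",
  function(a, b, mode = c("circular", "linear-padded"), outSize = "same")
    standardGeneric("convolveVol"))

#' @rdname convolveVol
#' @export
setMethod("convolveVol", signature("ObjectVolume", "ObjectVolume"),
  function(a, b, mode = c("circular", "linear-padded"), outSize = "same") {
    mode <- match.arg(mode)
    .check_same_shape(a@data, b@data)
    d <- dim(a@data)
    c0 <- .center0(d)
    if (mode == "circular") {
      out <- .roll(.circ_conv(a@data, b@data), -c0)
      return(ObjectVolume(out, a@voxelPitch))
    }
    full <- .lin_conv_full(a@data, b@data)
    if (outSize == "full")
      return(ObjectVolume(full, a@voxelPitch))
    out <- full[c0[1] + seq_len(d[1]), c0[2] + seq_len(d[2]),
                c0[3] + seq_len(d[3]), drop = FALSE]
    ObjectVolume(out, a@voxelPitch)
  })

#' @rdname convolveVol
#' @export
setMethod("convolveVol", signature("LagVolume", "LagVolume"),
  function(a, b, mode = c("circular", "linear-padded"), outSize = "same") {
    mode <- match.arg(mode)
    .check_same_shape(a@data, b@data)
    out <- .fftshift(.circ_conv(.ifftshift(a@data), .ifftshift(b@data)))
    LagVolume(out, mode = a@mode)
  })

#' Correlate two volumes
#'
#' Spectral cross-correlation with the lag convention
#' \code{(a star b)(xi) = sum_y a(y) b(y + xi)}; the zero lag is mapped to the
#' central voxel of the returned \linkS4class{LagVolume}. In linear-padded
#' mode the inputs are zero-padded to the next fast length at or above
#' \code{2n - 1} and the full \code{2n - 1} lag range is returned; in circular
#' mode lags wrap on the input grid.
#'
#' @param a,b \linkS4class{ObjectVolume}s of identical shape.
#' @param mode \code{"circular"} or \code{"linear-padded"}.
#' @return a \linkS4class{LagVolume}.
#' @export
correlateVol <- function(a, b, mode = c("circular", "linear-padded")) {
  mode <- match.arg(mode)
  .check_same_shape(a@data, b@data)
  d <- dim(a@data)
  if (mode == "circular") {
    x <- .ifft3re(Conj(.fft3(a@data)) * .fft3(b@data))
    return(LagVolume(.fftshift(x), mode = mode))
  }
  m <- vapply(2L * d - 1L, .next_fast, integer(1))
  pa <- array(0, m); pb <- array(0, m)
  pa[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a@data
  pb[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- b@data
  x <- .ifft3re(Conj(.fft3(pa)) * .fft3(pb))
  ## extract lags -(n-1) .. (n-1) per axis, centred
  idx <- function(n, mm) ((seq(-(n - 1L), n - 1L) %% mm) + 1L)
  out <- x[idx(d[1], m[1]), idx(d[2], m[2]), idx(d[3], m[3]), drop = FALSE]
  LagVolume(out, mode = mode)
}

#' Auto-correlate a volume
#'
#' Computes \code{A\{a\} = a star a}, the shift-invariant quantity on which
#' multi-view fusion without registration rests. The value at zero lag equals
#' \code{sum(a^2)}; in linear-padded mode the total sum equals
#' \code{sum(a)^2}.
#'
#' In circular mode the input is first canonicalized by circularly shifting
#' its (unique) argmax voxel to the origin, which makes the result exactly --
#' bitwise -- invariant to any integer circular shift of the input (shifted
#' copies reduce to the same array before the FFT). Set
#' \code{canonicalize = FALSE} to skip this. Linear-padded results are
#' shift-invariant by construction and are never canonicalized.
#'
#' @param a an \linkS4class{ObjectVolume}.
#' @param mode \code{"circular"} or \code{"linear-padded"}.
#' @param canonicalize see Details (circular mode only).
#' @return a \linkS4class{LagVolume}, centro-symmetric about its centre.
#' @export
setMethod("autocorrelate", "ObjectVolume",
  function(a, mode = c("circular", "linear-padded"), canonicalize = TRUE) {
    mode <- match.arg(mode)
    d <- dim(a@data)
    if (mode == "circular") {
      arr <- if (canonicalize) .canonicalize(a@data) else a@data
      x <- .ifft3re(Mod(.fft3(arr))^2)
      return(LagVolume(.fftshift(x), mode = mode))
    }
    m <- vapply(2L * d - 1L, .next_fast, integer(1))
    pa <- array(0, m)
    pa[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a@data
    x <- .ifft3re(Mod(.fft3(pa))^2)
    idx <- function(n, mm) ((seq(-(n - 1L), n - 1L) %% mm) + 1L)
    out <- x[idx(d[1], m[1]), idx(d[2], m[2]), idx(d[3], m[3]), drop = FALSE]
    LagVolume(out, mode = mode)
  })

#' Flip a volume about its centre
#'
#' Returns \code{a~} with \code{a~(x) = a(-x)} about the declared centre
#' (\code{floor(dim/2)} for ObjectVolumes, the zero-lag voxel for LagVolumes),
#' wrapping circularly. This realizes the adjoint appearing in the
#' Schulz-Snyder and Anchor-Update updates; \code{flipVol(flipVol(a)) = a}.
#'
#' @param a an \linkS4class{ObjectVolume} or \linkS4class{LagVolume}.
#' @return a volume of the same class.
#' @rdname flipVol
#' @export
setMethod("flipVol", "ObjectVolume", function(a) {
  ObjectVolume(.fftshift(.flip_origin(.ifftshift(a@data))), a@voxelPitch)
})

#' @rdname flipVol
#' @export
setMethod("flipVol", "LagVolume", function(a) {
  LagVolume(.fftshift(.flip_origin(.ifftshift(a@data))), mode = a@mode)
})

#' Translate a volume
#'
#' Integer shifts are applied as exact circular rolls; fractional shifts by a
#' spectral phase ramp (used to emulate sub-pixel misalignment).
#'
#' @param v an \linkS4class{ObjectVolume}.
#' @param s length-3 shift in voxels (z, y, x); content moves by \code{+s}.
#' @return the shifted \linkS4class{ObjectVolume}.
#' @export
shiftVolume <- function(v, s) {
  if (all(s == round(s)))
    return(ObjectVolume(.roll(v@data, round(s)), v@voxelPitch))
  d <- dim(v@data)
  kf <- function(n) {
    k <- 0:(n - 1L)
    ifelse(k <= n / 2, k, k - n)
  }
  expo <- outer(outer(kf(d[1]) * s[1] / d[1], kf(d[2]) * s[2] / d[2], "+"),
                kf(d[3]) * s[3] / d[3], "+")
  ph <- exp(-2i * pi * expo)
  ObjectVolume(Re(fft(.fft3(v@data) * ph, inverse = TRUE)) / length(v@data),
               v@voxelPitch)
}

#' Embed a small volume at the centre of a larger grid
#'
#' Places the central voxel of \code{small} at the central voxel of the target
#' grid, zero elsewhere. Used to lift rendered PSF kernels onto the view grid
#' before convolution.
#'
#' @param small an \linkS4class{ObjectVolume}.
#' @param shape integer length-3 target shape; must be at least the source
#'   shape on every axis.
#' @return an \linkS4class{ObjectVolume} of dimension \code{shape}.
#' @export
embedVolume <- function(small, shape) {
  d <- dim(small@data)
  shape <- as.integer(shape)
  if (any(shape < d))
    .stop2("acorrtomo_geometry_error",
           "target shape %s smaller than source %s",
           paste(shape, collapse = "x"), paste(d, collapse = "x"))
  out <- array(0, shape)
  off <- .center0(shape) - .center0(d)   # aligns the two central voxels
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
      off[3] + seq_len(d[3])] <- small@data
  ObjectVolume(out, small@voxelPitch)
}
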