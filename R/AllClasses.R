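#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' ObjectVolume: a direct-space 3D intensity volume
#'
#' Container for any direct-space volume handled by the package: an object
#' \code{o}, a single view \code{o_mu}, a point-spread function \code{h}, or a
#' fused/reconstructed volume. The axis order is fixed as (z scan/longitudinal,
#' y transverse, x lateral).
#'
#' @slot data 3D numeric array, axis order (z, y, x). All values finite.
#' @slot voxelPitch numeric length-3, micrometres per voxel along (z, y, x).
#'
#' @examples
#' v <- ObjectVolume(array(runif(27), c(3, 3, 3)))
#' dim(v)
#' @export
setClass("ObjectVolume",
  representation(data = "array", voxelPitch = "numeric"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L)
      return("data must be a 3D array (z, y, x)")
    if (any(dim(d) < 1L))
      return("all axis extents must be strictly positive")
    if (!all(is.finite(d)))
      return("data contains non-finite values")
    if (length(object@voxelPitch) != 3L || any(object@voxelPitch <= 0))
      return("voxelPitch must be three positive lengths (um)")
    TRUE
  }
)

#' @param data 3D numeric array (z, y, x).
#' @param voxelPitch micrometres per voxel along (z, y, x); a scalar is
#'   recycled to all three axes.
#' @rdname ObjectVolume-class
#' @export
ObjectVolume <- function(data, voxelPitch = c(1, 1, 1)) {
  if (is.numeric(data) && is.null(dim(data)))
    data <- array(data, c(length(data), 1L, 1L))
  if (length(dim(data)) == 2L)
    data <- array(data, c(dim(data), 1L))
  if (length(voxelPitch) == 1L) voxelPitch <- rep(voxelPitch, 3L)
  new("ObjectVolume", data = data, voxelPitch = as.numeric(voxelPitch))
}

#' LagVolume: a volume over correlation lags
#'
#' Holds correlation-space quantities (chi, chi_mu, averaged auto-correlations,
#' the auto-correlation-space PSF H and the effective kernel K). Zero lag sits
#' at the central voxel \code{floor(dim/2)} (0-based) of each axis so that the
#' centro-symmetry of real auto-correlations is inspectable by index
#' arithmetic.
#'
#' @slot data 3D numeric array over lags (z, y, x).
#' @slot centerIndex integer length-3, 1-based voxel holding zero lag
#'   (\code{floor(dim/2) + 1}).
#' @slot mode \code{"circular"} or \code{"linear-padded"}.
#' @export
setClass("LagVolume",
  representation(data = "array", centerIndex = "integer", mode = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L)
      return("data must be a 3D array")
    if (!all(is.finite(d)))
      return("data contains non-finite values")
    if (length(object@centerIndex) != 3L)
      return("centerIndex must have length 3")
    if (any(object@centerIndex != floor(dim(d) / 2) + 1L))
      return("centerIndex must be floor(dim/2)+1 on each axis")
    if (!object@mode %in% c("circular", "linear-padded"))
      return("mode must be 'circular' or 'linear-padded'")
    TRUE
  }
)

#' @param data 3D numeric array over lags.
#' @param mode correlation geometry, \code{"circular"} or
#'   \code{"linear-padded"}.
#' @rdname LagVolume-class
#' @export
LagVolume <- function(data, mode = "circular") {
  if (is.numeric(data) && is.null(dim(data)))
    data <- array(data, c(length(data), 1L, 1L))
  new("LagVolume", data = data,
      centerIndex = as.integer(floor(dim(data) / 2) + 1L), mode = mode)
}

#' PSFModel: parametric anisotropic Gaussian point-spread function
#'
#' The light-sheet PSF is modelled as a 3D Gaussian elongated along the
#' scanning (z) axis. Per-view realizations \code{h^{phi_i}} are rendered by
#' rotating the covariance about the transverse (y) axis.
#'
#' @slot sigmaLateral standard deviation along x, micrometres.
#' @slot sigmaTransverse standard deviation along y, micrometres.
#' @slot sigmaScan standard deviation along z (the elongated scan axis),
#'   micrometres; must satisfy \code{sigmaScan >= sigmaLateral}.
#' @slot support integer length-3 kernel extent in voxels per axis (odd).
#' @export
setClass("PSFModel",
  representation(sigmaLateral = "numeric", sigmaTransverse = "numeric",
                 sigmaScan = "numeric", support = "integer"),
  validity = function(object) {
    if (object@sigmaLateral <= 0 || object@sigmaTransverse <= 0 ||
        object@sigmaScan <= 0)
      return("all sigmas must be > 0")
    if (object@sigmaScan < object@sigmaLateral)
      return("sigmaScan must be >= sigmaLateral (axial elongation)")
    if (length(object@support) != 3L || any(object@support < 1L))
      return("support must be three positive voxel counts")
    if (any(object@support %% 2L == 0L))
      return("support must be odd on every axis (centred kernel)")
    TRUE
  }
)

#' @param sigmaLateral,sigmaTransverse,sigmaScan Gaussian standard deviations
#'   in micrometres (x, y, z axes respectively).
#' @param support kernel extent in voxels; default is the smallest odd size
#'   covering 8 standard deviations of the widest axis on z and x (so rotated
#'   realizations fit with little truncation), and of \code{sigmaTransverse}
#'   on y.
#' @param voxelPitch micrometres per voxel used to size the default support.
#' @rdname PSFModel-class
#' @export
PSFModel <- function(sigmaLateral, sigmaTransverse = sigmaLateral, sigmaScan,
                     support = NULL, voxelPitch = c(1, 1, 1)) {
  if (length(voxelPitch) == 1L) voxelPitch <- rep(voxelPitch, 3L)
  if (is.null(support)) {
    oddup <- function(x) { n <- ceiling(x); n + (n %% 2L == 0L) }
    wmax <- max(sigmaScan, sigmaLateral)
    support <- c(oddup(8 * wmax / voxelPitch[1]),
                 oddup(8 * sigmaTransverse / voxelPitch[2]),
                 oddup(8 * wmax / voxelPitch[3]))
  }
  if (length(support) == 1L) support <- rep(support, 3L)
  new("PSFModel", sigmaLateral = sigmaLateral,
      sigmaTransverse = sigmaTransverse, sigmaScan = sigmaScan,
      support = as.integer(support))
}

#' NoiseModel: measurement noise description
#'
#' The noiseless regime (\code{kind = "none"}) corresponds to neglecting the
#' additive term in the forward model; the other kinds exist to stress-test
#' the reconstruction.
#'
#' @slot kind one of \code{"none"}, \code{"gaussian"}, \code{"poisson"},
#'   \code{"poisson+gaussian"}.
#' @slot gaussianSigma additive Gaussian standard deviation, intensity units.
#' @slot photonScale counts per unit intensity for the Poisson component.
#' @slot backgroundLevel constant additive offset, intensity units.
#' @export
setClass("NoiseModel",
  representation(kind = "character", gaussianSigma = "numeric",
                 photonScale = "numeric", backgroundLevel = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("none", "gaussian", "poisson", "poisson+gaussian"))
      return("unknown noise kind")
    if (object@gaussianSigma < 0 || object@photonScale < 0 ||
        object@backgroundLevel < 0)
      return("noise parameters must be non-negative")
    TRUE
  }
)

#' @param kind,gaussianSigma,photonScale,backgroundLevel see slots.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(kind = "none", gaussianSigma = 0, photonScale = 0,
                       backgroundLevel = 0) {
  new("NoiseModel", kind = kind, gaussianSigma = gaussianSigma,
      photonScale = photonScale, backgroundLevel = backgroundLevel)
}

#' ViewSet: an ordered multi-view acquisition
#'
#' Holds the views of one multi-view experiment together with their rotation
#' angles about the transverse (y) axis, the true per-view rigid shifts (known
#' for synthetic data, NA for real data), and the frame the views live in:
#' \code{"acquisition"} (each view in its own rotated frame) or
#' \code{"reference"} (all views rotated back to the 0-degree orientation).
#'
#' @slot views list of \linkS4class{ObjectVolume}, all sharing one shape and
#'   voxel pitch.
#' @slot angles numeric, degrees, strictly increasing in [0, 360).
#' @slot trueShifts N x 3 numeric matrix of per-view shifts in voxels (z,y,x).
#' @slot referenceIndex 1-based position of the reference (0 degree) view.
#' @slot frame \code{"acquisition"} or \code{"reference"}.
#' @export
setClass("ViewSet",
  representation(views = "list", angles = "numeric", trueShifts = "matrix",
                 referenceIndex = "integer", frame = "character"),
  validity = function(object) {
    n <- length(object@views)
    if (n == 0L) return("empty ViewSet")
    if (!all(vapply(object@views, is, logical(1), "ObjectVolume")))
      return("views must all be ObjectVolume")
    dims <- vapply(object@views, function(v) dim(v@data), integer(3))
    if (n > 1L && !all(dims == dims[, 1L]))
      return("all views must share one shape")
    if (length(object@angles) != n)
      return("one angle per view required")
    if (any(object@angles < 0 | object@angles >= 360))
      return("angles must lie in [0, 360)")
    if (n > 1L && any(diff(object@angles) <= 0))
      return("angles must be strictly increasing")
    if (nrow(object@trueShifts) != n || ncol(object@trueShifts) != 3L)
      return("trueShifts must be an N x 3 matrix")
    if (object@referenceIndex < 1L || object@referenceIndex > n)
      return("referenceIndex out of range")
    sh <- object@trueShifts[object@referenceIndex, ]
    if (!all(is.na(sh)) && any(sh != 0))
      return("reference view must carry zero true shift")
    if (!object@frame %in% c("acquisition", "reference"))
      return("frame must be 'acquisition' or 'reference'")
    TRUE
  }
)

#' @param views list of \linkS4class{ObjectVolume}.
#' @param angles rotation angles in degrees.
#' @param trueShifts N x 3 matrix of true shifts (defaults to zeros).
#' @param referenceIndex index of the 0-degree view (default: position of the
#'   smallest angle equal to 0, else 1).
#' @param frame frame of the views.
#' @rdname ViewSet-class
#' @export
ViewSet <- function(views, angles, trueShifts = NULL, referenceIndex = NULL,
                    frame = "reference") {
  n <- length(views)
  if (is.null(trueShifts)) trueShifts <- matrix(0, n, 3)
  if (is.null(referenceIndex)) {
    referenceIndex <- if (any(angles == 0)) which(angles == 0)[1L] else 1L
  }
  new("ViewSet", views = views, angles = as.numeric(angles),
      trueShifts = trueShifts, referenceIndex = as.integer(referenceIndex),
      frame = frame)
}

#' SolverState: state of an iterative de-autocorrelation run
#'
#' @slot iterate the current estimate \code{o^t} (non-negative).
#' @slot kernel effective kernel \code{K^t = o^t (star) H} (Anchor-Update
#'   only; NULL for Schulz-Snyder).
#' @slot t iteration counter.
#' @slot trace data.frame with one row per checkpoint: iteration, I-divergence
#'   between the target and the model, and the iterate mass.
#' @slot mode correlation geometry of the run.
#' @slot scheme \code{"SS"} or \code{"AU"}.
#' @export
setClass("SolverState",
  representation(iterate = "ObjectVolume", kernel = "arrayOrNULL",
                 t = "integer", trace = "data.frame", mode = "character",
                 scheme = "character"),
  validity = function(object) {
    if (any(object@iterate@data < 0))
      return("iterate must be non-negative everywhere")
    if (!object@scheme %in% c("SS", "AU"))
      return("scheme must be 'SS' or 'AU'")
    TRUE
  }
)
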