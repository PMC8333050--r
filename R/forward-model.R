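## Synthetic multi-view light-sheet forward model: phantoms, anisotropic
## Gaussian PSFs, in-plane rotations and the measurement equation
## o_mu = o * h (+ noise).

.with_seed <- function(seed, expr) {
  if (is.null(seed))
    .stop2("acorrtomo_validation_error", "a seed is required (reproducibility)")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic phantom
#'
#' Non-negative test objects with compact support: \code{"bead_field"} (point
#' sources of random position/intensity), \code{"vessel_tree"} (branching
#' random-walk tubes with hollow lumina, emulating labelled vasculature) and
#' \code{"shell"} (a hollow sphere). All kinds keep a zero margin of at least
#' \code{margin} voxels on every face so that blurring and modest shifts do
#' not push signal outside the grid; the generator is deterministic given
#' \code{seed}.
#'
#' @param kind phantom family.
#' @param shape integer length-3 grid shape (z, y, x).
#' @param params named list overriding kind-specific defaults:
#'   \describe{
#'     \item{bead_field}{\code{nBeads} (15), \code{minSep} (5 voxels),
#'       \code{intensityRange} (c(0.5, 1.5)).}
#'     \item{vessel_tree}{\code{nSteps} (120), \code{outerRadius} (3),
#'       \code{wallThickness} (1.4), \code{branchProb} (0.04),
#'       \code{stepSigma} (0.35, direction jitter).}
#'     \item{shell}{\code{radius} (shape/4), \code{thickness} (1.5).}
#'   }
#'   All kinds accept \code{margin} (default 10 voxels).
#' @param seed mandatory integer seed.
#' @param voxelPitch micrometres per voxel.
#' @return an \linkS4class{ObjectVolume}.
#' @export
generatePhantom <- function(kind = c("bead_field", "vessel_tree", "shell"),
                            shape = c(48, 48, 48), params = list(), seed,
                            voxelPitch = c(1, 1, 1)) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  margin <- if (!is.null(params$margin)) params$margin else 10L
  if (any(shape - 2L * margin < 1L))
    .stop2("acorrtomo_geometry_error",
           "margin %d leaves no interior for shape %s", margin,
           paste(shape, collapse = "x"))
  arr <- .with_seed(seed, switch(kind,
    bead_field = .phantom_beads(shape, margin, params),
    vessel_tree = .phantom_vessels(shape, margin, params),
    shell = .phantom_shell(shape, margin, params)))
  ## enforce the declared zero margin exactly
  mask <- array(0, shape)
  i <- lapply(shape, function(n) (margin + 1L):(n - margin))
  mask[i[[1]], i[[2]], i[[3]]] <- 1
  ObjectVolume(arr * mask, voxelPitch)
}

.phantom_beads <- function(shape, margin, params) {
  n_beads <- if (!is.null(params$nBeads)) params$nBeads else 15L
  min_sep <- if (!is.null(params$minSep)) params$minSep else 5
  irange <- if (!is.null(params$intensityRange)) params$intensityRange
            else c(0.5, 1.5)
  arr <- array(0, shape)
  if (n_beads == 0L) return(arr)
  pos <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(pos) < n_beads && tries < 20000L) {
    tries <- tries + 1L
    p <- vapply(shape, function(n)
      sample((margin + 1L):(n - margin), 1L), numeric(1))
    if (nrow(pos) == 0L ||
        min(sqrt(colSums((t(pos) - p)^2))) >= min_sep)
      pos <- rbind(pos, p)
  }
  if (nrow(pos) < n_beads)
    .stop2("acorrtomo_geometry_error",
           "could not place %d beads with separation %g", n_beads, min_sep)
  for (k in seq_len(nrow(pos)))
    arr[pos[k, 1], pos[k, 2], pos[k, 3]] <- runif(1, irange[1], irange[2])
  arr
}

.phantom_vessels <- function(shape, margin, params) {
  n_steps <- if (!is.null(params$nSteps)) params$nSteps else 120L
  r_out <- if (!is.null(params$outerRadius)) params$outerRadius else 3
  wall <- if (!is.null(params$wallThickness)) params$wallThickness else 1.4
  p_branch <- if (!is.null(params$branchProb)) params$branchProb else 0.04
  jitter <- if (!is.null(params$stepSigma)) params$stepSigma else 0.35
  r_in <- max(r_out - wall, 0)
  lo <- rep(margin + 1 + r_out, 3)
  hi <- shape - margin - r_out
  arr <- array(0, shape)
  ## shell-painting stencil: offsets whose radius falls inside the wall
  ro <- ceiling(r_out)
  off <- expand.grid(dz = -ro:ro, dy = -ro:ro, dx = -ro:ro)
  dd <- sqrt(off$dz^2 + off$dy^2 + off$dx^2)
  keep <- dd <= r_out & dd >= r_in
  off <- off[keep, ]
  paint <- function(p) {
    iz <- round(p[1]) + off$dz; iy <- round(p[2]) + off$dy
    ix <- round(p[3]) + off$dx
    ok <- iz >= 1 & iz <= shape[1] & iy >= 1 & iy <= shape[2] &
          ix >= 1 & ix <= shape[3]
    idx <- cbind(iz[ok], iy[ok], ix[ok])
    arr[idx] <<- pmax(arr[idx], 1)
  }
  walk_one <- function(p, dirv, steps) {
    for (s in seq_len(steps)) {
      paint(p)
      dirv <- dirv + rnorm(3, 0, jitter)
      dirv <- dirv / sqrt(sum(dirv^2))
      p2 <- p + dirv
      ## reflect off the allowed interior box
      for (ax in 1:3) {
        if (p2[ax] < lo[ax] || p2[ax] > hi[ax]) {
          dirv[ax] <- -dirv[ax]
          p2[ax] <- p[ax] + dirv[ax]
        }
      }
      p <- pmin(pmax(p2, lo), hi)
      if (runif(1) < p_branch && steps - s > 10) {
        bd <- dirv + rnorm(3, 0, 1)
        bd <- bd / sqrt(sum(bd^2))
        walk_one(p, bd, floor((steps - s) / 2))
      }
    }
  }
  start <- lo + (hi - lo) * runif(3)
  d0 <- rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
  walk_one(start, d0, n_steps)
  arr
}

.phantom_shell <- function(shape, margin, params) {
  radius <- if (!is.null(params$radius)) params$radius
            else min(shape) / 4
  thick <- if (!is.null(params$thickness)) params$thickness else 1.5
  ctr <- (shape + 1) / 2
  z <- seq_len(shape[1]) - ctr[1]
  y <- seq_len(shape[2]) - ctr[2]
  x <- seq_len(shape[3]) - ctr[3]
  r2 <- outer(outer(z^2, y^2, "+"), x^2, "+")
  r <- sqrt(r2)
  arr <- array(0, shape)
  arr[r >= radius - thick / 2 & r <= radius + thick / 2] <- 1
  arr
}

## in-plane (z,x) rotation matrix: positive angle moves content from +x
## toward +z
.rotmat <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2, byrow = TRUE)
}

#' Render an anisotropic Gaussian PSF
#'
#' Samples the Gaussian kernel on the model's support grid and normalizes it
#' to unit sum. The elongated (scan) axis is the z axis rotated by
#' \code{-angle} into the reference frame, i.e. the kernel returned is
#' \code{h^{phi}}, the realization of the system PSF as seen after rotating
#' the view at angle \code{phi} back to the reference orientation.
#'
#' @param model a \linkS4class{PSFModel}.
#' @param angle view angle in degrees about the transverse (y) axis.
#' @param voxelPitch micrometres per voxel (z, y, x).
#' @return a unit-sum \linkS4class{ObjectVolume} kernel.
#' @export
renderPSF <- function(model, angle = 0, voxelPitch = c(1, 1, 1)) {
  if (length(voxelPitch) == 1L) voxelPitch <- rep(voxelPitch, 3L)
  sup <- model@support
  ## 6 sigma must fit: check the rotated in-plane footprint and y
  smax <- max(model@sigmaScan, model@sigmaLateral)
  if (sup[1] * voxelPitch[1] < 6 * smax || sup[3] * voxelPitch[3] < 6 * smax)
    .stop2("acorrtomo_validation_error",
           "support too small to hold 6 sigma of the rotated kernel")
  if (sup[2] * voxelPitch[2] < 6 * model@sigmaTransverse)
    .stop2("acorrtomo_validation_error",
           "support too small to hold 6 sigma on the transverse axis")
  R <- .rotmat(-angle)
  C2 <- R %*% diag(c(model@sigmaScan^2, model@sigmaLateral^2)) %*% t(R)
  P2 <- solve(C2)
  ctr <- (sup + 1) / 2
  z <- (seq_len(sup[1]) - ctr[1]) * voxelPitch[1]
  y <- (seq_len(sup[2]) - ctr[2]) * voxelPitch[2]
  x <- (seq_len(sup[3]) - ctr[3]) * voxelPitch[3]
  ## quadratic form in (z, x), separable Gaussian in y
  qzx <- outer(z^2 * P2[1, 1], x^2 * P2[2, 2], "+") +
         2 * P2[1, 2] * outer(z, x)
  gy <- exp(-0.5 * y^2 / model@sigmaTransverse^2)
  arr <- array(0, sup)
  ezx <- exp(-0.5 * qzx)
  for (j in seq_len(sup[2])) arr[, j, ] <- ezx * gy[j]
  ObjectVolume(arr / sum(arr), voxelPitch)
}

#' Rotate a volume about the transverse (y) axis
#'
#' Inverse-mapping rotation about the grid centre in the (z, x) plane;
#' positive angles move content from +x toward +z. Interpolation is bilinear
#' (\code{order = 1}) or cubic convolution (\code{order = 3}, Catmull-Rom).
#' Voxels mapped from outside the grid are set to zero.
#'
#' @param v an \linkS4class{ObjectVolume}.
#' @param angle degrees.
#' @param order 1 or 3.
#' @return the rotated \linkS4class{ObjectVolume}.
#' @export
rotateVolume <- function(v, angle, order = 3) {
  if (!order %in% c(1, 3))
    .stop2("acorrtomo_validation_error", "order must be 1 or 3")
  if (angle %% 360 == 0) return(v)
  d <- dim(v@data)
  ctr <- (d + 1) / 2
  Rinv <- .rotmat(-angle)
  g <- expand.grid(z = seq_len(d[1]) - ctr[1], x = seq_len(d[3]) - ctr[3])
  src_z <- Rinv[1, 1] * g$z + Rinv[1, 2] * g$x + ctr[1]
  src_x <- Rinv[2, 1] * g$z + Rinv[2, 2] * g$x + ctr[3]
  nzx <- d[1] * d[3]
  ny <- d[2]
  out <- array(0, d)
  acc <- matrix(0, nzx, ny)
  z0 <- floor(src_z); x0 <- floor(src_x)
  fz <- src_z - z0; fx <- src_x - x0
  if (order == 1) {
    taps <- 0:1
    wzf <- cbind(1 - fz, fz)
    wxf <- cbind(1 - fx, fx)
  } else {
    taps <- -1:2
    cubw <- function(f) {
      ## Catmull-Rom (cubic convolution, a = -1/2) weights for offsets -1..2
      cbind(((-0.5 * f + 1) * f - 0.5) * f,
            (1.5 * f - 2.5) * f * f + 1,
            ((-1.5 * f + 2) * f + 0.5) * f,
            (0.5 * f - 0.5) * f * f)
    }
    wzf <- cubw(fz)
    wxf <- cubw(fx)
  }
  ystride <- d[1]
  xstride <- d[1] * d[2]
  yoff <- (seq_len(ny) - 1L) * ystride
  for (iz in seq_along(taps)) {
    zz <- z0 + taps[iz]
    for (ix in seq_along(taps)) {
      xx <- x0 + taps[ix]
      w <- wzf[, iz] * wxf[, ix]
      ok <- zz >= 1 & zz <= d[1] & xx >= 1 & xx <= d[3] & w != 0
      if (!any(ok)) next
      base <- zz[ok] + (xx[ok] - 1L) * xstride
      idx <- outer(base, yoff, "+")
      acc[ok, ] <- acc[ok, ] + w[ok] * v@data[idx]
    }
  }
  ## acc rows run over (z, x) in expand.grid order; scatter back
  for (j in seq_len(ny)) out[, j, ] <- matrix(acc[, j], d[1], d[3])
  ObjectVolume(out, v@voxelPitch)
}

#' Simulate a multi-view acquisition
#'
#' Applies the measurement model \code{o_mu = o * h} per view: the phantom is
#' observed at each angle, blurred by the anisotropic PSF, rigidly shifted to
#' emulate stage misalignment, and optionally corrupted by noise. Two
#' equivalent forward paths are offered: \code{"rotate_psf"} (default) blurs
#' the unrotated phantom with the analytically rotated kernel
#' \code{h^{phi_i}}, producing views directly in the reference frame with no
#' interpolation error; \code{"rotate_object"} rotates the phantom and blurs
#' with the angle-0 kernel, producing views in the acquisition frame (rotate
#' back with \code{\link{preprocessViews}}). The reference (0 degree) view is
#' pinned at zero shift.
#'
#' @param phantom an \linkS4class{ObjectVolume}.
#' @param psfModel a \linkS4class{PSFModel}.
#' @param angles view angles in degrees, strictly increasing in [0, 360).
#' @param shiftLaw \code{NULL} for no shifts, or a list with \code{kind =
#'   "uniform_int"}, \code{max} (voxel radius, default 4) and optional
#'   \code{fractional = TRUE} to add a sub-voxel component.
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed mandatory integer seed.
#' @param path forward path, see Details.
#' @param order rotation interpolation order for \code{"rotate_object"}.
#' @return a \linkS4class{ViewSet} carrying the true shifts.
#' @export
simulateViews <- function(phantom, psfModel, angles, shiftLaw = NULL,
                          noise = NoiseModel("none"), seed,
                          path = c("rotate_psf", "rotate_object"), order = 3) {
  path <- match.arg(path)
  n <- length(angles)
  ref <- if (any(angles == 0)) which(angles == 0)[1L] else 1L
  .with_seed(seed, {
    shifts <- matrix(0, n, 3)
    if (!is.null(shiftLaw)) {
      mx <- if (!is.null(shiftLaw$max)) shiftLaw$max else 4
      shifts <- matrix(sample(seq(-mx, mx), 3L * n, replace = TRUE), n, 3)
      if (isTRUE(shiftLaw$fractional))
        shifts <- shifts + matrix(runif(3L * n, -0.5, 0.5), n, 3)
      shifts[ref, ] <- 0
    }
    h0 <- if (path == "rotate_object")
      embedVolume(renderPSF(psfModel, 0, phantom@voxelPitch), dim(phantom))
    else NULL
    views <- vector("list", n)
    for (i in seq_len(n)) {
      if (path == "rotate_psf") {
        hi <- embedVolume(renderPSF(psfModel, angles[i], phantom@voxelPitch),
                          dim(phantom))
        vi <- convolveVol(phantom, hi, mode = "circular")
      } else {
        rot <- rotateVolume(phantom, angles[i], order)
        vi <- convolveVol(rot, h0, mode = "circular")
      }
      if (any(shifts[i, ] != 0)) vi <- shiftVolume(vi, shifts[i, ])
      views[[i]] <- .apply_noise(vi, noise)
    }
    ViewSet(views, angles, trueShifts = shifts, referenceIndex = ref,
            frame = if (path == "rotate_psf") "reference" else "acquisition")
  })
}

.apply_noise <- function(v, noise) {
  if (noise@kind == "none" && noise@backgroundLevel == 0) return(v)
  arr <- v@data + noise@backgroundLevel
  if (noise@kind %in% c("poisson", "poisson+gaussian") &&
      noise@photonScale > 0) {
    arr <- rpois(length(arr), pmax(arr, 0) * noise@photonScale) /
      noise@photonScale
    arr <- array(arr, dim(v@data))
  }
  if (noise@kind %in% c("gaussian", "poisson+gaussian") &&
      noise@gaussianSigma > 0)
    arr <- arr + array(rnorm(length(arr), 0, noise@gaussianSigma), dim(arr))
  ObjectVolume(arr, v@voxelPitch)
}
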