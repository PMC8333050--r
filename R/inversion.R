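## De-autocorrelation solvers: Schulz-Snyder (SS) fixed-point iterations for
## chi = o (star) o, and the Anchor-Update (AU) scheme for simultaneous
## de-autocorrelation and deconvolution of chi = (o star o) * H, with the
## effective kernel K^t = o^t (star) H re-derived at every step.
##
## Normalization. The multiplicative updates are divided by the constant
## 2*sqrt(sum(chi)) (SS) and sqrt(sum(chi)*sum(H)) (AU): the object mass
## implied by the model (sum(chi) = sum(o)^2 * sum(H)). A per-iterate
## normalizer 2*sum(o^t) leaves the exact solution fixed but makes the pure
## scale direction oscillate with period 2 (c -> 1/c), destroying the descent
## property; the constant-mass normalizer keeps the exact solution a fixed
## point AND corrects any scale error in a single step.

.as_lag_array <- function(x) {
  if (is(x, "LagVolume")) x@data else x
}

#' Csiszar I-divergence between a target and a model auto-correlation
#'
#' \code{sum(chi * log(chi / model) - chi + model)} with \code{0 log 0 = 0}
#' and the model floored at \code{epsDiv * max(model)}. Non-negative, zero iff
#' the arrays agree almost everywhere. This is the objective the
#' Schulz-Snyder-type multiplicative iterations minimize.
#'
#' @param chi,model non-negative \linkS4class{LagVolume}s or arrays of equal
#'   shape.
#' @param epsDiv relative floor applied to the model.
#' @return a scalar.
#' @export
iDivergence <- function(chi, model, epsDiv = 1e-12) {
  chi <- pmax(.as_lag_array(chi), 0)
  model <- .as_lag_array(model)
  m <- pmax(model, epsDiv * max(model))
  sum(ifelse(chi > 0, chi * log(chi / m), 0) - chi + model)
}

## one SS update on raw origin-layout arrays; returns the new iterate and the
## model of the *incoming* iterate
.ss_update <- function(o, chi, mass, eps_div, bracket) {
  FO <- .fft3(o)
  model <- .ifft3re(Mod(FO)^2)
  r <- chi / pmax(model, eps_div * max(model))
  FR <- .fft3(r)
  if (bracket == "classic") {
    ## r~ * o and r (star) o coincide identically under the lag convention;
    ## the bracket is twice the ratio correlation
    t2 <- .ifft3re(Conj(FR) * FO)
    o_new <- o * t2 / mass
  } else {
    ## as printed: (chi/m) * o~  +  (chi/m) (star) o; the first term is the
    ## flip of the second, symmetrizing the update between o and its mirror
    t1 <- .ifft3re(FR * Conj(FO))
    o_new <- o * (t1 + .flip_origin(t1)) / (2 * mass)
  }
  list(o = pmax(o_new, 0), model = model)
}

## one AU update; FH is the precomputed spectrum of H (origin layout)
.au_update <- function(o, chi, FH, mass, eps_div) {
  FO <- .fft3(o)
  FK <- Conj(FO) * FH            # K^t = o^t (star) H, re-derived every step
  model <- .ifft3re(FO * FK)     # o^t * K^t
  r <- chi / pmax(model, eps_div * max(model))
  term <- .ifft3re(.fft3(r) * Conj(FK))   # (chi / model) * K~^t
  list(o = pmax(o * term / mass, 0), model = model, FK = FK)
}

## spectral round-off may leave ~ -1e-16 values in otherwise non-negative
## volumes; the multiplicative updates require true non-negativity, so tiny
## negatives are clamped here (and only here) while real negatives error out
.clamp_nonneg <- function(x, what) {
  mn <- min(x)
  if (mn < 0) {
    if (mn < -1e-10 * max(abs(x)))
      .stop2("acorrtomo_validation_error",
             "%s must be non-negative (sanitize it first)", what)
    x[x < 0] <- 0
  }
  x
}

.check_solver_inputs <- function(chi, o) {
  if (sum(o) <= 0)
    .stop2("acorrtomo_degenerate_error", "init has zero total mass")
}

#' One Schulz-Snyder iteration
#'
#' Applies a single multiplicative update
#' \code{o <- o [ (chi/m)~ * o + (chi/m) (star) o ] / (2 sqrt(sum(chi)))}
#' with \code{m = o (star) o}, preserving non-negativity and leaving any
#' exact solution unchanged. \code{bracket = "printed"} uses the variant with
#' \code{o~} in the first term (the flip-symmetrized update), which does not
#' guarantee monotone I-divergence.
#'
#' @param state a \linkS4class{SolverState}.
#' @param chiTarget the target \linkS4class{LagVolume} (non-negative).
#' @param epsDiv relative denominator floor.
#' @param bracket \code{"classic"} or \code{"printed"}.
#' @return the advanced \linkS4class{SolverState}.
#' @export
ssStep <- function(state, chiTarget, epsDiv = 1e-12, bracket = "classic") {
  chi <- .clamp_nonneg(.ifftshift(chiTarget@data), "chi_target")
  o <- .clamp_nonneg(state@iterate@data, "iterate")
  .check_solver_inputs(chi, o)
  mass <- sqrt(sum(chi))
  up <- .ss_update(o, chi, mass, epsDiv, bracket)
  d <- iDivergence(chi, up$model, epsDiv)
  new("SolverState", iterate = ObjectVolume(up$o, state@iterate@voxelPitch),
      kernel = NULL, t = state@t + 1L,
      trace = rbind(state@trace,
                    data.frame(iteration = state@t, idiv = d,
                               mass = sum(o))),
      mode = state@mode, scheme = "SS")
}

#' One Anchor-Update iteration
#'
#' Re-derives the effective kernel \code{K^t = o^t (star) H}, then applies
#' \code{o <- o [ (chi / (o * K^t)) * K~^t ] / sqrt(sum(chi) sum(H))}.
#' Preserves non-negativity; any pair (o, H) satisfying
#' \code{chi = (o star o) * H} is a fixed point.
#'
#' @param state a \linkS4class{SolverState}.
#' @param chiTarget the target \linkS4class{LagVolume}.
#' @param H the auto-correlation-space PSF \linkS4class{LagVolume}
#'   (non-negative, unit sum for unit-sum direct-space PSFs).
#' @param epsDiv relative denominator floor.
#' @return the advanced \linkS4class{SolverState} (with the kernel slot
#'   holding \code{K^t} in centred layout).
#' @export
auStep <- function(state, chiTarget, H, epsDiv = 1e-12) {
  chi <- .clamp_nonneg(.ifftshift(chiTarget@data), "chi_target")
  Ha <- .clamp_nonneg(.ifftshift(H@data), "H")
  o <- .clamp_nonneg(state@iterate@data, "iterate")
  .check_solver_inputs(chi, o)
  mass <- sqrt(sum(chi) * sum(Ha))
  up <- .au_update(o, chi, .fft3(Ha), mass, epsDiv)
  d <- iDivergence(chi, up$model, epsDiv)
  K <- .fftshift(.ifft3re(up$FK))
  new("SolverState", iterate = ObjectVolume(up$o, state@iterate@voxelPitch),
      kernel = K, t = state@t + 1L,
      trace = rbind(state@trace,
                    data.frame(iteration = state@t, idiv = d,
                               mass = sum(o))),
      mode = state@mode, scheme = "AU")
}

#' Invert an auto-correlation
#'
#' Runs Schulz-Snyder (scheme \code{"SS"}) or Anchor-Update (scheme
#' \code{"AU"}) iterations on \code{chiTarget}. The iterate lives on the lag
#' grid of \code{chiTarget}; a smaller \code{init} (e.g. the reference view on
#' an unpadded grid, or any close guess) is embedded at the centre. The
#' solvers are deterministic; the iteration count is the only parameter that
#' must be chosen. The solution is defined up to a global shift and flip.
#'
#' @param chiTarget target \linkS4class{LagVolume} (non-negative; use
#'   \code{\link{fuseAcorr}} output).
#' @param scheme \code{"SS"} or \code{"AU"}.
#' @param H auto-correlation-space PSF (\linkS4class{LagVolume}), AU only.
#' @param init initial guess \linkS4class{ObjectVolume}; typically the
#'   reference view or the aligned mean.
#' @param nIter iteration budget.
#' @param checkpointEvery trace/validity cadence in iterations.
#' @param tol optional early stop: relative I-divergence change per
#'   checkpoint window below \code{tol}; \code{NULL} (default) runs the full
#'   budget.
#' @param epsDiv relative denominator floor.
#' @param bracket SS bracket variant, see \code{\link{ssStep}}.
#' @return a list with \code{recon} (the final \linkS4class{ObjectVolume})
#'   and \code{state} (the full \linkS4class{SolverState} with trace).
#' @export
solveAcorr <- function(chiTarget, scheme = c("SS", "AU"), H = NULL, init,
                       nIter = 5000L, checkpointEvery = 100L, tol = NULL,
                       epsDiv = 1e-12, bracket = "classic") {
  scheme <- match.arg(scheme)
  dgrid <- dim(chiTarget@data)
  if (!identical(dim(init@data), dgrid)) init <- embedVolume(init, dgrid)
  chi <- .clamp_nonneg(.ifftshift(chiTarget@data), "chi_target")
  o <- .clamp_nonneg(init@data, "init")
  .check_solver_inputs(chi, o)
  tr <- data.frame(iteration = integer(0), idiv = numeric(0),
                   mass = numeric(0))
  if (scheme == "AU") {
    if (is.null(H))
      .stop2("acorrtomo_validation_error", "AU requires the H kernel")
    if (!identical(dim(H@data), dgrid))
      .stop2("acorrtomo_geometry_error", "H grid must match chi grid")
    Ha <- .clamp_nonneg(.ifftshift(H@data), "H")
    FH <- .fft3(Ha)
    mass <- sqrt(sum(chi) * sum(Ha))
  } else {
    mass <- sqrt(sum(chi))
  }
  last_d <- Inf
  t_done <- 0L
  if (nIter >= 1L) for (t in seq_len(nIter)) {
    up <- if (scheme == "SS") .ss_update(o, chi, mass, epsDiv, bracket)
          else .au_update(o, chi, FH, mass, epsDiv)
    ckpt <- ((t - 1L) %% checkpointEvery == 0L)
    if (ckpt) {
      d <- iDivergence(chi, up$model, epsDiv)
      tr <- rbind(tr, data.frame(iteration = t - 1L, idiv = d,
                                 mass = sum(o)))
      if (!all(is.finite(up$o)))
        .stop2("acorrtomo_numerical_error",
               "non-finite values at iteration %d", t)
      if (!is.null(tol) && is.finite(last_d) &&
          abs(last_d - d) < tol * max(abs(last_d), .Machine$double.eps)) {
        o <- up$o; t_done <- t; break
      }
      last_d <- d
    }
    o <- up$o
    t_done <- t
  }
  ## final checkpoint on the returned iterate
  FOf <- .fft3(o)
  model_f <- if (scheme == "SS") .ifft3re(Mod(FOf)^2)
             else .ifft3re(FOf * Conj(FOf) * FH)
  tr <- rbind(tr, data.frame(iteration = t_done,
                             idiv = iDivergence(chi, model_f, epsDiv),
                             mass = sum(o)))
  state <- new("SolverState",
               iterate = ObjectVolume(o, init@voxelPitch),
               kernel = if (scheme == "AU")
                 .fftshift(.ifft3re(Conj(FOf) * FH)) else NULL,
               t = t_done, trace = tr, mode = chiTarget@mode, scheme = scheme)
  list(recon = state@iterate, state = state)
}

#' Build a fresh SolverState
#'
#' @param init initial \linkS4class{ObjectVolume}.
#' @param scheme \code{"SS"} or \code{"AU"}.
#' @param mode correlation geometry label.
#' @return a \linkS4class{SolverState} at t = 0.
#' @export
newSolverState <- function(init, scheme = "SS", mode = "circular") {
  new("SolverState", iterate = init, kernel = NULL, t = 0L,
      trace = data.frame(iteration = integer(0), idiv = numeric(0),
                         mass = numeric(0)),
      mode = mode, scheme = scheme)
}

#' Write a solver trace as a plain-text table
#'
#' @param state a \linkS4class{SolverState}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTrace <- function(state, path) {
  utils::write.csv(state@trace, path, row.names = FALSE)
  invisible(path)
}
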