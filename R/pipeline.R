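## Experiment drivers tying the modules into the full pipeline
## (simulate -> pre-process -> fuse -> invert -> report), plus the YAML
## configuration surface used by the command-line script.

.config_defaults <- list(
  phantom = list(kind = "bead_field", shape = c(48L, 48L, 48L),
                 margin = 10L, params = list()),
  psf = list(sigma_lateral = 1.0, sigma_transverse = 1.0, sigma_scan = 3.0),
  views = list(angle_step = 30, n_views = NULL),
  shift = list(max = 4L, fractional = FALSE, enabled = TRUE),
  noise = list(kind = "none", gaussian_sigma = 0, photon_scale = 0,
               background_level = 0),
  voxel_pitch_um = c(1, 1, 1),
  seed = NULL,
  solver = list(n_iter = 5000L, checkpoint_every = 100L, mode = "circular",
                eps_div = 1e-12, init = "reference")
)

.merge_config <- function(user, defaults = .config_defaults, path = "") {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0)
    .stop2("acorrtomo_validation_error",
           "unknown config key(s): %s",
           paste0(path, bad, collapse = ", "))
  out <- defaults
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "params") {
      out[[k]] <- .merge_config(user[[k]], defaults[[k]],
                                paste0(path, k, "."))
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, validates keys against the schema, and fills
#' unset values with package defaults. Unknown keys raise a validation error
#' listing the offenders; a seed is mandatory for simulation.
#'
#' @param path YAML file path, or a named list already parsed.
#' @return the fully resolved configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  .merge_config(user)
}

.config_angles <- function(cfg) {
  if (!is.null(cfg$views$n_views))
    seq(0, 360 - 360 / cfg$views$n_views, length.out = cfg$views$n_views)
  else seq(0, 360 - cfg$views$angle_step, by = cfg$views$angle_step)
}

.config_psf <- function(cfg) {
  PSFModel(sigmaLateral = cfg$psf$sigma_lateral,
           sigmaTransverse = cfg$psf$sigma_transverse,
           sigmaScan = cfg$psf$sigma_scan,
           voxelPitch = cfg$voxel_pitch_um)
}

#' Simulate a multi-view experiment to disk
#'
#' Generates the configured phantom, simulates the multi-view acquisition and
#' writes per-angle TIFF stacks, sidecar metadata, the ground-truth phantom
#' and the fully resolved configuration into \code{outDir}.
#'
#' @param config path to a YAML configuration or a named list; a seed is
#'   mandatory.
#' @param outDir output directory.
#' @return the \linkS4class{ViewSet}, invisibly.
#' @export
cmdSimulate <- function(config, outDir) {
  cfg <- readPipelineConfig(config)
  if (is.null(cfg$seed))
    .stop2("acorrtomo_validation_error",
           "config must set a seed for simulation")
  phantom <- generatePhantom(cfg$phantom$kind, cfg$phantom$shape,
                             c(cfg$phantom$params,
                               list(margin = cfg$phantom$margin)),
                             seed = cfg$seed,
                             voxelPitch = cfg$voxel_pitch_um)
  noise <- NoiseModel(cfg$noise$kind, cfg$noise$gaussian_sigma,
                      cfg$noise$photon_scale, cfg$noise$background_level)
  shift_law <- if (isTRUE(cfg$shift$enabled))
    list(kind = "uniform_int", max = cfg$shift$max,
         fractional = isTRUE(cfg$shift$fractional)) else NULL
  vs <- simulateViews(phantom, .config_psf(cfg), .config_angles(cfg),
                      shiftLaw = shift_law, noise = noise, seed = cfg$seed)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  writeViewSet(vs, outDir, seed = cfg$seed)
  writeVolumeTIFF(phantom, file.path(outDir, "truth.tif"),
                  meta = list(role = "ground_truth"))
  yaml::write_yaml(cfg, file.path(outDir, "config_resolved.yml"))
  invisible(vs)
}

#' Reconstruct a multi-view experiment
#'
#' Reads per-angle stacks from \code{inputDir} and reconstructs with one of
#' the three routes: \code{"direct"} (cross-correlation registration and
#' averaging, the standard baseline), \code{"ss"} (auto-correlation fusion
#' inverted by Schulz-Snyder) or \code{"au"} (fusion inverted by
#' Anchor-Update, additionally deconvolving the auto-correlation-space PSF
#' rendered from the configured PSF parameters). Writes the reconstruction,
#' the solver trace (CSV) and a metrics report into \code{outDir}.
#'
#' @param inputDir directory produced by \code{\link{cmdSimulate}} (or
#'   matching its layout).
#' @param scheme \code{"direct"}, \code{"ss"} or \code{"au"}.
#' @param outDir output directory.
#' @param config configuration (path or list) for solver/PSF options;
#'   defaults are used when NULL.
#' @param registered for \code{scheme = "direct"}: register the views first?
#' @return a list with the reconstruction \linkS4class{ObjectVolume} and,
#'   for the iterative schemes, the \linkS4class{SolverState}.
#' @export
cmdReconstruct <- function(inputDir, scheme = c("direct", "ss", "au"),
                           outDir, config = NULL, registered = TRUE) {
  scheme <- match.arg(scheme)
  cfg <- readPipelineConfig(if (is.null(config)) list() else config)
  vs <- preprocessViews(readViewSet(inputDir))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  mode <- cfg$solver$mode
  state <- NULL
  if (scheme == "direct") {
    recon <- fuseDirect(vs, registered = registered, mode = mode)
  } else {
    chi <- fuseAcorr(vs, mode = mode)
    init <- if (identical(cfg$solver$init, "mean"))
      fuseDirect(vs, registered = FALSE) else referenceView(vs)
    if (scheme == "ss") {
      res <- solveAcorr(chi, "SS", init = init, nIter = cfg$solver$n_iter,
                        checkpointEvery = cfg$solver$checkpoint_every,
                        epsDiv = cfg$solver$eps_div)
    } else {
      if (is.null(cfg$psf))
        .stop2("acorrtomo_validation_error", "AU requires PSF parameters")
      H <- .render_H_on_grid(.config_psf(cfg), viewAngles(vs),
                             dim(chi@data), cfg$voxel_pitch_um, mode)
      res <- solveAcorr(chi, "AU", H = H, init = init,
                        nIter = cfg$solver$n_iter,
                        checkpointEvery = cfg$solver$checkpoint_every,
                        epsDiv = cfg$solver$eps_div)
    }
    recon <- res$recon
    state <- res$state
    writeTrace(state, file.path(outDir, "trace.csv"))
  }
  writeVolumeTIFF(recon, file.path(outDir, sprintf("recon_%s.tif", scheme)),
                  meta = list(scheme = scheme, n_views = nViews(vs),
                              mode = mode))
  yaml::write_yaml(cfg, file.path(outDir, "config_resolved.yml"))
  list(recon = recon, state = state)
}

## render Hbar = mean of A{h^phi_i} directly on the solver lag grid
.render_H_on_grid <- function(psfModel, angles, grid, voxelPitch, mode) {
  acc <- NULL
  for (a in angles) {
    h <- embedVolume(renderPSF(psfModel, a, voxelPitch), grid)
    A <- autocorrelate(h, "circular", canonicalize = FALSE)
    acc <- if (is.null(acc)) A@data else acc + A@data
  }
  LagVolume(pmax(acc / length(angles), 0), mode = mode)
}

#' PSF analysis report
#'
#' Renders the per-view PSFs for the configured angles, builds the
#' direct-space average \code{hbar}, its auto-correlation, the
#' auto-correlation-space average \code{Hbar} and the effective PSF
#' \code{h_eff} recovered by inverting \code{Hbar}, and writes a per-axis
#' FWHM table (CSV) plus the volumes into \code{outDir}.
#'
#' @param config configuration (path or list) with PSF sigmas and angles.
#' @param outDir output directory.
#' @param nIter iteration budget for the effective-PSF inversion.
#' @return the FWHM table, invisibly.
#' @export
cmdPsfReport <- function(config, outDir, nIter = 3000L) {
  cfg <- readPipelineConfig(if (is.null(config)) list() else config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  angles <- .config_angles(cfg)
  fp <- fusePsfAcorr(.config_psf(cfg), angles, cfg$voxel_pitch_um)
  heff <- effectivePSF(fp$Hbar, nIter = nIter,
                       voxelPitch = cfg$voxel_pitch_um)
  axes <- c(z = 1, y = 2, x = 3)
  tab <- data.frame(
    axis = names(axes),
    fwhm_hbar_um = vapply(axes, function(a) fwhm(fp$hbar, a), numeric(1)),
    fwhm_heff_um = vapply(axes, function(a) fwhm(heff, a), numeric(1)))
  utils::write.csv(tab, file.path(outDir, "psf_fwhm.csv"), row.names = FALSE)
  writeVolumeTIFF(fp$hbar, file.path(outDir, "hbar.tif"))
  writeVolumeTIFF(heff, file.path(outDir, "h_eff.tif"))
  writeVolumeTIFF(ObjectVolume(fp$Hbar@data, cfg$voxel_pitch_um),
                  file.path(outDir, "Hbar.tif"))
  writeVolumeTIFF(ObjectVolume(fp$Ahbar@data, cfg$voxel_pitch_um),
                  file.path(outDir, "A_hbar.tif"))
  yaml::write_yaml(cfg, file.path(outDir, "config_resolved.yml"))
  invisible(tab)
}
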