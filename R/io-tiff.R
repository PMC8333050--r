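## Multi-page TIFF I/O (page = z, row = y, col = x, 32-bit float samples)
## with plain-text YAML sidecars. Sample values are stored normalized to
## [0, 1] with the scale recorded in the sidecar and restored on read.

#' Write a volume as a multi-page TIFF with sidecar metadata
#'
#' @param v an \linkS4class{ObjectVolume}.
#' @param path output TIFF path; the sidecar is written next to it with a
#'   \code{.yml} extension.
#' @param meta named list of extra metadata stored in the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeVolumeTIFF <- function(v, path, meta = list()) {
  arr <- v@data
  lo <- min(arr)
  scale <- max(arr - lo)
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(i) (arr[i, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(shape = as.integer(dim(arr)),
                 voxel_pitch_um = as.numeric(v@voxelPitch),
                 intensity_offset = lo, intensity_scale = scale), meta)
  yaml::write_yaml(side, .sidecar_path(path))
  invisible(path)
}

#' Read a volume written by \code{\link{writeVolumeTIFF}}
#'
#' @param path TIFF path.
#' @return a list with \code{volume} (\linkS4class{ObjectVolume}) and
#'   \code{meta} (the sidecar contents).
#' @export
readVolumeTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(.sidecar_path(path))
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr <- arr * meta$intensity_scale + meta$intensity_offset
  list(volume = ObjectVolume(arr, unlist(meta$voxel_pitch_um)), meta = meta)
}

.sidecar_path <- function(path) sub("\\.tiff?$", ".yml", path)

#' Write a ViewSet as per-angle TIFF stacks
#'
#' One multi-page TIFF per rotation angle plus a sidecar recording the angle,
#' voxel pitch, true shift, frame and seed.
#'
#' @param views a \linkS4class{ViewSet}.
#' @param dir output directory (created if missing).
#' @param seed the generator seed recorded in each sidecar.
#' @return the vector of TIFF paths, invisibly.
#' @export
writeViewSet <- function(views, dir, seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(views@views))
  for (i in seq_along(views@views)) {
    p <- file.path(dir, sprintf("view_%03d.tif", i))
    writeVolumeTIFF(views@views[[i]], p,
                    meta = list(angle_deg = views@angles[i],
                                true_shift = as.numeric(views@trueShifts[i, ]),
                                frame = views@frame,
                                reference_index = views@referenceIndex,
                                seed = seed))
    paths[i] <- p
  }
  invisible(paths)
}

#' Read a ViewSet written by \code{\link{writeViewSet}}
#'
#' @param dir directory holding \code{view_*.tif} stacks and sidecars.
#' @return a \linkS4class{ViewSet}.
#' @export
readViewSet <- function(dir) {
  files <- sort(list.files(dir, pattern = "^view_\\d+\\.tiff?$",
                           full.names = TRUE))
  if (length(files) == 0L)
    .stop2("acorrtomo_validation_error", "no view_*.tif stacks in %s", dir)
  vols <- lapply(files, readVolumeTIFF)
  views <- lapply(vols, `[[`, "volume")
  metas <- lapply(vols, `[[`, "meta")
  angles <- vapply(metas, function(m) as.numeric(m$angle_deg), numeric(1))
  shifts <- do.call(rbind, lapply(metas, function(m)
    as.numeric(unlist(m$true_shift))))
  ViewSet(views, angles, trueShifts = shifts,
          referenceIndex = as.integer(metas[[1]]$reference_index),
          frame = metas[[1]]$frame)
}
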