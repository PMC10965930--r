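# NIfTI-1 and sidecar I/O for volumes, multi-echo data and atlases.

#' Write a 3D/4D volume as NIfTI-1
#'
#' @param vol Numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size recorded in the header.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol * 1, pixdim = voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#' @param path Input path.
#' @return List with `data` (array) and `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- attr(RNifti::niftiHeader(img), "pixdim") %||%
    RNifti::pixdim(img)
  list(data = as.array(img), voxel_size_mm = as.numeric(vox)[1:3])
}

#' Write multi-echo GRE data as 4D NIfTI plus a JSON sidecar
#'
#' Magnitude and phase go to `<stem>_mag.nii.gz` / `<stem>_phase.nii.gz`;
#' echo times, field strength and B0 direction go to `<stem>_meta.json`.
#'
#' @param gre A `multi_echo_gre`.
#' @param stem Output path stem.
#' @return The sidecar path, invisibly.
#' @export
write_gre <- function(gre, stem) {
  stopifnot(inherits(gre, "multi_echo_gre"))
  write_volume(gre$magnitude, paste0(stem, "_mag.nii.gz"),
               gre$voxel_size_mm)
  write_volume(gre$phase, paste0(stem, "_phase.nii.gz"), gre$voxel_size_mm)
  meta <- list(te_ms = gre$te_ms, b0_tesla = gre$b0_tesla,
               b0_direction = gre$b0_direction,
               gamma_mhz_per_t = gre$gamma_mhz_per_t,
               voxel_size_mm = gre$voxel_size_mm)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, "_meta.json"))
}

#' Read multi-echo GRE data written by [write_gre()]
#' @param stem Path stem used when writing.
#' @return A `multi_echo_gre`.
#' @export
read_gre <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  mag <- read_volume(paste0(stem, "_mag.nii.gz"))
  phs <- read_volume(paste0(stem, "_phase.nii.gz"))
  structure(list(magnitude = mag$data, phase = phs$data,
                 te_ms = meta$te_ms, voxel_size_mm = meta$voxel_size_mm,
                 b0_tesla = meta$b0_tesla, b0_direction = meta$b0_direction,
                 gamma_mhz_per_t = meta$gamma_mhz_per_t),
            class = "multi_echo_gre")
}

#' Write a VOI atlas as integer NIfTI plus a JSON label map
#' @param atlas A [voi_atlas()].
#' @param stem Output path stem.
#' @return The label-map path, invisibly.
#' @export
write_atlas <- function(atlas, stem) {
  stopifnot(inherits(atlas, "voi_atlas"))
  write_volume(atlas$labels, paste0(stem, ".nii.gz"), atlas$voxel_size_mm)
  jsonlite::write_json(atlas$label_map, paste0(stem, "_labels.json"),
                       digits = NA)
  invisible(paste0(stem, "_labels.json"))
}

#' Read a VOI atlas written by [write_atlas()]
#' @param stem Path stem used when writing.
#' @return A [voi_atlas()].
#' @export
read_atlas <- function(stem) {
  vol <- read_volume(paste0(stem, ".nii.gz"))
  lm <- jsonlite::read_json(paste0(stem, "_labels.json"),
                            simplifyVector = TRUE)
  voi_atlas(array(as.integer(round(vol$data)), dim(vol$data)), lm,
            vol$voxel_size_mm)
}
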