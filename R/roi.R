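# Volume-of-interest measurement: per-structure mean susceptibility over a
# 2-pixel in-plane-eroded VOI (partial-volume control) and volume from the
# uneroded voxel count, each computed per hemisphere then averaged.

#' The ten subcortical structures
#' @return Character vector of structure names.
#' @export
subcortical_structures <- function() {
  c("red nucleus", "substantia nigra", "caudate", "putamen", "thalamus",
    "hippocampus", "nucleus accumbens", "amygdala",
    "globus pallidus externa", "globus pallidus interna")
}

#' Labeled volume-of-interest atlas
#'
#' @param labels Integer 3D array; 0 is background.
#' @param label_map Data frame with columns `label` (integer), `structure`,
#'   `hemisphere` (`"left"`/`"right"`).
#' @param voxel_size_mm Numeric length-3 voxel size (mm).
#' @return A `voi_atlas` list.
#' @export
voi_atlas <- function(labels, label_map, voxel_size_mm) {
  stopifnot(length(dim(labels)) == 3,
            all(c("label", "structure", "hemisphere") %in% names(label_map)))
  if (anyDuplicated(label_map$label)) stop("duplicate integer labels")
  present <- unique(as.integer(labels[labels > 0]))
  if (!all(present %in% label_map$label))
    stop("labels present in the volume but missing from label_map: ",
         paste(setdiff(present, label_map$label), collapse = ", "))
  structure(list(labels = labels, label_map = label_map,
                 voxel_size_mm = voxel_size_mm),
            class = "voi_atlas")
}

# 2D binary erosion of one slice, cross (4-connected) or full 3x3
# (8-connected) structuring element, zero-padded borders.
erode_slice <- function(m, connectivity = 4) {
  shift <- function(x, dx, dy) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    xi <- seq_len(nrow(x)) - dx
    yi <- seq_len(ncol(x)) - dy
    ok_x <- xi >= 1 & xi <= nrow(x)
    ok_y <- yi >= 1 & yi <= ncol(x)
    out[ok_x, ok_y] <- x[xi[ok_x], yi[ok_y], drop = FALSE]
    out
  }
  e <- m & shift(m, 1, 0) & shift(m, -1, 0) & shift(m, 0, 1) & shift(m, 0, -1)
  if (connectivity == 8)
    e <- e & shift(m, 1, 1) & shift(m, 1, -1) & shift(m, -1, 1) &
      shift(m, -1, -1)
  e
}

#' In-plane erosion of a structure's VOI
#'
#' Erodes the named structure's mask by `n_pixels` iterations of 1-pixel 2D
#' binary erosion applied independently to each axial (fixed-z) slice, using
#' a 4-connected cross structuring element by default.  Slices are eroded
#' in-plane only, so a structure spanning few slices is not thinned along z.
#'
#' @param atlas A [voi_atlas()].
#' @param structure Structure name present in the atlas.
#' @param n_pixels Erosion iterations per slice (default 2).
#' @param connectivity 4 (cross) or 8 (full 3x3 square).
#' @return Logical 3D array covering both hemispheres after erosion.
#' @export
erode_voi_inplane <- function(atlas, structure, n_pixels = 2,
                              connectivity = 4) {
  stopifnot(inherits(atlas, "voi_atlas"), connectivity %in% c(4, 8),
            n_pixels >= 0)
  labs <- atlas$label_map$label[atlas$label_map$structure == structure]
  if (!length(labs)) stop("structure not present in atlas: ", structure)
  m <- array(atlas$labels %in% labs, dim(atlas$labels))
  for (k in seq_len(n_pixels)) {
    for (z in seq_len(dim(m)[3])) {
      if (any(m[, , z])) m[, , z] <- erode_slice(m[, , z], connectivity)
    }
  }
  if (!any(m))
    stop("eroded VOI empty in both hemispheres for structure: ", structure)
  m
}

#' Per-structure susceptibility and volume measurements
#'
#' For each structure in the atlas: mean susceptibility over the eroded VOI
#' per hemisphere, volume as the uneroded voxel count times the voxel
#' volume per hemisphere, then an unweighted left/right average of each.
#' A hemisphere whose eroded VOI is empty is dropped from the susceptibility
#' average and flagged.
#'
#' @param chi A `susceptibility_map` (see [zero_reference()]) or a plain 3D
#'   array of susceptibility values (ppm).
#' @param atlas A [voi_atlas()] on the same grid.
#' @param erode_px In-plane erosion applied before averaging susceptibility
#'   (default 2 pixels).
#' @param connectivity Structuring-element connectivity for the erosion.
#' @return Data frame with one row per structure: `structure`,
#'   `susceptibility_ppm`, `volume_mm3`, `n_vox_left`, `n_vox_right`
#'   (eroded voxel counts), `flagged`.
#' @export
extract_measurements <- function(chi, atlas, erode_px = 2, connectivity = 4) {
  vol <- if (inherits(chi, "susceptibility_map")) chi$chi_ppm else chi
  stopifnot(inherits(atlas, "voi_atlas"))
  if (!identical(dim(vol), dim(atlas$labels)))
    stop("grid mismatch between susceptibility map and atlas")
  voxvol <- prod(atlas$voxel_size_mm)
  lm <- atlas$label_map
  out <- lapply(unique(lm$structure), function(st) {
    eroded <- erode_voi_inplane(atlas, st, n_pixels = erode_px,
                                connectivity = connectivity)
    sus <- c(); vols <- c(); nv <- c(left = 0L, right = 0L)
    flagged <- FALSE
    for (h in c("left", "right")) {
      labs <- lm$label[lm$structure == st & lm$hemisphere == h]
      if (!length(labs)) { flagged <- TRUE; next }
      full <- array(atlas$labels %in% labs, dim(atlas$labels))
      er <- eroded & full
      nv[h] <- sum(er)
      if (nv[h] >= 1) sus <- c(sus, mean(vol[er])) else flagged <- TRUE
      vols <- c(vols, sum(full) * voxvol)
    }
    data.frame(structure = st, susceptibility_ppm = mean(sus),
               volume_mm3 = mean(vols), n_vox_left = nv[["left"]],
               n_vox_right = nv[["right"]], flagged = flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Batch ROI extraction into a cohort table
#'
#' Applies [extract_measurements()] to each subject and binds the results
#' into the long cohort-table schema shared with [simulate_cohort()].
#' Per-subject failures are reported in the `exclusions` attribute rather
#' than silently dropped.
#'
#' @param subjects List; each element a list with `chi`, `atlas`,
#'   `subject_id`, `group`, and optionally covariate fields (`sex`,
#'   `handedness`, `iq`, `illness_duration_y`, `severity`, `med_dose`).
#' @param erode_px Passed to [extract_measurements()].
#' @return Data frame with columns `subject_id`, `group`, `region`,
#'   `susceptibility_ppm`, `volume_mm3`, `sex`, `handedness`, `iq`,
#'   `illness_duration_y`, `severity`, `med_dose`; attribute `exclusions`
#'   is a data frame of failed subjects and error messages.
#' @export
cohort_extract <- function(subjects, erode_px = 2) {
  stopifnot(length(subjects) >= 1)
  cov_fields <- c("sex", "handedness", "iq", "illness_duration_y",
                  "severity", "med_dose")
  rows <- list(); excl <- list()
  for (s in subjects) {
    res <- tryCatch(extract_measurements(s$chi, s$atlas, erode_px = erode_px),
                    error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = s$subject_id, message = conditionMessage(res),
        stringsAsFactors = FALSE)
      next
    }
    covs <- lapply(cov_fields, function(f) s[[f]] %||% NA)
    names(covs) <- cov_fields
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = s$subject_id, group = s$group, region = res$structure,
      susceptibility_ppm = res$susceptibility_ppm,
      volume_mm3 = res$volume_mm3, covs, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), group = character(),
               region = character(), susceptibility_ppm = numeric(),
               volume_mm3 = numeric())
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), message = character())
  out
}
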