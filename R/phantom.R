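# Digital susceptibility phantom and multi-echo gradient-echo forward model.
#
# The phantom stands in for in-vivo brains: a spherical "brain" of
# susceptibility 0, ellipsoidal subcortical structures with chi spanning the
# range measured in deep grey matter (-0.015 to +0.12 ppm), a CSF-like
# ventricle pair at chi = 0 that anchors the zero reference, and strongly
# paramagnetic sources outside the brain (air-like, 9 ppm) that generate the
# harmonic background field the reconstruction has to remove.

#' Describe one geometric element of a phantom scene
#'
#' @param geometry One of `"sphere"`, `"ellipsoid"`, `"box"`.
#' @param center Voxel coordinates of the centre (1-based, length 3).
#' @param radii Semi-axes in voxels (length 1 for a sphere, else 3).
#' @param chi_ppm Susceptibility of the element (ppm).
#' @param r2star_per_s Effective transverse relaxation rate (1/s).
#' @param structure Subcortical structure name, or `NA` for unlabeled tissue.
#' @param hemisphere `"left"`, `"right"` or `NA`.
#' @param role `"structure"`, `"brain"`, `"ventricle"` or `"background"`.
#' @return A `phantom_shape` list.
#' @export
phantom_shape <- function(geometry = c("sphere", "ellipsoid", "box"),
                          center, radii, chi_ppm = 0, r2star_per_s = 0,
                          structure = NA_character_,
                          hemisphere = NA_character_,
                          role = c("structure", "brain", "ventricle",
                                   "background")) {
  geometry <- match.arg(geometry)
  role <- match.arg(role)
  if (length(radii) == 1) radii <- rep(radii, 3)
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0),
            is.finite(chi_ppm), r2star_per_s >= 0)
  structure(list(geometry = geometry, center = as.numeric(center),
                 radii = as.numeric(radii), chi_ppm = chi_ppm,
                 r2star_per_s = r2star_per_s, structure = structure,
                 hemisphere = hemisphere, role = role),
            class = "phantom_shape")
}

#' Specify a phantom scene
#'
#' @param grid_shape Integer vector of 3 array dimensions (voxels).
#' @param voxel_size_mm Voxel size (mm), length 1 or 3.
#' @param shapes List of [phantom_shape()] elements; exactly the shapes with
#'   `role = "brain"` define the brain mask.
#' @param external_sources List of [phantom_shape()] elements lying entirely
#'   outside the brain mask (background-field generators).
#' @param brain_margin_vox Minimum clearance (voxels) between the brain mask
#'   and the grid edge, required because all spectral operators treat the
#'   grid as periodic.
#' @param seed Integer seed recorded with the spec (rasterisation itself is
#'   deterministic).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, voxel_size_mm = c(1, 1, 1),
                         shapes = list(), external_sources = list(),
                         brain_margin_vox = 8, seed = 1L) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            all(voxel_size_mm > 0), brain_margin_vox >= 0)
  all_shapes <- c(shapes, external_sources)
  for (s in all_shapes) {
    if (!inherits(s, "phantom_shape")) stop("shapes must be phantom_shape objects")
    if (any(s$center < 1) || any(s$center > grid_shape))
      stop("shape centre outside grid: ",
           if (is.na(s$structure)) s$role else s$structure)
  }
  lab <- vapply(shapes, function(s)
    if (is.na(s$structure)) NA_character_
    else paste(s$structure, s$hemisphere, sep = ":"), character(1))
  lab <- lab[!is.na(lab)]
  if (anyDuplicated(lab))
    stop("duplicate structure labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 shapes = shapes, external_sources = external_sources,
                 brain_margin_vox = as.integer(brain_margin_vox),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Logical mask of one shape on the grid.
rasterize_shape <- function(shape, grid_shape) {
  x <- seq_len(grid_shape[1]) - shape$center[1]
  y <- seq_len(grid_shape[2]) - shape$center[2]
  z <- seq_len(grid_shape[3]) - shape$center[3]
  r <- shape$radii
  if (shape$geometry == "box") {
    m <- outer(outer(abs(x) <= r[1], abs(y) <= r[2], `&`), abs(z) <= r[3], `&`)
  } else {
    m <- outer(outer((x / r[1])^2, (y / r[2])^2, `+`), (z / r[3])^2, `+`) <= 1
  }
  array(m, grid_shape)
}

#' Rasterise a phantom scene into ground-truth volumes
#'
#' Paints susceptibility, R2*, brain and ventricle masks, and an integer
#' VOI atlas on the grid.  Labeled structures (and ventricles) must be
#' disjoint and lie inside the brain mask; external sources must lie outside
#' it.
#'
#' @param spec A [phantom_spec()].
#' @return A `qsm_ground_truth` list: `chi_ppm`, `chi_external_ppm`,
#'   `r2star_per_s`, `brain_mask`, `ventricle_mask`, `atlas` (a
#'   [voi_atlas()]), `voxel_size_mm`, `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  chi <- array(0, gs)
  r2s <- array(0, gs)
  labels <- array(0L, gs)
  brain <- array(FALSE, gs)
  vent <- array(FALSE, gs)

  roles <- vapply(spec$shapes, `[[`, character(1), "role")
  # brain first so tissue elements overwrite its chi/R2*
  for (s in spec$shapes[roles == "brain"]) {
    m <- rasterize_shape(s, gs)
    brain <- brain | m
    chi[m] <- s$chi_ppm
    r2s[m] <- s$r2star_per_s
  }
  if (any(brain)) {
    idx <- which(brain, arr.ind = TRUE)
    margin <- min(idx - 1, sweep(-idx, 2, gs, `+`))
    if (margin < spec$brain_margin_vox)
      stop("brain mask closer than brain_margin_vox (", spec$brain_margin_vox,
           ") voxels to the grid edge")
  }

  label_map <- data.frame(label = integer(), structure = character(),
                          hemisphere = character(), stringsAsFactors = FALSE)
  next_label <- 1L
  painted <- array(FALSE, gs)
  for (s in spec$shapes[roles != "brain"]) {
    m <- rasterize_shape(s, gs)
    if (any(m & painted)) {
      coll <- if (is.na(s$structure)) s$role
              else paste(s$structure, s$hemisphere, sep = ":")
      prev <- unique(labels[m & painted])
      prev <- prev[prev > 0]
      prev_names <- if (length(prev))
        paste(label_map$structure[match(prev, label_map$label)], collapse = ", ")
      else "ventricle/background"
      stop("overlapping phantom elements: ", coll, " collides with ", prev_names)
    }
    if (s$role != "background" && !all(brain[m]))
      stop("structure extends outside the brain mask: ", s$structure)
    chi[m] <- s$chi_ppm
    r2s[m] <- s$r2star_per_s
    if (s$role == "ventricle") vent <- vent | m
    if (s$role == "structure" && !is.na(s$structure)) {
      labels[m] <- next_label
      label_map <- rbind(label_map, data.frame(
        label = next_label, structure = s$structure,
        hemisphere = s$hemisphere, stringsAsFactors = FALSE))
      next_label <- next_label + 1L
    }
    painted <- painted | m
  }

  chi_ext <- array(0, gs)
  for (s in spec$external_sources) {
    m <- rasterize_shape(s, gs)
    if (any(m & brain))
      stop("external source intersects the brain mask")
    chi_ext[m] <- chi_ext[m] + s$chi_ppm
  }

  structure(list(chi_ppm = chi, chi_external_ppm = chi_ext,
                 r2star_per_s = r2s, brain_mask = brain,
                 ventricle_mask = vent,
                 atlas = voi_atlas(labels, label_map, spec$voxel_size_mm),
                 voxel_size_mm = spec$voxel_size_mm, spec = spec),
            class = "qsm_ground_truth")
}

#' Multi-echo gradient-echo acquisition parameters
#'
#' Defaults follow a 3 T product multi-echo GRE protocol: first echo time
#' 3.6 ms, echo spacing 5.91 ms, 8 echoes, flip angle 15 degrees (metadata
#' only; the signal model does not use it).
#'
#' @param te_first_ms First echo time (ms).
#' @param echo_spacing_ms Echo spacing (ms).
#' @param n_echoes Number of echoes (>= 2).
#' @param b0_tesla Main field strength (T).
#' @param gamma_mhz_per_t Gyromagnetic ratio (MHz/T).
#' @param flip_deg Flip angle (degrees, metadata).
#' @param snr Signal-to-noise ratio of the first-echo magnitude within the
#'   brain mask; `Inf` for a noiseless simulation.
#' @param seed Integer seed for the noise stream.
#' @return An `acquisition_params` list with the per-echo `te_ms` vector.
#' @export
acquisition_params <- function(te_first_ms = 3.6, echo_spacing_ms = 5.91,
                               n_echoes = 8, b0_tesla = 3,
                               gamma_mhz_per_t = 42.577, flip_deg = 15,
                               snr = Inf, seed = 1L) {
  stopifnot(te_first_ms > 0, echo_spacing_ms > 0, n_echoes >= 2,
            b0_tesla > 0, gamma_mhz_per_t > 0)
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive")
  te_ms <- te_first_ms + (seq_len(n_echoes) - 1) * echo_spacing_ms
  structure(list(te_first_ms = te_first_ms, echo_spacing_ms = echo_spacing_ms,
                 n_echoes = as.integer(n_echoes), te_ms = te_ms,
                 b0_tesla = b0_tesla, gamma_mhz_per_t = gamma_mhz_per_t,
                 flip_deg = flip_deg, snr = snr, seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Wrap phase into (-pi, pi]
#' @param phi Numeric array of phase values (rad).
#' @return Array of the same shape.
#' @export
wrap_phase <- function(phi) {
  w <- Arg(complex(modulus = 1, argument = phi))
  if (is.null(dim(phi))) w else array(w, dim = dim(phi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate multi-echo gradient-echo data from a phantom
#'
#' Signal model per echo i: `M0 * exp(-TE_i * R2*) * exp(1i * phi_i)` with
#' `phi_i = 2*pi * gamma_Hz * B0 * field_ppm * 1e-6 * TE_i` and the field
#' given by the dipole forward model of tissue plus external susceptibility.
#' Positive phase corresponds to positive (paramagnetic) field shift; the
#' simulator and the reconstruction share this convention.  Complex Gaussian
#' noise is added at the stated SNR and the stored phase is wrapped to
#' (-pi, pi].
#'
#' @param truth A `qsm_ground_truth` from [build_phantom()].
#' @param acq An [acquisition_params()].
#' @param include_background Include the external sources' field (default
#'   TRUE).
#' @return A `multi_echo_gre` list: 4D `magnitude` and `phase`
#'   (x, y, z, echo), `te_ms`, `voxel_size_mm`, `b0_tesla`, `b0_direction`,
#'   `gamma_mhz_per_t`.
#' @export
simulate_gre <- function(truth, acq, include_background = TRUE) {
  stopifnot(inherits(truth, "qsm_ground_truth"),
            inherits(acq, "acquisition_params"))
  gs <- dim(truth$chi_ppm)
  kernel <- dipole_kernel(gs, truth$voxel_size_mm)
  chi_total <- truth$chi_ppm +
    if (include_background) truth$chi_external_ppm else 0
  field <- forward_field(chi_total, kernel)
  gamma_hz <- acq$gamma_mhz_per_t * 1e6
  m0 <- as.numeric(truth$brain_mask)
  ne <- acq$n_echoes
  mag <- array(0, c(gs, ne))
  phs <- array(0, c(gs, ne))
  noise_sd <- 0
  if (is.finite(acq$snr)) {
    m1 <- m0 * exp(-acq$te_ms[1] * 1e-3 * truth$r2star_per_s)
    noise_sd <- mean(m1[truth$brain_mask]) / acq$snr
  }
  with_seed(acq$seed, {
    for (i in seq_len(ne)) {
      te_s <- acq$te_ms[i] * 1e-3
      phi <- 2 * pi * gamma_hz * acq$b0_tesla * field * 1e-6 * te_s
      sig <- m0 * exp(-te_s * truth$r2star_per_s) *
        complex(modulus = 1, argument = phi)
      if (noise_sd > 0)
        sig <- sig + complex(real = stats::rnorm(length(sig), 0, noise_sd),
                             imaginary = stats::rnorm(length(sig), 0, noise_sd))
      mag[, , , i] <- Mod(sig)
      phs[, , , i] <- Arg(sig)
    }
  })
  structure(list(magnitude = mag, phase = phs, te_ms = acq$te_ms,
                 voxel_size_mm = truth$voxel_size_mm,
                 b0_tesla = acq$b0_tesla, b0_direction = c(0, 0, 1),
                 gamma_mhz_per_t = acq$gamma_mhz_per_t),
            class = "multi_echo_gre")
}

#' Default bilateral two-structure phantom scene
#'
#' A 64-voxel cubic grid at 1 mm isotropic resolution: a spherical brain of
#' radius 24 voxels (chi = 0), bilateral paramagnetic spheres (putamen-like,
#' +0.1 ppm), bilateral weakly diamagnetic spheres (hippocampus-like,
#' -0.015 ppm), a ventricle pair at chi = 0 for zero-referencing, and two
#' air-like external spheres (+9 ppm) above and below the brain that induce
#' a harmonic background field.
#'
#' @param grid Cubic grid side in voxels (default 64; scales the scene).
#' @param seed Seed recorded in the spec.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(grid = 64, seed = 1L) {
  g <- grid
  c0 <- (g + 1) / 2
  sc <- g / 64                      # scene scales with the grid
  rad <- function(r) max(2, round(r * sc))
  off <- function(o) o * sc
  # structures stay >= 9 voxels clear of the brain boundary so V-SHARP's
  # largest kernel fits everywhere inside them (see the methods vignette)
  shapes <- list(
    phantom_shape("sphere", c(c0, c0, c0), 24 * sc, chi_ppm = 0,
                  r2star_per_s = 20, role = "brain"),
    phantom_shape("sphere", c(c0 - off(9), c0, c0 + off(3)), rad(5),
                  chi_ppm = 0.1, r2star_per_s = 45,
                  structure = "putamen", hemisphere = "left"),
    phantom_shape("sphere", c(c0 + off(9), c0, c0 + off(3)), rad(5),
                  chi_ppm = 0.1, r2star_per_s = 45,
                  structure = "putamen", hemisphere = "right"),
    phantom_shape("sphere", c(c0 - off(6), c0 + off(8.5), c0 - off(3.5)),
                  rad(4), chi_ppm = -0.015, r2star_per_s = 25,
                  structure = "hippocampus", hemisphere = "left"),
    phantom_shape("sphere", c(c0 + off(6), c0 + off(8.5), c0 - off(3.5)),
                  rad(4), chi_ppm = -0.015, r2star_per_s = 25,
                  structure = "hippocampus", hemisphere = "right"),
    phantom_shape("sphere", c(c0 - off(4.5), c0 - off(9), c0), rad(4),
                  chi_ppm = 0, r2star_per_s = 2, role = "ventricle"),
    phantom_shape("sphere", c(c0 + off(4.5), c0 - off(9), c0), rad(4),
                  chi_ppm = 0, r2star_per_s = 2, role = "ventricle")
  )
  ext <- list(
    phantom_shape("sphere", c(c0, c0, 2.5), max(1.5, 2.5 * sc), chi_ppm = 9,
                  role = "background"),
    phantom_shape("sphere", c(c0, c0, g - 1.5), max(1.5, 2.5 * sc), chi_ppm = 9,
                  role = "background")
  )
  phantom_spec(c(g, g, g), c(1, 1, 1), shapes, ext,
               brain_margin_vox = min(8, floor(g / 2 - 24 * sc)), seed = seed)
}
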