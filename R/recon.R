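# Susceptibility reconstruction from multi-echo GRE phase:
# Laplacian unwrapping -> V-SHARP background removal (per echo) ->
# R2*-weighted echo combination -> two-stage iterative least-squares dipole
# inversion -> ventricle zero-referencing.

#' Reconstruction configuration
#'
#' @param vsharp_radii_mm Ascending spherical-mean-value radii (mm);
#'   default 1 to 29 mm in 2 mm steps.  Radii too large to fit inside the
#'   brain mask anywhere are dropped at run time.
#' @param deconv_threshold Truncation level for the V-SHARP deconvolution:
#'   k-space points with `|1 - S(k)| <` this are zeroed (default 0.05).
#' @param lsqr_max_iter Maximum LSQR iterations for the dipole inversion.
#' @param lsqr_tol Relative-residual stopping tolerance for LSQR.
#' @param streak_kernel_threshold Ill-conditioned k-space cone for the
#'   streaking-artifact stage: `|D(k)| <` this (default 0.1).
#' @param streak_max_iter LSQR iterations for the artifact re-estimation.
#' @param r2star_floor_per_s Lower clip for fitted R2* (default 0).
#' @return A `recon_config` list.
#' @export
recon_config <- function(vsharp_radii_mm = seq(1, 29, by = 2),
                         deconv_threshold = 0.05,
                         lsqr_max_iter = 50, lsqr_tol = 1e-4,
                         streak_kernel_threshold = 0.1,
                         streak_max_iter = 15,
                         r2star_floor_per_s = 0) {
  stopifnot(all(vsharp_radii_mm > 0), !is.unsorted(vsharp_radii_mm),
            deconv_threshold > 0, deconv_threshold < 1,
            lsqr_max_iter >= 1, lsqr_tol > 0,
            streak_kernel_threshold > 0, streak_kernel_threshold < 1,
            r2star_floor_per_s >= 0)
  structure(list(vsharp_radii_mm = vsharp_radii_mm,
                 deconv_threshold = deconv_threshold,
                 lsqr_max_iter = as.integer(lsqr_max_iter),
                 lsqr_tol = lsqr_tol,
                 streak_kernel_threshold = streak_kernel_threshold,
                 streak_max_iter = as.integer(streak_max_iter),
                 r2star_floor_per_s = r2star_floor_per_s),
            class = "recon_config")
}

#' Laplacian phase unwrapping
#'
#' Computes the unwrapped phase spectrally from the wrapped phase via
#' `inv_lap(cos(phi) * lap(sin(phi)) - sin(phi) * lap(cos(phi)))`, where the
#' Laplacian is multiplication by `-|2 pi k|^2` in k-space and its inverse
#' zeroes the undetermined DC term.  The result is smooth (no 2 pi jumps)
#' and agrees with the true phase up to an additive constant plus a small
#' harmonic residual.
#'
#' @param phase_wrapped 3D phase array in (-pi, pi].
#' @param voxel_size_mm Voxel size (mm), length 3.
#' @param boundary `"neumann"` (default) evaluates the spectral operators on
#'   the mirror-extended grid, which preserves a net phase ramp across the
#'   volume; `"periodic"` works on the raw grid, where any mean gradient is
#'   unrepresentable and is silently removed.
#' @return 3D unwrapped phase array (mean-free).
#' @export
laplacian_unwrap <- function(phase_wrapped, voxel_size_mm = c(1, 1, 1),
                             boundary = c("neumann", "periodic")) {
  if (!all(is.finite(phase_wrapped))) stop("phase contains non-finite values")
  boundary <- match.arg(boundary)
  gs0 <- dim(phase_wrapped)
  p <- phase_wrapped
  if (boundary == "neumann") {
    p <- p[c(seq_len(gs0[1]), rev(seq_len(gs0[1]))), , , drop = FALSE]
    p <- p[, c(seq_len(gs0[2]), rev(seq_len(gs0[2]))), , drop = FALSE]
    p <- p[, , c(seq_len(gs0[3]), rev(seq_len(gs0[3]))), drop = FALSE]
  }
  gs <- dim(p)
  k2 <- (2 * pi)^2 * k_grids(gs, voxel_size_mm)$k2
  lap <- function(x) -Re(ifft(k2 * stats::fft(x)))
  s <- sin(p); cphi <- cos(p)
  rhs <- cphi * lap(s) - s * lap(cphi)
  rk <- stats::fft(rhs) / (-k2)
  rk[k2 == 0] <- 0
  out <- Re(ifft(rk))
  out[seq_len(gs0[1]), seq_len(gs0[2]), seq_len(gs0[3]), drop = FALSE]
}

# Admissibility: voxels where a sphere of the given radius lies entirely
# inside the mask (spherical mean of the mask ~ 1).
smv_admissible <- function(mask_num, kernel_ft) {
  spectral_conv(mask_num, kernel_ft) > 1 - 1e-6
}

#' V-SHARP background field removal
#'
#' Removes the harmonic background field generated by sources outside the
#' brain using spherical-mean-value (SMV) filtering with a variable kernel
#' radius: each voxel is high-pass filtered `(I - S_r)` with the largest
#' sphere radius that still fits inside the brain mask at that voxel (large
#' spheres deep in the brain, small near the boundary), and the residual
#' SMV convolution is then deconvolved with the largest configured radius,
#' truncating `|1 - S(k)|` below `deconv_threshold`.  The valid output mask
#' is the input mask eroded by the smallest radius.
#'
#' @param field 3D array: unwrapped phase (rad) or field (ppm); units are
#'   preserved.
#' @param brain_mask Logical 3D array.
#' @param voxel_size_mm Voxel size (mm).
#' @param config A [recon_config()].
#' @return A `local_field_map` list: `field` (same units as input, zero
#'   outside `valid_mask`), `valid_mask`, `radii_used_mm`.
#' @export
vsharp <- function(field, brain_mask, voxel_size_mm = c(1, 1, 1),
                   config = recon_config()) {
  gs <- dim(field)
  stopifnot(identical(gs, dim(brain_mask)))
  if (!any(brain_mask)) stop("brain mask is empty")
  mask_num <- array(as.numeric(brain_mask), gs)
  f <- field * mask_num

  radii <- config$vsharp_radii_mm
  kernels <- lapply(radii, function(r) smv_kernel(gs, voxel_size_mm, r))
  adm <- lapply(kernels, function(k) smv_admissible(mask_num, k$ft))
  fits <- vapply(adm, any, logical(1))
  if (!fits[1])
    stop("brain mask too thin for the smallest SMV radius (",
         radii[1], " mm); use smaller vsharp_radii_mm")
  radii <- radii[fits]; kernels <- kernels[fits]; adm <- adm[fits]

  # largest admissible radius per voxel: ascending overwrite
  hp <- array(0, gs)
  for (i in seq_along(radii)) {
    hpi <- f - spectral_conv(f, kernels[[i]]$ft)
    hp[adm[[i]]] <- hpi[adm[[i]]]
  }
  valid <- adm[[1]]
  hp <- hp * valid

  s_max <- kernels[[length(kernels)]]$ft
  denom <- 1 - s_max
  fk <- stats::fft(hp) / denom
  fk[abs(denom) < config$deconv_threshold] <- 0
  local <- Re(ifft(fk)) * valid

  structure(list(field = local, valid_mask = valid, radii_used_mm = radii),
            class = "local_field_map")
}

#' Voxelwise R2* from multi-echo magnitudes
#'
#' Log-linear least-squares: the negated slope of `log(magnitude)` against
#' echo time, clipped below at `floor_per_s`.  Voxels with non-positive
#' magnitude at any echo cannot be fitted and return R2* = 0, flagged in the
#' `"degenerate"` attribute.
#'
#' @param magnitude 4D array (x, y, z, echo), non-negative.
#' @param te_ms Echo times (ms), length matching the 4th dimension.
#' @param floor_per_s Lower clip (1/s).
#' @return 3D R2* array (1/s) with logical attribute `degenerate`.
#' @export
estimate_r2star <- function(magnitude, te_ms, floor_per_s = 0) {
  stopifnot(length(dim(magnitude)) == 4, dim(magnitude)[4] == length(te_ms),
            length(te_ms) >= 2)
  te_s <- te_ms * 1e-3
  gs <- dim(magnitude)[1:3]
  ne <- length(te_s)
  bad <- array(FALSE, gs)
  for (i in seq_len(ne)) bad <- bad | magnitude[, , , i] <= 0
  tc <- te_s - mean(te_s)
  sxx <- sum(tc^2)
  sxy <- array(0, gs)
  lm_clipped <- function(i) {
    m <- magnitude[, , , i]
    m[m <= 0] <- 1          # placeholder; these voxels are zeroed below
    log(m)
  }
  for (i in seq_len(ne)) sxy <- sxy + tc[i] * lm_clipped(i)
  r2s <- -sxy / sxx
  r2s[bad] <- 0
  r2s <- pmax(r2s, floor_per_s)
  r2s <- array(r2s, gs)
  attr(r2s, "degenerate") <- bad
  r2s
}

#' R2*-weighted combination of per-echo field maps
#'
#' Voxelwise weighted mean with weights `w_i` proportional to
#' `TE_i * exp(-TE_i * R2*)` (the phase-SNR optimal weighting for a
#' monoexponentially decaying magnitude), normalised to sum to 1.  Voxels
#' where all weights vanish fall back to the unweighted mean with a warning.
#'
#' @param fields List of per-echo `local_field_map`s (or 3D arrays) in
#'   consistent units (ppm).
#' @param te_ms Echo times (ms).
#' @param r2star 3D R2* map (1/s).
#' @return A `local_field_map` with the combined field and the intersection
#'   of the per-echo valid masks.
#' @export
combine_echo_fields <- function(fields, te_ms, r2star) {
  stopifnot(length(fields) == length(te_ms), length(fields) >= 1)
  get_f <- function(x) if (inherits(x, "local_field_map")) x$field else x
  get_m <- function(x) if (inherits(x, "local_field_map")) x$valid_mask else
    array(TRUE, dim(x))
  gs <- dim(get_f(fields[[1]]))
  valid <- Reduce(`&`, lapply(fields, get_m))
  te_s <- te_ms * 1e-3
  num <- array(0, gs); den <- array(0, gs); plain <- array(0, gs)
  for (i in seq_along(fields)) {
    w <- te_s[i] * exp(-te_s[i] * r2star)
    fi <- get_f(fields[[i]])
    num <- num + w * fi
    den <- den + w
    plain <- plain + fi / length(fields)
  }
  zero_w <- den <= 0 & valid
  if (any(zero_w))
    warning(sum(zero_w), " voxel(s) had zero combination weight; ",
            "falling back to the unweighted mean there")
  out <- num / den
  out[zero_w] <- plain[zero_w]
  out[!valid] <- 0
  structure(list(field = out, valid_mask = valid, radii_used_mm = NULL),
            class = "local_field_map")
}

# Generic LSQR (Paige & Saunders) on array-valued linear operators.
lsqr_solve <- function(aop, atop, b, max_iter, tol) {
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0)
    return(list(x = 0 * atop(b), iterations = 0L, converged = TRUE,
                relres = 0))
  u <- b; beta <- bnorm; u <- u / beta
  v <- atop(u); alpha <- sqrt(sum(v^2)); v <- v / alpha
  w <- v
  x <- array(0, dim(v))
  phibar <- beta; rhobar <- alpha
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    u <- aop(v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    v <- atop(u) - beta * v
    alpha <- sqrt(sum(v^2))
    if (alpha > 0) v <- v / alpha
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho; sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    if (phibar / bnorm < tol) { converged <- TRUE; break }
  }
  list(x = x, iterations = it, converged = converged,
       relres = phibar / bnorm)
}

# Forward differences with circular shift along one axis and their adjoint.
fwd_diff <- function(x, axis) {
  n <- dim(x)[axis]
  idx <- c(2:n, 1L)
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE]) - x
}
fwd_diff_adj <- function(x, axis) {
  n <- dim(x)[axis]
  idx <- c(n, 1:(n - 1L))
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE]) - x
}

#' Two-stage iterative least-squares dipole inversion
#'
#' Stage 1 solves the support-constrained least-squares problem
#' `argmin_chi || M (IFFT(D FFT(M chi)) - f) ||_2` by LSQR, with `M` the
#' valid mask: susceptibility is reconstructed only where the field was
#' measured, which removes the null-space components that otherwise shrink
#' structure values.  Stage 2 estimates the streaking artifact that the
#' ill-conditioned dipole cone leaves in the stage-1 map: a field
#' constrained to the cone `{|D(k)| < streak_kernel_threshold}` in k-space
#' is fitted by least squares to the edge-weighted spatial gradients of the
#' stage-1 map (weights suppress genuine tissue boundaries, flagged by
#' large local-field gradients, so mostly streaks are captured) and
#' subtracted inside the mask.  The result is zero outside the valid mask
#' and not yet zero-referenced.
#'
#' @param field A `local_field_map` (ppm) or 3D array.
#' @param kernel Dipole kernel on the same grid.
#' @param config A [recon_config()].
#' @param valid_mask Required if `field` is a plain array.
#' @return 3D susceptibility array (ppm) with attributes `converged`,
#'   `iterations`.
#' @export
dipole_inversion_ilsqr <- function(field, kernel, config = recon_config(),
                                   valid_mask = NULL) {
  if (inherits(field, "local_field_map")) {
    valid_mask <- field$valid_mask
    field <- field$field
  }
  if (is.null(valid_mask)) stop("valid_mask required for plain-array input")
  gs <- dim(field)
  if (!identical(gs, dim(kernel))) stop("grid mismatch with dipole kernel")
  m <- array(as.numeric(valid_mask), gs)
  b <- field * m

  aop <- function(x) m * Re(ifft(kernel * stats::fft(m * x)))
  st1 <- lsqr_solve(aop, aop, b, config$lsqr_max_iter, config$lsqr_tol)
  if (!st1$converged && st1$relres > config$lsqr_tol)
    warning("LSQR reached max_iter (", st1$iterations,
            ") with relative residual ", signif(st1$relres, 3))
  chi1 <- m * st1$x

  cone <- abs(kernel) < config$streak_kernel_threshold
  if (any(cone) && config$streak_max_iter > 0) {
    # scale-invariant edge weights from the local field: ~1 in smooth
    # tissue, small across boundaries, so true edges are not treated as
    # streaks.  Weights depend only on the field's gradient *pattern*, so
    # the whole inversion stays linear under rescaling of the input.
    wts <- lapply(1:3, function(ax) {
      g <- abs(fwd_diff(b, ax))
      sc <- stats::median(g[g > 0]) %||% 0
      if (!is.finite(sc) || sc == 0) sc <- 1
      1 / (1 + (g / (4 * sc))^2)
    })
    pcone <- function(x) {
      xk <- stats::fft(x)
      xk[!cone] <- 0
      Re(ifft(xk))
    }
    bop <- function(x) {
      px <- pcone(x)
      arr <- array(0, c(gs, 3))
      for (ax in 1:3) arr[, , , ax] <- wts[[ax]] * fwd_diff(px, ax)
      arr
    }
    btop <- function(y) {
      acc <- array(0, gs)
      for (ax in 1:3)
        acc <- acc + fwd_diff_adj(wts[[ax]] * y[, , , ax, drop = FALSE][, , , 1],
                                  ax)
      pcone(acc)
    }
    data2 <- array(0, c(gs, 3))
    for (ax in 1:3) data2[, , , ax] <- wts[[ax]] * fwd_diff(chi1, ax)
    st2 <- lsqr_solve(bop, btop, data2,
                      config$streak_max_iter, config$lsqr_tol)
    chi1 <- m * (chi1 - pcone(st2$x))
  }

  attr(chi1, "converged") <- st1$converged
  attr(chi1, "iterations") <- st1$iterations
  chi1
}

#' Zero-reference a susceptibility map to a region
#'
#' Subtracts the mean susceptibility over the reference region (lateral
#' ventricles), fixing the arbitrary offset that dipole inversion leaves
#' undetermined.
#'
#' @param chi 3D susceptibility array (ppm).
#' @param ventricle_mask Logical 3D array, non-empty.
#' @param valid_mask Optional logical mask of reconstructed voxels.
#' @param reference_region Name recorded in the output.
#' @return A `susceptibility_map` list: `chi_ppm`, `valid_mask`,
#'   `reference_region`, `reference_offset_ppm`.
#' @export
zero_reference <- function(chi, ventricle_mask, valid_mask = NULL,
                           reference_region = "lateral ventricles") {
  stopifnot(identical(dim(chi), dim(ventricle_mask)))
  if (!any(ventricle_mask)) stop("ventricle mask is empty")
  offset <- mean(chi[ventricle_mask])
  out <- chi - offset
  if (!is.null(valid_mask)) out <- out * valid_mask
  structure(list(chi_ppm = out,
                 valid_mask = valid_mask %||% array(TRUE, dim(chi)),
                 reference_region = reference_region,
                 reference_offset_ppm = offset),
            class = "susceptibility_map")
}

#' Full QSM reconstruction from multi-echo GRE data
#'
#' Composition of the stages: Laplacian unwrapping of each echo's phase,
#' per-echo V-SHARP background removal, conversion to field in ppm
#' (`phase / (2 pi gamma B0 TE 1e-6)`), R2*-weighted echo combination,
#' two-stage LSQR dipole inversion, and zero-referencing to the ventricles.
#'
#' @param gre A `multi_echo_gre` from [simulate_gre()] or [read_gre()].
#' @param brain_mask Logical 3D array.
#' @param ventricle_mask Logical 3D array inside the brain mask.
#' @param config A [recon_config()].
#' @param verbose Log stage progress to stderr.
#' @param keep_field Attach the combined local field map (the dipole
#'   inversion's input) as the `local_field` element of the result, for
#'   data-fidelity audits.
#' @return A `susceptibility_map`; `valid_mask` is the V-SHARP-eroded brain
#'   mask intersected across echoes.
#' @export
reconstruct_qsm <- function(gre, brain_mask, ventricle_mask,
                            config = recon_config(), verbose = FALSE,
                            keep_field = FALSE) {
  stopifnot(inherits(gre, "multi_echo_gre"))
  gs <- dim(gre$phase)[1:3]
  stopifnot(identical(gs, dim(brain_mask)),
            identical(gs, dim(ventricle_mask)))
  if (all(gre$magnitude == 0)) {
    warning("zero-signal input; returning an all-zero map")
    return(zero_reference(array(0, gs), ventricle_mask,
                          valid_mask = brain_mask))
  }
  say <- function(...) if (verbose) message("[reconstruct_qsm] ", ...)
  ne <- length(gre$te_ms)
  gamma_hz <- gre$gamma_mhz_per_t * 1e6
  fields <- vector("list", ne)
  for (i in seq_len(ne)) {
    say("echo ", i, "/", ne, ": unwrap + V-SHARP")
    unwrapped <- laplacian_unwrap(gre$phase[, , , i], gre$voxel_size_mm)
    lf <- vsharp(unwrapped, brain_mask, gre$voxel_size_mm, config)
    scale <- 2 * pi * gamma_hz * gre$b0_tesla * 1e-6 * gre$te_ms[i] * 1e-3
    lf$field <- lf$field / scale
    fields[[i]] <- lf
  }
  say("R2* fit and echo combination")
  r2s <- estimate_r2star(gre$magnitude, gre$te_ms, config$r2star_floor_per_s)
  combined <- combine_echo_fields(fields, gre$te_ms, r2s)
  say("dipole inversion (LSQR, max ", config$lsqr_max_iter, " iterations)")
  kernel <- dipole_kernel(gs, gre$voxel_size_mm, gre$b0_direction)
  chi <- dipole_inversion_ilsqr(combined, kernel, config)
  vent_valid <- ventricle_mask & combined$valid_mask
  if (!any(vent_valid)) vent_valid <- ventricle_mask
  say("zero-referencing to ventricles")
  out <- zero_reference(chi, vent_valid, valid_mask = combined$valid_mask)
  if (keep_field) out$local_field <- combined
  out
}
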