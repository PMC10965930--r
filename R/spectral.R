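# Spectral primitives shared by the forward model and the reconstruction
# chain.  All operators treat the grid as periodic; phantom scenes keep the
# brain mask at least 8 voxels from every edge so wrap-around is negligible.

#' Discrete Fourier-transform sample frequencies
#'
#' Frequencies (cycles per unit) for an n-point DFT with sample spacing `d`,
#' in standard FFT order (DC first, negative frequencies in the upper half).
#'
#' @param n Number of samples.
#' @param d Sample spacing (e.g. voxel size in mm).
#' @return Numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L)) / (n * d)
}

ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Spatial-frequency coordinate grids
#'
#' @param grid_shape Integer vector of 3 array dimensions.
#' @param voxel_size_mm Numeric vector of 3 voxel sizes (mm).
#' @return List with 3D arrays `kx`, `ky`, `kz` (cycles/mm) and `k2 = |k|^2`.
#' @keywords internal
k_grids <- function(grid_shape, voxel_size_mm) {
  fx <- fft_freq(grid_shape[1], voxel_size_mm[1])
  fy <- fft_freq(grid_shape[2], voxel_size_mm[2])
  fz <- fft_freq(grid_shape[3], voxel_size_mm[3])
  kx <- array(fx, grid_shape)
  ky <- array(rep(fy, each = grid_shape[1]), grid_shape)
  kz <- array(rep(fz, each = grid_shape[1] * grid_shape[2]), grid_shape)
  list(kx = kx, ky = ky, kz = kz, k2 = kx^2 + ky^2 + kz^2)
}

#' Unit dipole kernel in k-space
#'
#' The magnetostatic point-dipole response relating a susceptibility
#' distribution to the field it induces along B0:
#' `D(k) = 1/3 - (k . b0)^2 / |k|^2`.  `D` vanishes on the magic-angle cone,
#' which is what makes dipole inversion ill-posed.  The undetermined DC term
#' is set to 0, so reconstructed susceptibility is mean-free until
#' zero-referencing fixes the offset.
#'
#' @param grid_shape Integer vector of 3 array dimensions.
#' @param voxel_size_mm Numeric vector of 3 voxel sizes (mm).
#' @param b0_direction Unit vector of the main field direction (default +z).
#' @return Real 3D array in FFT layout.
#' @export
dipole_kernel <- function(grid_shape, voxel_size_mm, b0_direction = c(0, 0, 1)) {
  stopifnot(length(grid_shape) == 3, length(voxel_size_mm) == 3,
            all(grid_shape >= 1), all(voxel_size_mm > 0))
  nrm <- sqrt(sum(b0_direction^2))
  if (!is.finite(nrm) || nrm <= 0)
    stop("b0_direction must be a non-zero vector")
  b0 <- b0_direction / nrm
  kg <- k_grids(grid_shape, voxel_size_mm)
  kpar <- kg$kx * b0[1] + kg$ky * b0[2] + kg$kz * b0[3]
  d <- 1 / 3 - kpar^2 / kg$k2
  d[kg$k2 == 0] <- 0
  d
}

#' Field induced by a susceptibility distribution
#'
#' Forward dipole model `field = IFFT(D * FFT(chi))`, in the same units as
#' `chi` (ppm in, ppm out).
#'
#' @param chi_ppm Real 3D susceptibility array (ppm).
#' @param kernel Dipole kernel from [dipole_kernel()] on the same grid.
#' @return Real 3D field array (ppm).
#' @export
forward_field <- function(chi_ppm, kernel) {
  if (!all(is.finite(chi_ppm))) stop("chi_ppm must be finite everywhere")
  if (!identical(dim(chi_ppm), dim(kernel)))
    stop("grid mismatch between chi_ppm and kernel")
  Re(ifft(kernel * stats::fft(chi_ppm)))
}

#' Spherical-mean-value kernel in k-space
#'
#' Normalised hard-sphere averaging kernel of the given radius, rasterised
#' on the periodic grid (centre at the array origin) and Fourier transformed.
#' Used by SHARP-family background removal: `(I - S_r)` annihilates fields
#' harmonic over the sphere.
#'
#' @param grid_shape Integer vector of 3 array dimensions.
#' @param voxel_size_mm Numeric vector of 3 voxel sizes (mm).
#' @param radius_mm Sphere radius in mm.
#' @return List with `ft` (real k-space kernel) and `n_vox` (sphere size).
#' @keywords internal
smv_kernel <- function(grid_shape, voxel_size_mm, radius_mm) {
  stopifnot(radius_mm > 0)
  # wrapped signed distance from the origin along each axis
  ax <- function(n, d) {
    i <- seq_len(n) - 1L
    pmin(i, n - i) * d
  }
  dx <- ax(grid_shape[1], voxel_size_mm[1])
  dy <- ax(grid_shape[2], voxel_size_mm[2])
  dz <- ax(grid_shape[3], voxel_size_mm[3])
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  sph <- array(as.numeric(r2 <= radius_mm^2 + 1e-9), grid_shape)
  n_vox <- sum(sph)
  list(ft = Re(stats::fft(sph / n_vox)), n_vox = n_vox)
}

#' Spectral convolution with a precomputed k-space kernel
#' @keywords internal
spectral_conv <- function(x, kernel_ft) {
  Re(ifft(kernel_ft * stats::fft(x)))
}
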