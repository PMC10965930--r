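# Independent oracles and shared fixtures for the test suite.

# Literal Benjamini-Hochberg step-up, loop-based: q_(i) = min_{j >= i} of
# p_(j) * m / j on the order statistics, mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# Brute-force one-way ANOVA from raw data via explicit sums of squares.
anova_brute <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  N <- length(values)
  gm <- mean(values)
  ssb <- 0
  ssw <- 0
  for (lv in levels(g)) {
    x <- values[g == lv]
    ssb <- ssb + length(x) * (mean(x) - gm)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Analytic field of a uniform susceptibility sphere (Lorentz-corrected):
# zero inside, chi * a^3 / 3 * (3 cos^2 theta - 1) / r^3 outside.
sphere_field_analytic <- function(grid_shape, center, radius, chi) {
  x <- seq_len(grid_shape[1]) - center[1]
  y <- seq_len(grid_shape[2]) - center[2]
  z <- seq_len(grid_shape[3]) - center[3]
  X <- array(x, grid_shape)
  Y <- array(rep(y, each = grid_shape[1]), grid_shape)
  Z <- array(rep(z, each = grid_shape[1] * grid_shape[2]), grid_shape)
  r2 <- X^2 + Y^2 + Z^2
  r2[r2 == 0] <- Inf
  fld <- chi * radius^3 / 3 * (3 * Z^2 / r2 - 1) / r2^1.5
  fld[r2 <= radius^2] <- 0
  fld
}

# Small shared phantom (built once per test file load).
small_truth <- function() build_phantom(default_phantom_spec(48))

# Cheap recon config for unit tests on small grids.
test_recon_config <- function()
  recon_config(vsharp_radii_mm = c(1, 3, 5), lsqr_max_iter = 30)

# Phantom-scale reconstruction configuration: V-SHARP radii capped at the
# structures' depth below the brain boundary (9 voxels in the default
# scene) so the deconvolution radius is admissible throughout every VOI.
phantom_recon_config <- function()
  recon_config(vsharp_radii_mm = seq(1, 7, by = 2))

# Reference table restricted to the nucleus accumbens (single-region
# simulations for the interaction-recovery study).
accumbens_only_stats <- function() {
  ref <- subcortical_reference_stats()
  ref[ref$region == "nucleus accumbens", ]
}
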