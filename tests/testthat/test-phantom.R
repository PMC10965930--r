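test_that("build_phantom rasterises scenes and enforces geometry invariants", {
  # empty scene
  sp <- phantom_spec(c(16, 16, 16), shapes = list(), brain_margin_vox = 0)
  tr <- build_phantom(sp)
  expect_true(all(tr$chi_ppm == 0))
  expect_false(any(tr$brain_mask))

  # analytic sphere volume vs rasterisation
  sp <- phantom_spec(c(32, 32, 32), shapes = list(
    phantom_shape("sphere", c(16.5, 16.5, 16.5), 14, role = "brain"),
    phantom_shape("sphere", c(16.5, 16.5, 16.5), 8, chi_ppm = 0.1,
                  structure = "caudate", hemisphere = "left")),
    brain_margin_vox = 2)
  tr <- build_phantom(sp)
  n_vox <- sum(tr$atlas$labels == 1)
  expect_lt(abs(n_vox - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.05)

  # overlapping labelled shapes collide with an informative error
  sp_bad <- phantom_spec(c(32, 32, 32), shapes = list(
    phantom_shape("sphere", c(16.5, 16.5, 16.5), 14, role = "brain"),
    phantom_shape("sphere", c(14.5, 16.5, 16.5), 4, structure = "caudate",
                  hemisphere = "left"),
    phantom_shape("sphere", c(18.5, 16.5, 16.5), 4, structure = "putamen",
                  hemisphere = "left")), brain_margin_vox = 2)
  expect_error(build_phantom(sp_bad), "caudate")

  # centre outside the grid is rejected at spec time
  expect_error(phantom_spec(c(16, 16, 16), shapes = list(
    phantom_shape("sphere", c(40, 8, 8), 2, structure = "caudate",
                  hemisphere = "left"))), "outside grid")
})

test_that("dipole kernel matches the unit-dipole response on axes", {
  d <- dipole_kernel(c(8, 8, 8), c(1, 1, 1))
  expect_equal(d[1, 1, 1], 0)              # declared DC convention
  expect_equal(d[1, 1, 2], 1 / 3 - 1)      # k parallel to B0: -2/3
  expect_equal(d[2, 1, 1], 1 / 3)          # k perpendicular to B0
  expect_equal(d[1, 3, 1], 1 / 3)
  expect_error(dipole_kernel(c(8, 8, 8), c(1, 1, 1), c(0, 0, 0)),
               "non-zero")
})

test_that("forward field is linear, kills uniform chi, and matches the analytic sphere", {
  gs <- c(64, 64, 64)
  d <- dipole_kernel(gs, c(1, 1, 1))
  expect_equal(max(abs(forward_field(array(0.7, gs), d))), 0)

  chi <- array(0, gs)
  ctr <- c(32.5, 32.5, 32.5); a <- 6
  x <- seq_len(64)
  r2 <- outer(outer((x - ctr[1])^2, (x - ctr[2])^2, `+`), (x - ctr[3])^2, `+`)
  chi[r2 <= a^2] <- 0.1
  f <- forward_field(chi, d)
  fa <- sphere_field_analytic(gs, ctr, a, 0.1)
  shell <- r2 > (2 * a)^2 & r2 < (3.2 * a)^2
  expect_lt(sqrt(mean((f[shell] - fa[shell])^2)) / sqrt(mean(fa[shell]^2)),
            0.05)

  # linearity to machine precision
  chi2 <- array(stats::rnorm(prod(gs)), gs)
  lhs <- forward_field(2 * chi + 3 * chi2, d)
  rhs <- 2 * forward_field(chi, d) + 3 * forward_field(chi2, d)
  expect_lt(max(abs(lhs - rhs)), 1e-12)

  expect_error(forward_field(array(0, c(8, 8, 8)), d), "mismatch")
})

test_that("external-source fields are harmonic inside the brain mask", {
  # a band-limited (Gaussian) source outside the mask: its dipole field
  # must have vanishing discrete Laplacian in the mask interior.  (Hard-
  # edged rasterised spheres add broadband Gibbs ringing that the
  # finite-difference Laplacian amplifies, so the smooth source isolates
  # the physics being checked.)
  gs <- c(64, 64, 64)
  d <- dipole_kernel(gs, c(1, 1, 1))
  x <- seq_len(64)
  r2 <- outer(outer((x - 32.5)^2, (x - 32.5)^2, `+`), (x - 6)^2, `+`)
  chi <- 9 * exp(-r2 / (2 * 2^2))
  f <- forward_field(chi, d)
  rb <- outer(outer((x - 32.5)^2, (x - 32.5)^2, `+`), (x - 32.5)^2, `+`)
  mask <- rb <= 24^2
  sh <- function(a, ax, by) {
    n <- dim(a)[ax]; idx <- ((seq_len(n) - 1 + by) %% n) + 1
    switch(ax, a[idx, , ], a[, idx, ], a[, , idx])
  }
  lap <- sh(f, 1, 1) + sh(f, 1, -1) + sh(f, 2, 1) + sh(f, 2, -1) +
    sh(f, 3, 1) + sh(f, 3, -1) - 6 * f
  interior <- rb <= (24 - 6)^2     # clear of the source's Gaussian tail
  expect_lt(max(abs(lap[interior])), 1e-3 * diff(range(f[mask])))
})

test_that("simulate_gre follows the stated signal model", {
  tr <- small_truth()
  acq <- acquisition_params(snr = Inf, n_echoes = 3)
  gre <- simulate_gre(tr, acq)

  # magnitude decay law between consecutive echoes
  dte_s <- (gre$te_ms[2] - gre$te_ms[1]) * 1e-3
  inb <- which(tr$brain_mask & tr$r2star_per_s > 0)
  m1 <- gre$magnitude[, , , 1][inb]
  m2 <- gre$magnitude[, , , 2][inb]
  expect_equal(m2 / m1, exp(-dte_s * tr$r2star_per_s[inb]), tolerance = 1e-10)

  # phase scales with TE and is wrapped to (-pi, pi]
  expect_true(all(gre$phase > -pi - 1e-12 & gre$phase <= pi + 1e-12))
  expect_equal(wrap_phase(2 * pi + 0.3), 0.3, tolerance = 1e-12)
  expect_equal(wrap_phase(0.5), 0.5, tolerance = 1e-12)

  # determinism: identical seeds give bit-identical noise realisations
  acq_n <- acquisition_params(snr = 40, seed = 11, n_echoes = 2)
  g1 <- simulate_gre(tr, acq_n)
  g2 <- simulate_gre(tr, acq_n)
  expect_identical(g1$magnitude, g2$magnitude)
  expect_identical(g1$phase, g2$phase)
  g3 <- simulate_gre(tr, acquisition_params(snr = 40, seed = 12, n_echoes = 2))
  expect_false(identical(g1$phase, g3$phase))

  expect_error(acquisition_params(snr = -5), "positive")
})

test_that("noiseless magnitudes return the exact R2* map", {
  tr <- small_truth()
  gre <- simulate_gre(tr, acquisition_params(snr = Inf, n_echoes = 4))
  r2s <- estimate_r2star(gre$magnitude, gre$te_ms)
  inb <- tr$brain_mask
  expect_equal(r2s[inb], tr$r2star_per_s[inb], tolerance = 1e-8)
})
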