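test_that("Laplacian unwrapping recovers wrap-free and wrapped smooth phase", {
  gs <- c(48, 48, 48)
  expect_equal(laplacian_unwrap(array(0, gs)), array(0, gs))

  # smooth bump with |phase| < pi: idempotent up to a constant
  x <- seq_len(48)
  r2 <- outer(outer((x - 24.5)^2, (x - 24.5)^2, `+`), (x - 24.5)^2, `+`)
  bump <- 2.8 * exp(-r2 / (2 * 6^2))
  u <- laplacian_unwrap(wrap_phase(bump))
  interior <- 9:40
  dev <- (u - bump)[interior, interior, interior]
  dev <- dev - mean(dev)
  expect_lt(max(abs(dev)), 0.05)

  # wrapped ramp spanning 6 pi across the mask, plateaus outside
  ramp1d <- pmin(pmax((x - 9) / (40 - 9), 0), 1) * 6 * pi
  true <- array(rep(ramp1d, times = 48 * 48), gs)
  u <- laplacian_unwrap(wrap_phase(true))
  dev <- (u - true)[13:36, interior, interior]
  dev <- dev - mean(dev)
  expect_lt(max(abs(dev)), 0.1)

  expect_error(laplacian_unwrap(array(NaN, c(4, 4, 4))), "finite")
})

test_that("V-SHARP removes external harmonic fields and keeps internal ones", {
  tr <- small_truth()
  d <- dipole_kernel(dim(tr$chi_ppm), tr$voxel_size_mm)
  cfg <- test_recon_config()

  z <- vsharp(array(0, dim(tr$chi_ppm)), tr$brain_mask, tr$voxel_size_mm, cfg)
  expect_equal(max(abs(z$field)), 0)

  f_ext <- forward_field(tr$chi_external_ppm, d)
  lf <- vsharp(f_ext, tr$brain_mask, tr$voxel_size_mm, cfg)
  v <- lf$valid_mask
  expect_lt(sqrt(mean(lf$field[v]^2)) / sqrt(mean(f_ext[v]^2)), 0.05)

  # superposition: internal dipole field survives background removal
  f_int <- forward_field(tr$chi_ppm, d)
  lf2 <- vsharp(f_int + f_ext, tr$brain_mask, tr$voxel_size_mm, cfg)
  err <- lf2$field - f_int
  expect_lt(sqrt(mean(err[v]^2)) / diff(range(f_int[v])), 0.10)

  # a mask too thin for the smallest radius errors with advice
  thin <- array(FALSE, c(24, 24, 24)); thin[12, , ] <- TRUE
  expect_error(vsharp(array(1, c(24, 24, 24)), thin, c(1, 1, 1),
                      recon_config(vsharp_radii_mm = c(5))), "smaller")
})

test_that("R2* estimation is exact on noiseless decays and handles edge cases", {
  te <- c(5, 10, 20, 40)
  mk <- function(r2s, m0 = 1) {
    arr <- array(0, c(2, 2, 2, 4))
    for (i in 1:4) arr[, , , i] <- m0 * exp(-te[i] * 1e-3 * r2s)
    arr
  }
  expect_equal(unclass(estimate_r2star(mk(20), te))[1], 20, tolerance = 1e-10)
  expect_equal(unclass(estimate_r2star(mk(50), te))[1], 50, tolerance = 1e-10)
  expect_equal(unclass(estimate_r2star(mk(0), te))[1], 0)
  z <- estimate_r2star(array(0, c(2, 2, 2, 4)), te)
  expect_true(all(z == 0))
  expect_true(all(attr(z, "degenerate")))
})

test_that("echo combination uses TE-weighted exponential weights", {
  gs <- c(4, 4, 4)
  f <- array(0.3, gs)
  # identical fields at every echo pass through unchanged
  comb <- combine_echo_fields(list(f, f, f), c(10, 20, 30),
                              array(25, gs))
  expect_equal(comb$field, f, tolerance = 1e-12)

  # two echoes, TE 10/20 ms, R2* = 100: w2/w1 = 2 exp(-1)
  f1 <- array(1, gs); f2 <- array(0, gs)
  comb <- combine_echo_fields(list(f1, f2), c(10, 20), array(100, gs))
  w2_over_w1 <- 2 * exp(-1)
  expect_equal(comb$field[1], 1 / (1 + w2_over_w1), tolerance = 1e-12)

  # R2* = 0 reduces to TE-proportional weights
  comb <- combine_echo_fields(list(f1, f2), c(10, 30), array(0, gs))
  expect_equal(comb$field[1], 10 / 40, tolerance = 1e-12)
})

test_that("dipole inversion is linear, self-consistent, and zero on zero field", {
  tr <- small_truth()
  gs <- dim(tr$chi_ppm)
  d <- dipole_kernel(gs, tr$voxel_size_mm)
  cfg <- test_recon_config()
  mask <- tr$brain_mask

  z <- dipole_inversion_ilsqr(array(0, gs), d, cfg, valid_mask = mask)
  expect_equal(max(abs(z)), 0)

  f <- forward_field(tr$chi_ppm, d) * mask
  chi1 <- suppressWarnings(dipole_inversion_ilsqr(f, d, cfg,
                                                  valid_mask = mask))
  chi2 <- suppressWarnings(dipole_inversion_ilsqr(2 * f, d, cfg,
                                                  valid_mask = mask))
  expect_lt(max(abs(chi2 - 2 * chi1)) / max(abs(chi1)), 1e-6)

  # data fidelity: the recovered map re-predicts the masked field
  resid <- (forward_field(chi1, d) - f) * mask
  expect_lt(sqrt(mean(resid[mask]^2)) / sqrt(mean(f[mask]^2)), 0.05)

  # voxels outside the valid mask stay exactly zero
  expect_true(all(chi1[!mask] == 0))
})

test_that("zero-referencing subtracts the ventricle mean exactly", {
  gs <- c(8, 8, 8)
  vent <- array(FALSE, gs); vent[3:5, 3:5, 3:5] <- TRUE
  zm <- zero_reference(array(5, gs), vent)
  expect_equal(zm$reference_offset_ppm, 5)
  expect_equal(max(abs(zm$chi_ppm)), 0)

  set.seed(1)
  chi <- array(stats::rnorm(prod(gs)), gs)
  zm <- zero_reference(chi, vent)
  expect_lt(abs(mean(zm$chi_ppm[vent])), 1e-12)
  expect_error(zero_reference(chi, array(FALSE, gs)), "empty")
})

test_that("spectral operators commute with circular shifts", {
  gs <- c(24, 24, 24)
  set.seed(7)
  x <- array(stats::rnorm(prod(gs)), gs)
  d <- dipole_kernel(gs, c(1, 1, 1))
  sh <- function(a, by) a[c((by + 1):gs[1], 1:by), , ]
  expect_equal(forward_field(sh(x, 5), d), sh(forward_field(x, d), 5),
               tolerance = 1e-10)
})

test_that("full reconstruction is deterministic and refuses to emit NaN", {
  tr <- small_truth()
  gre <- simulate_gre(tr, acquisition_params(snr = 60, seed = 5,
                                             n_echoes = 4))
  cfg <- test_recon_config()
  r1 <- suppressWarnings(reconstruct_qsm(gre, tr$brain_mask,
                                         tr$ventricle_mask, cfg))
  r2 <- suppressWarnings(reconstruct_qsm(gre, tr$brain_mask,
                                         tr$ventricle_mask, cfg))
  expect_identical(r1$chi_ppm, r2$chi_ppm)
  expect_true(all(is.finite(r1$chi_ppm)))
  expect_lt(abs(mean(r1$chi_ppm[tr$ventricle_mask & r1$valid_mask])), 1e-9)

  # zero-signal input: all-zero map with a warning, never NaN
  gre0 <- gre
  gre0$magnitude[] <- 0
  expect_warning(r0 <- reconstruct_qsm(gre0, tr$brain_mask,
                                       tr$ventricle_mask, cfg),
                 "zero-signal")
  expect_true(all(r0$chi_ppm == 0))
})
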