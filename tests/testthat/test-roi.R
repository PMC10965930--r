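make_slab_atlas <- function(w = 5, vox = c(1, 1, 1)) {
  labels <- array(0L, c(12, 12, 3))
  labels[4:(3 + w), 4:(3 + w), 2] <- 1L
  voi_atlas(labels, data.frame(label = 1L, structure = "caudate",
                               hemisphere = "left"), vox)
}

test_that("two-pixel in-plane erosion of a 5x5 square leaves the centre pixel", {
  at <- make_slab_atlas(5)
  er <- erode_voi_inplane(at, "caudate", n_pixels = 2)
  expect_equal(sum(er), 1)
  expect_true(er[6, 6, 2])

  # a 3x3 square is fully eroded and errors, naming the structure
  expect_error(erode_voi_inplane(make_slab_atlas(3), "caudate", 2),
               "caudate")

  # erosion result is a subset and monotone in n_pixels
  at7 <- make_slab_atlas(7)
  full <- at7$labels == 1
  e1 <- erode_voi_inplane(at7, "caudate", 1)
  e2 <- erode_voi_inplane(at7, "caudate", 2)
  expect_true(all(!e1 | full))
  expect_true(all(!e2 | e1))
  expect_lte(sum(e2), sum(e1))
})

test_that("in-plane erosion matches an independent morphology implementation", {
  tr <- small_truth()
  er <- erode_voi_inplane(tr$atlas, "putamen", n_pixels = 2)
  cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  ref <- array(FALSE, dim(tr$atlas$labels))
  m <- array(tr$atlas$labels %in%
               tr$atlas$label_map$label[tr$atlas$label_map$structure ==
                                          "putamen"],
             dim(tr$atlas$labels))
  for (z in seq_len(dim(m)[3])) {
    sl <- m[, , z] * 1
    sl <- EBImage::erode(EBImage::erode(sl, cross), cross)
    ref[, , z] <- sl > 0.5
  }
  expect_identical(er, ref)
})

test_that("measurements follow the erode-for-chi, full-count-for-volume rule", {
  # uniform susceptibility inside a structure measures exactly
  labels <- array(0L, c(16, 16, 5))
  labels[3:9, 3:9, 2:4] <- 1L        # left, 7x7 in-plane
  labels[3:9, 3:9, 5] <- 2L          # right, single slice (smaller)
  at <- voi_atlas(labels, data.frame(label = 1:2,
                                     structure = "thalamus",
                                     hemisphere = c("left", "right")),
                  c(0.8, 0.8, 0.8))
  chi <- array(0, dim(labels))
  chi[labels > 0] <- 0.1
  m <- extract_measurements(chi, at)
  expect_equal(m$susceptibility_ppm, 0.1)

  # volume: bilateral mean of uneroded voxel counts times voxel volume
  nl <- sum(labels == 1); nr <- sum(labels == 2)
  expect_equal(m$volume_mm3, (nl + nr) / 2 * 0.512)

  # arithmetic worked example: 100 and 120 voxels at 0.8 mm isotropic
  expect_equal((100 + 120) / 2 * 0.8^3, 56.32)

  # adding a constant shifts every susceptibility by exactly that constant
  m2 <- extract_measurements(chi + 0.05, at)
  expect_equal(m2$susceptibility_ppm, m$susceptibility_ppm + 0.05)
  # volume invariant to the susceptibility values
  expect_equal(m2$volume_mm3, m$volume_mm3)

  # susceptibility invariant to voxel size; volume scales with it
  at2 <- voi_atlas(labels, at$label_map, c(1, 1, 1))
  m3 <- extract_measurements(chi, at2)
  expect_equal(m3$susceptibility_ppm, m$susceptibility_ppm)
  expect_equal(m3$volume_mm3, (nl + nr) / 2)

  expect_error(extract_measurements(array(0, c(4, 4, 4)), at), "mismatch")
})

test_that("cohort extraction reports exclusions and keeps the cohort schema", {
  tr <- small_truth()
  chi <- tr$chi_ppm
  good <- list(chi = chi, atlas = tr$atlas, subject_id = "s1", group = "HC")
  bad <- list(chi = array(0, c(4, 4, 4)), atlas = tr$atlas,
              subject_id = "s2", group = "MDD")   # grid mismatch -> fails
  tab <- cohort_extract(list(good, bad,
                             modifyList(good, list(subject_id = "s3",
                                                   group = "SCZ"))))
  expect_equal(nrow(tab), 4)    # 2 structures x 2 surviving subjects
  excl <- attr(tab, "exclusions")
  expect_equal(excl$subject_id, "s2")

  sim <- simulate_cohort(cohort_spec(seed = 1))
  expect_identical(names(tab), names(sim))
})
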