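test_that("voxelized ground-truth ICV matches the analytic ellipsoid volume", {
  # pure ellipsoid (taper and petalia off): 20 x 25 x 20 mm semi-axes at
  # 1 mm spacing -> (4/3) pi abc = 41.89 cm^3 within 2%
  sp <- phantom_spec("20w", semi_axes = c(20, 25, 20), spacing = c(1, 1, 1),
                     grid_shape = c(64, 64, 64), taper = 0,
                     petalia = c(0, 0), seed = 3)
  ph <- make_head_phantom(sp)
  expect_equal(ph$true_icv_cm3, 4 / 3 * pi * 20 * 25 * 20 / 1000,
               tolerance = 0.02)
  # the ICV identity holds exactly
  expect_equal(ph$true_icv_cm3, mask_volume_cm3(ph$mask))
})

test_that("phantom generation is deterministic and mirror-consistent", {
  s <- phantom_spec("20w", seed = 7)
  a <- make_head_phantom(s)
  b <- make_head_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)

  # flipping the orientation label mirrors the data, same true ICV
  sR <- phantom_spec("20w", seed = 7, orientation_label = "Right")
  r <- make_head_phantom(sR)
  expect_equal(r$true_icv_cm3, a$true_icv_cm3)
  n1 <- dim(a$volume$data)[1]
  expect_identical(r$volume$data, a$volume$data[n1:1, , , drop = FALSE])

  # shadow sector and sweep padding affect intensities but not true ICV
  s_clean <- phantom_spec("20w", seed = 7, shadow_sector = NULL,
                          sweep = FALSE)
  clean <- make_head_phantom(s_clean)
  expect_equal(clean$true_icv_cm3, a$true_icv_cm3)
  expect_gt(mean(a$volume$data == 0), 0)     # padding/shadow present
  expect_equal(mean(clean$volume$data == 0), 0)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec("20w", shell_thickness = 0), "shell_thickness")
  expect_error(phantom_spec("20w", semi_axes = c(60, 60, 60)), "margin")
  expect_error(phantom_spec("20w", spacing = c(0, 1, 1)), "spacing")
})

test_that("cohorts are seeded, scaled, and carry exact ground truth", {
  base <- phantom_spec("20w", seed = 1)
  coh <- make_cohort(4, base, scale_range = c(1, 1), jitter = FALSE,
                     seed = 5)
  expect_length(coh$subjects, 4)
  expect_equal(nrow(coh$manifest), 4)
  # scale 1, no jitter: subjects differ only in speckle -> identical masks
  for (i in 2:4)
    expect_identical(coh$subjects[[i]]$mask$data,
                     coh$subjects[[1]]$mask$data)
  expect_false(identical(coh$subjects[[1]]$volume$data,
                         coh$subjects[[2]]$volume$data))

  # recorded truth equals mask voxel count times voxel volume
  for (s in coh$subjects)
    expect_equal(s$true_icv_cm3, mask_volume_cm3(s$mask))

  # same seed reproduces; different seed differs
  coh2 <- make_cohort(4, base, scale_range = c(1, 1), jitter = FALSE,
                      seed = 5)
  expect_identical(coh2$manifest, coh$manifest)
  coh3 <- make_cohort(4, base, scale_range = c(1, 1), jitter = FALSE,
                      seed = 6)
  expect_false(identical(coh3$subjects[[1]]$volume$data,
                         coh$subjects[[1]]$volume$data))

  expect_error(make_cohort(3, base, scale_range = c(1.1, 0.9)),
               "scale_range")
})

test_that("isotropic scaling multiplies true ICV by the cube of the factor", {
  s1 <- phantom_spec("20w", seed = 2, speckle_sigma = 0,
                     semi_axes = c(22, 28, 24))
  s2 <- phantom_spec("20w", seed = 2, speckle_sigma = 0,
                     semi_axes = c(22, 28, 24) * 1.1)
  r <- make_head_phantom(s2)$true_icv_cm3 / make_head_phantom(s1)$true_icv_cm3
  expect_equal(r, 1.1^3, tolerance = 0.02)
})
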