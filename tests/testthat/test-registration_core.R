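test_that("blur smooths without changing dimensions", {
  ph <- test_phantom(seed = 6, grid = 24)
  v <- ph$volume
  expect_identical(blur(v, 0)$data, v$data)
  for (sg in c(0.5, 2, 4))
    expect_identical(dim(blur(v, sg)$data), dim(v$data))
  # voxelwise variance strictly decreases on a speckle phantom
  expect_lt(var(as.numeric(blur(v, 2)$data)), var(as.numeric(v$data)))
  expect_error(blur(v, -1), "sigma")
})

test_that("intensity metrics match a brute-force triple-loop oracle", {
  a <- rand_volume(c(8, 8, 8), seed = 21)
  b <- rand_volume(c(8, 8, 8), seed = 22)
  expect_equal(intensity_metric(a, b, "ssd"), ssd_oracle(a, b),
               tolerance = 1e-10)
  expect_equal(intensity_metric(a, b, "ncc"), ncc_oracle(a, b),
               tolerance = 1e-10)

  expect_equal(intensity_metric(a, a, "ssd"), 0)
  expect_equal(intensity_metric(a, a, "ncc"), 1)

  # constant offset: ssd positive, ncc still exactly 1
  shifted <- a; shifted$data <- a$data + 17
  expect_gt(intensity_metric(a, shifted, "ssd"), 0)
  expect_equal(intensity_metric(a, shifted, "ncc"), 1, tolerance = 1e-12)

  const <- new_volume(array(5, c(8, 8, 8)))
  expect_error(intensity_metric(a, const, "ncc"), "constant")
})

test_that("registering a volume to itself stays at identity", {
  ph <- test_phantom(seed = 7, grid = 32)
  v <- replace_zero_voxels(ph$volume)
  pts <- voxel_centers_test(list(dim = dim(v$data), spacing = v$spacing,
                                 origin = v$origin))
  pts <- pts[, seq(1, ncol(pts), by = 199)]
  for (fam in c("translation", "rigid", "similarity", "affine", "bspline")) {
    p <- fast_params(fam, seed = 31, max_iterations = 20L)
    r <- register(v, v, p)
    moved <- transform_points(r$transform, pts) - pts
    expect_lt(max(abs(moved)), 0.1 * min(v$spacing))  # within 0.1 voxel
  }
})

test_that("known translations and rotations are recovered", {
  ph <- test_phantom(seed = 7, grid = 48)
  v <- replace_zero_voxels(ph$volume)
  ctr <- world_center(v)

  # translation of (4, -2, 3) voxels recovered within 0.5 voxel
  tr <- translation_transform(c(4, -2, 3) * v$spacing)
  mv <- apply_transform(v, tr)
  r <- register(v, mv, fast_params("translation", seed = 3))
  expect_lt(max(abs(r$transform$offset - (-c(4, -2, 3) * v$spacing))),
            0.5 * min(v$spacing))

  # 5-degree rotation recovered within 0.5 degree
  rot <- linear_transform(euler_matrix(c(5 * pi / 180, 0, 0)), c(0, 0, 0),
                          ctr, "rigid")
  mvr <- apply_transform(v, rot)
  rr <- register(v, mvr, fast_params("rigid", seed = 3))
  ang <- acos(pmin(1, (sum(diag(rr$transform$matrix)) - 1) / 2)) * 180 / pi
  expect_lt(abs(ang - 5), 0.5)
})

test_that("similarity registration recovers global scale within 3 percent", {
  ph <- test_phantom(seed = 11, grid = 48)
  v <- replace_zero_voxels(ph$volume)
  ctr <- world_center(v)
  for (s in c(0.9, 1.1)) {
    tr <- linear_transform(s * diag(3), c(0, 0, 0), ctr, "similarity")
    mv <- apply_transform(v, tr)
    r <- register(v, mv, fast_params("similarity", seed = 4))
    s_rec <- det(r$transform$matrix)^(1 / 3)
    expect_lt(abs(s_rec * s - 1), 0.03)  # recovered inverse scale
  }
})

test_that("registration is deterministic given the seed and never worsens
           the metric", {
  ph <- test_phantom(seed = 9, grid = 32)
  v <- replace_zero_voxels(ph$volume)
  mv <- apply_transform(v, translation_transform(c(3, 1, -2)))
  p <- fast_params("affine", seed = 77, max_iterations = 25L)
  r1 <- register(v, mv, p)
  r2 <- register(v, mv, p)
  expect_identical(r1$transform, r2$transform)
  expect_identical(r1$iterations_used, r2$iterations_used)

  # final metric no worse than the metric at the initial (identity) guess
  p0 <- fast_params("affine", seed = 77, max_iterations = 1L)
  r0 <- register(v, mv, p0)
  expect_lte(r1$final_metric, r0$final_metric + 1e-12)
})

test_that("registration parameters are validated", {
  expect_error(registration_params("affine", pyramid_schedule = c(1, 2)),
               "nonincreasing")
  expect_error(registration_params("affine", sp_a = 0), "sp_a")
  expect_error(registration_params("rigid", metric = "mi"), "arg")
})
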