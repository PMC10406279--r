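test_that("apply_transform resamples exactly for identity and voxel shifts", {
  v <- rand_volume(c(12, 12, 12), seed = 5, lo = 1, hi = 100)
  idt <- translation_transform(c(0, 0, 0))
  expect_equal(apply_transform(v, idt)$data, v$data)

  # translation by exactly +2 voxels along axis 1 equals an index shift
  tr <- translation_transform(c(2, 0, 0))
  w <- apply_transform(v, tr)
  expect_equal(w$data[1:10, , ], v$data[3:12, , ])
})

test_that("uniform scaling changes mask volume by the cube of the factor", {
  m <- ball_mask(c(48, 48, 48), radius = 20)
  ctr <- world_center(m)
  # pull-back scale s=2 about the center: warped ball radius halves
  s2 <- linear_transform(2 * diag(3), c(0, 0, 0), ctr, "similarity")
  w <- warp_mask(m, s2)
  expect_equal(sum(w$data) / sum(m$data), (1 / 2)^3, tolerance = 0.03)

  # s = 1.2 magnification: voxel count ratio within 2% of 1.2^3
  s12 <- linear_transform(diag(3) / 1.2, c(0, 0, 0), ctr, "similarity")
  w12 <- warp_mask(m, s12)
  expect_equal(sum(w12$data) / sum(m$data), 1.2^3, tolerance = 0.02)

  # identity and integer-voxel translation preserve interior masks exactly
  expect_identical(warp_mask(m, translation_transform(c(0, 0, 0)))$data,
                   m$data)
  w_tr <- warp_mask(m, translation_transform(c(3, -2, 1)))
  expect_equal(sum(w_tr$data), sum(m$data))
})

test_that("compose collapses adjacent linear members exactly", {
  t1 <- translation_transform(c(3, -1, 2))
  t2 <- translation_transform(c(-3, 1, -2))
  cc <- compose(transform_chain(t1, t2))
  expect_length(cc$members, 1)
  expect_lt(max(abs(cc$members[[1]]$offset)), 1e-10)
  expect_lt(max(abs(cc$members[[1]]$matrix - diag(3))), 1e-10)

  r <- linear_transform(euler_matrix(c(0.2, -0.1, 0.3)), c(1, 2, 3),
                        c(10, 10, 10), "rigid")
  ri <- invert(r)
  cri <- compose(transform_chain(r, ri))
  pts <- matrix(runif(30, 0, 40), 3)
  expect_lt(max(abs(transform_points(cri, pts) - pts)), 1e-10)

  # collapsed chain maps random points identically to the original chain
  set.seed(8)
  ch <- transform_chain(
    translation_transform(c(1, 2, -1)),
    linear_transform(euler_matrix(c(0.1, 0.05, -0.2)), c(0.5, 0, 1),
                     c(20, 20, 20), "rigid"),
    linear_transform(1.1 * diag(3), c(0, -1, 0), c(20, 20, 20),
                     "similarity"))
  cc2 <- compose(ch)
  expect_length(cc2$members, 1)
  pts <- matrix(runif(300, -10, 50), 3)
  expect_lt(max(abs(transform_points(cc2, pts) - transform_points(ch, pts))),
            1e-8)
})

test_that("linear inversion is closed-form and exact", {
  tr <- invert(translation_transform(c(3, -1, 2)))
  expect_equal(tr$offset, c(-3, 1, -2))

  s <- linear_transform(1.25 * diag(3), c(0, 0, 0), c(5, 5, 5), "similarity")
  si <- invert(s)
  expect_equal(det(si$matrix)^(1 / 3), 0.8, tolerance = 1e-12)
})

test_that("B-spline inversion matches a per-voxel brute-force root search", {
  geom <- list(dim = c(24, 24, 24), spacing = c(1, 1, 1),
               origin = c(0, 0, 0))
  set.seed(11)
  tr <- bspline_transform(c(6, 6, 6), world_bbox_test(geom))
  tr$coefficients[] <- rnorm(length(tr$coefficients), 0, 0.6)  # max ~2 voxels
  inv <- invert(tr, spacing = c(1, 1, 1), tolerance = 0.05)

  # round-trip residual at voxel centers is within tolerance
  pts <- voxel_centers_test(geom)
  rt <- transform_points(tr, transform_points(inv, pts))
  expect_lt(max(sqrt(colSums((rt - pts)^2))), 0.1)

  # brute-force oracle: solve T(y) = x by direct minimization at a sample
  # of interior points, independent of the fixed-point machinery
  set.seed(12)
  sel <- sample(ncol(pts), 25)
  for (i in sel) {
    x <- pts[, i]
    obj <- function(y) sum((transform_points(tr, matrix(y, 3)) - x)^2)
    y_bf <- optim(x, obj, method = "BFGS",
                  control = list(reltol = 1e-14))$par
    y_inv <- transform_points(inv, matrix(x, 3))
    expect_lt(sqrt(sum((y_inv - y_bf)^2)), 0.06)
  }
})

test_that("chain inversion equals member-wise inversion in reverse order", {
  r <- linear_transform(euler_matrix(c(0.1, 0.2, -0.15)), c(2, -1, 0.5),
                        c(12, 12, 12), "rigid")
  t <- translation_transform(c(-4, 2, 1))
  ch <- transform_chain(t, r)
  inv_chain <- invert(ch)
  manual <- transform_chain(invert(r), invert(t))
  pts <- matrix(runif(90, 0, 24), 3)
  expect_lt(max(abs(transform_points(inv_chain, pts) -
                      transform_points(manual, pts))), 1e-6)
  # invert(compose(chain)) residual under 0.05 voxel (1 mm spacing here)
  rt <- transform_points(ch, transform_points(invert(compose(ch)), pts))
  expect_lt(max(sqrt(colSums((rt - pts)^2))), 0.05)
})

test_that("double inversion reproduces the transform's action", {
  geom <- list(dim = c(20, 20, 20), spacing = c(1, 1, 1),
               origin = c(0, 0, 0))
  set.seed(13)
  tr <- bspline_transform(c(5, 5, 5), world_bbox_test(geom))
  tr$coefficients[] <- rnorm(length(tr$coefficients), 0, 0.4)
  tol <- 0.05
  tri <- invert(tr, spacing = c(1, 1, 1), tolerance = tol)
  trii <- invert(tri, spacing = c(1, 1, 1), tolerance = tol)
  pts <- voxel_centers_test(geom)[, seq(1, 8000, by = 37)]
  expect_lt(max(sqrt(colSums((transform_points(trii, pts) -
                                transform_points(tr, pts))^2))), 2 * tol + 0.05)
})

test_that("rigid transforms nearly preserve the volume of large ball masks", {
  m <- ball_mask(c(40, 40, 40), radius = 12)
  r <- linear_transform(euler_matrix(c(0.15, -0.1, 0.2)), c(1.2, -0.7, 0.4),
                        world_center(m), "rigid")
  w <- warp_mask(m, r)
  expect_lt(abs(sum(w$data) / sum(m$data) - 1), 0.02)
})

test_that("transforms serialize to JSON and back", {
  r <- linear_transform(euler_matrix(c(0.1, 0, 0)), c(1, 2, 3),
                        c(5, 5, 5), "rigid")
  geom <- list(dim = c(12, 12, 12), spacing = c(2, 2, 2),
               origin = c(0, 0, 0))
  b <- bspline_transform(c(8, 8, 8), world_bbox_test(geom))
  b$coefficients[] <- seq_len(length(b$coefficients)) / 100
  ch <- transform_chain(r, b)
  f <- file.path(tempdir(), "chain.json")
  write_transform(ch, f)
  ch2 <- read_transform(f)
  pts <- matrix(runif(60, 0, 22), 3)
  expect_equal(transform_points(ch2, pts), transform_points(ch, pts),
               tolerance = 1e-12)
})

test_that("singular linear transforms are rejected", {
  expect_error(linear_transform(matrix(0, 3, 3)), "singular")
})
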