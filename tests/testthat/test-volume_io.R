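test_that("NIfTI read/write round trip is lossless for data and geometry", {
  v <- rand_volume(c(4, 4, 4), seed = 2, spacing = c(0.5, 0.5, 0.5))
  expect_equal(prod(dim(v$data)), 64)
  expect_equal(voxel_volume_mm3(v), 0.125)
  f <- file.path(tempdir(), "rt.nii.gz")
  write_volume(v, f)
  w <- read_volume(f)
  expect_identical(w$data, v$data)
  expect_equal(w$spacing, v$spacing)
  expect_equal(w$origin, v$origin)

  # mask round trip preserves the {0,1} value set and integer storage
  m <- ball_mask(c(10, 10, 10), radius = 3)
  fm <- file.path(tempdir(), "rt_mask.nii.gz")
  write_volume(m, fm)
  m2 <- read_volume(fm, mask = TRUE)
  expect_true(all(m2$data %in% c(0, 1)))
  expect_identical(m2$data, m$data)

  # overwriting an existing file succeeds
  expect_silent(write_volume(v, f))
  expect_identical(read_volume(f)$data, v$data)
})

test_that("read_volume rejects missing files and non-3D images", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "missing")
  f4 <- file.path(tempdir(), "vol4d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(3, 3, 3, 2))), f4)
  expect_error(read_volume(f4), "expected 3D")
})

test_that("volume constructors enforce their invariants", {
  expect_error(new_volume(matrix(1, 3, 3)), "3")
  expect_error(new_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "spacing")
  expect_error(new_volume(array(c(1, NA), c(2, 2, 2))), "finite")
  expect_error(new_mask(array(2, c(2, 2, 2))), "0 or 1")
})

test_that("replace_zero_voxels fills zeros with the nonzero mean", {
  v <- new_volume(array(c(0, 10, 20, 0, 0, 0, 0, 0), c(2, 2, 2)))
  r <- replace_zero_voxels(v)
  expect_equal(r$data[1, 1, 1], 15)           # mean of the nonzero voxels
  expect_equal(r$data[2, 1, 1], 10)
  expect_equal(r$data[1, 2, 1], 20)
  expect_true(all(r$data[r$data != 10 & r$data != 20] == 15))

  # a volume with no zeros is returned unchanged
  w <- rand_volume(c(4, 4, 4), seed = 3, lo = 1, hi = 9)
  expect_identical(replace_zero_voxels(w)$data, w$data)

  # idempotent when the nonzero mean is itself nonzero
  expect_identical(replace_zero_voxels(r)$data, r$data)

  expect_error(replace_zero_voxels(new_volume(array(0, c(2, 2, 2)))),
               "all zero")
})

test_that("orientation canonicalization mirrors the left-right axis", {
  ph <- test_phantom(seed = 4, grid = 24)
  v <- ph$volume                          # generated as "Left"
  expect_identical(canonicalize_orientation(v, "Left")$data, v$data)

  r <- canonicalize_orientation(v, "Right")
  expect_equal(r$orientation_label, "Right")
  # histogram (value multiset) preserved exactly
  expect_identical(sort(as.numeric(r$data)), sort(as.numeric(v$data)))
  # involution: flipping back restores the original
  expect_identical(canonicalize_orientation(r, "Left")$data, v$data)

  # off-center marker: left-right centroid coordinate changes sign about
  # the grid center after mirroring
  m <- new_volume(array(0, c(9, 9, 9)) + 1, orientation_label = "Left")
  m$data[2, 5, 5] <- 100
  cen <- function(x) {
    w <- x$data / sum(x$data)
    idx <- arrayInd(seq_along(w), dim(x$data))
    sum(idx[, 1] * w) - 5              # relative to grid center
  }
  before <- cen(m)
  after <- cen(canonicalize_orientation(m, "Right"))
  expect_lt(before, 0)
  expect_equal(after, -before, tolerance = 1e-10)

  v$orientation_label <- "unknown"
  expect_error(canonicalize_orientation(v, "Left"), "manual")
})
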