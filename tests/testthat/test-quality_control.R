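test_that("overlap similarity matches its closed cases and the oracle", {
  a <- rand_volume(c(8, 8, 8), seed = 41)
  expect_equal(overlap_similarity(a, a), 1.0)

  # disjoint supports -> exactly 0
  lo <- new_volume(array(c(rep(1, 256), rep(0, 256)), c(8, 8, 8)))
  hi <- new_volume(array(c(rep(0, 256), rep(1, 256)), c(8, 8, 8)))
  expect_equal(overlap_similarity(lo, hi), 0.0)

  # a = (1, 0, ...), b = (1, 1, 0, ...) -> 1/sqrt(2)
  x <- new_volume(array(c(1, rep(0, 7)), c(2, 2, 2)))
  y <- new_volume(array(c(1, 1, rep(0, 6)), c(2, 2, 2)))
  expect_equal(overlap_similarity(x, y), 1 / sqrt(2), tolerance = 1e-12)

  # symmetry, positive-scale invariance, bounds, brute-force agreement
  for (seed in c(1, 2, 3)) {
    u <- rand_volume(c(8, 8, 8), seed = seed)
    w <- rand_volume(c(8, 8, 8), seed = seed + 100)
    s <- overlap_similarity(u, w)
    expect_equal(s, overlap_similarity(w, u))
    w3 <- w; w3$data <- 3.7 * w$data
    expect_equal(overlap_similarity(u, w3), s, tolerance = 1e-12)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, similarity_oracle(u, w), tolerance = 1e-12)
  }

  z <- new_volume(array(0, c(8, 8, 8)))
  expect_error(overlap_similarity(a, z), "all-zero")
})

test_that("the SD gate implements the two-value sample SD convention", {
  expect_equal(two_value_sd(80, 90), abs(80 - 90) / sqrt(2))
  expect_equal(two_value_sd(80, 90), sd(c(80, 90)))

  g0 <- sd_gate(85, 85, "fraction_of_mean", 0.10)
  expect_equal(g0$sd_value, 0)
  expect_equal(g0$verdict, "pass")
  expect_equal(sd_gate(85, 85, "absolute", 10)$verdict, "pass")

  # fraction rule: ICVs 80 and 90, fraction 0.10 -> threshold 8.5, SD 7.071
  g <- sd_gate(80, 90, "fraction_of_mean", 0.10)
  expect_equal(g$sd_threshold, 8.5)
  expect_equal(g$sd_value, 7.071, tolerance = 1e-4)
  expect_equal(g$verdict, "pass")

  # absolute rule: ICVs 240 and 275 against 20 cm^3 -> SD 24.75, retry
  ga <- sd_gate(240, 275, "absolute", 20)
  expect_equal(ga$sd_value, 24.749, tolerance = 1e-3)
  expect_equal(ga$verdict, "retry")

  # monotone: widening the disagreement never flips retry back to pass
  verdicts <- vapply(seq(0, 40, by = 5), function(d)
    sd_gate(100, 100 + d, "absolute", 15)$verdict, character(1))
  first_retry <- match("retry", verdicts)
  expect_true(all(verdicts[seq_along(verdicts) >= first_retry] == "retry"))

  expect_error(sd_gate(-1, 50, "absolute", 10), "positive")
})

test_that("the similarity floor is inclusive at 0.7", {
  expect_true(similarity_gate(0.71))
  expect_true(similarity_gate(0.7))     # "below 0.7" fails, 0.7 passes
  expect_false(similarity_gate(0.42))
  expect_false(similarity_gate(0.699999))
})

test_that("repeated median filtering smooths masks as expected", {
  ones <- new_mask(array(1, c(10, 10, 10)))
  expect_identical(smooth_mask(ones)$data, ones$data)

  # a single isolated voxel disappears after one pass
  iso <- new_mask(array(0, c(9, 9, 9)))
  iso$data[5, 5, 5] <- 1
  expect_equal(sum(smooth_mask(iso, repeats = 1)$data), 0)

  # a 20^3 solid cube changes volume by < 5% after 3 passes
  cube <- new_mask(array(0, c(30, 30, 30)))
  cube$data[6:25, 6:25, 6:25] <- 1
  sm <- smooth_mask(cube, kernel = 3, repeats = 3)
  expect_lt(abs(sum(sm$data) / sum(cube$data) - 1), 0.05)
  expect_true(all(sm$data %in% c(0, 1)))

  # deterministic
  expect_identical(smooth_mask(cube)$data, smooth_mask(cube)$data)

  expect_error(smooth_mask(cube, kernel = 4), "odd")
})

test_that("overlay rendering writes one contour image per plane", {
  ph <- test_phantom(seed = 14, grid = 24)
  out <- file.path(tempdir(), "overlays")
  files <- render_overlay(ph$volume, ph$mask, out, subject_id = "T1")
  expect_length(files, 3)
  expect_true(all(file.exists(files)))

  empty <- new_mask(array(0, dim(ph$mask$data)), ph$mask$spacing)
  expect_warning(render_overlay(ph$volume, empty, out, subject_id = "T2"),
                 "empty mask")
  expect_error(render_overlay(ph$volume, ph$mask, out, subject_id = "T3",
                              slice_index = 99), "out of range")
})
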