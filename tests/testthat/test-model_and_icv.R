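# shared small model fixture (built once per file)
local_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- make_cohort(4, phantom_spec("20w", seed = 1),
                         scale_range = c(0.97, 1.03), seed = 42)
      scans <- lapply(coh$subjects, function(s)
        replace_zero_voxels(s$volume))
      masks <- lapply(coh$subjects, function(s) s$mask)
      build <- build_model(scans,
                           params = model_stage_params("fast", seed = 9))
      cache <<- list(model = attach_icv_mask(build, masks), build = build,
                     cohort = coh)
    }
    cache
  }
})

test_that("averaging identical phantoms reproduces the phantom", {
  sp <- phantom_spec("20w", seed = 5, grid_shape = c(32, 32, 32),
                     spacing = c(3, 3, 3), semi_axes = c(26, 33, 28) * 0.85,
                     speckle_sigma = 0)
  ph <- make_head_phantom(sp)
  v <- replace_zero_voxels(ph$volume)
  scans <- list(v, v, v, v, v)
  params <- model_stage_params("fast", seed = 3)
  params <- lapply(params, function(p) { p$max_iterations <- 10L; p })
  build <- build_model(scans, params = params)
  expect_gt(cor(as.numeric(build$template$data), as.numeric(v$data)), 0.99)
  expect_equal(build$n_subjects, 5)
})

test_that("groupwise averaging is sharper than the naive unaligned mean", {
  sp <- phantom_spec("20w", seed = 6, grid_shape = c(40, 40, 40),
                     spacing = c(2.4, 2.4, 2.4),
                     semi_axes = c(26, 33, 28) * 0.85,
                     speckle_sigma = 0.1)
  ph <- make_head_phantom(sp)
  seed_scan <- replace_zero_voxels(ph$volume)
  shifts <- list(c(0, 0, 0), c(6, -4, 2), c(-4, 6, -6))
  scans <- lapply(shifts, function(s)
    apply_transform(seed_scan, translation_transform(s)))
  params <- model_stage_params("fast", seed = 4)[1:4]  # affine rounds only
  build <- build_model(scans, params = params)
  naive <- (scans[[1]]$data + scans[[2]]$data + scans[[3]]$data) / 3
  c_grp <- cor(as.numeric(build$template$data), as.numeric(seed_scan$data))
  c_naive <- cor(as.numeric(naive), as.numeric(seed_scan$data))
  expect_gt(c_grp, c_naive)
})

test_that("study-sized cohorts (13, 11, 17 scans) are accepted", {
  # input validation and the full stage plan run on miniature volumes
  mini <- function(seed) {
    set.seed(seed)
    new_volume(array(runif(512, 10, 100), c(8, 8, 8)),
               orientation_label = "Left")
  }
  tiny_params <- model_stage_params("fast", seed = 1)[c(1, 5)]
  tiny_params <- lapply(tiny_params, function(p) {
    p$max_iterations <- 1L; p$pyramid_schedule <- 0; p$max_samples <- 128L
    p$bspline_grid_spacing <- 4; p
  })
  for (n in c(13, 11, 17)) {
    scans <- lapply(seq_len(n), mini)
    build <- build_model(scans, params = tiny_params)
    expect_equal(build$n_subjects, n)
  }
  # mixed orientations abort
  scans <- lapply(1:3, mini)
  scans[[2]]$orientation_label <- "Right"
  expect_error(build_model(scans, params = tiny_params), "orientation")
  expect_error(build_model(scans[1], params = tiny_params), "at least 2")
})

test_that("the ICV identity and the mask geometry hold on pipeline output", {
  fx <- local_model()
  model <- fx$model
  res <- run_pipeline(model$template, model,
                      pipeline_config("minc_style", profile = "fast",
                                      seed = 5))
  # identity subject: ICV within 1% of the model mask's own volume
  expect_equal(res$icv_cm3, mask_volume_cm3(model$icv_mask),
               tolerance = 0.01)
  # exact voxel-count identity on the subject grid
  expect_equal(res$icv_cm3,
               sum(res$subject_mask$data) *
                 voxel_volume_mm3(res$subject_mask) / 1000)
  expect_true(res$converged)
})

test_that("a 10% magnified subject yields 1.331 times the mask volume", {
  fx <- local_model()
  model <- fx$model
  ctr <- world_center(model$template)
  S <- linear_transform(diag(3) / 1.10, c(0, 0, 0), ctr, "similarity")
  sub <- apply_transform(model$template, S)
  res <- run_pipeline(sub, model,
                      pipeline_config("minc_style", profile = "fast",
                                      seed = 5))
  expect_equal(res$icv_cm3, 1.331 * mask_volume_cm3(model$icv_mask),
               tolerance = 0.05)
})

test_that("measured ICV increases monotonically with subject scale", {
  fx <- local_model()
  model <- fx$model
  ctr <- world_center(model$template)
  icvs <- vapply(c(0.9, 1.0, 1.1), function(s) {
    S <- linear_transform(diag(3) / s, c(0, 0, 0), ctr, "similarity")
    sub <- apply_transform(model$template, S)
    run_pipeline(sub, model,
                 pipeline_config("minc_style", profile = "fast",
                                 seed = 5))$icv_cm3
  }, numeric(1))
  expect_true(all(diff(icvs) > 0))
})

test_that("cross-orientation pairing is refused rather than mirrored", {
  fx <- local_model()
  sub <- fx$cohort$subjects[[1]]$volume
  sub$orientation_label <- "Right"
  expect_error(run_pipeline(sub, fx$model,
                            pipeline_config("minc_style",
                                            profile = "fast", seed = 1)),
               "orientation")
})

test_that("consensus arithmetic and order invariance hold", {
  fx <- local_model()
  sub <- fx$cohort$subjects[[2]]$volume
  cr <- measure_icv_consensus(sub, fx$model, profile = "fast", seed = 8)
  a <- cr$result_minc_style$icv_cm3
  b <- cr$result_elastix_style$icv_cm3
  expect_equal(cr$mean_icv_cm3, mean(c(a, b)))
  expect_equal(cr$sd_icv_cm3, abs(a - b) / sqrt(2))
  expect_equal(cr$sd_icv_cm3, sd(c(a, b)))      # two-value sample SD
  expect_equal(cr$mean_icv_cm3, mean(c(b, a)))  # order-invariant by formula
  expect_true(cr$qc$verdict %in% c("pass", "excluded"))
  expect_equal(cr$similarity_score, cr$result_elastix_style$similarity)
})

test_that("pipeline configs enforce the fixed stage plans", {
  cm <- pipeline_config("minc_style", profile = "fast")
  expect_equal(names(cm$stages),
               c(paste0("affine", 1:4), paste0("bspline", 1:3)))
  ce <- pipeline_config("elastix_style", profile = "fast")
  expect_equal(names(ce$stages),
               c("translation", "rigid", paste0("bspline", 1:4)))
  expect_equal(ce$stages$rigid$family, "rigid")
  cf <- pipeline_config("elastix_style", force_similarity = TRUE)
  expect_equal(cf$stages$rigid$family, "similarity")
  expect_error(pipeline_config("minc_style",
                               stage_overrides = list(zz = 1)), "unknown")
})
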