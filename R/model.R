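#' Average brain model (atlas) with its ICV mask
#'
#' @param template \code{icv_volume}: the average image.
#' @param icv_mask \code{icv_mask} on the template grid (nonempty).
#' @param age_group_label text label of the size class (e.g. "20w", "30w").
#' @param orientation_label \code{"Left"} or \code{"Right"}.
#' @param n_subjects number of scans averaged into the template.
#' @return object of class \code{brain_model}.
#' @export
brain_model <- function(template, icv_mask, age_group_label = "unspecified",
                        orientation_label = template$orientation_label,
                        n_subjects = NA_integer_) {
  stopifnot(inherits(template, "icv_volume"), inherits(icv_mask, "icv_mask"))
  if (!same_geometry(template, icv_mask))
    stop("template and icv_mask must share geometry")
  if (sum(icv_mask$data) == 0) stop("icv_mask must be nonempty")
  orientation_label <- match.arg(orientation_label, c("Left", "Right"))
  structure(list(template = template, icv_mask = icv_mask,
                 age_group_label = age_group_label,
                 orientation_label = orientation_label,
                 n_subjects = n_subjects),
            class = "brain_model")
}

#' @export
print.brain_model <- function(x, ...) {
  cat(sprintf("<brain model> %s / %s, averaged from %s scans\n",
              x$age_group_label, x$orientation_label, x$n_subjects))
  print(x$template)
  print(x$icv_mask)
  invisible(x)
}

#' Default per-stage parameters for groupwise model building
#'
#' Four affine stages followed by four B-spline stages. The
#' \code{"fast"} profile shortens the pyramid and iteration counts for
#' desk-scale phantom studies; \code{"standard"} is the full schedule.
#'
#' @param profile \code{"standard"} or \code{"fast"}.
#' @param seed master seed; each stage draws a derived sub-seed.
#' @return named list of 8 \code{\link{registration_params}}.
#' @export
model_stage_params <- function(profile = c("standard", "fast"), seed = 1L) {
  profile <- match.arg(profile)
  lin_pyr <- if (profile == "fast") c(2, 0) else c(4, 2, 1, 0)
  bsp_pyr <- if (profile == "fast") c(1, 0) else c(2, 1, 0)
  it <- if (profile == "fast") 40L else 80L
  ns <- if (profile == "fast") 6000L else 16384L
  st <- list()
  for (i in 1:4)
    st[[paste0("affine", i)]] <-
      registration_params("affine", metric = "ssd",
                          optimizer = "standard_gd", sp_a = 1,
                          pyramid_schedule = lin_pyr, max_iterations = it,
                          max_samples = ns,
                          seed = derive_seed(seed, "model_affine", i))
  for (i in 1:4)
    st[[paste0("bspline", i)]] <-
      registration_params("bspline", metric = "ssd",
                          optimizer = "standard_gd", sp_a = 0.5,
                          pyramid_schedule = bsp_pyr, max_iterations = it,
                          max_samples = ns,
                          seed = derive_seed(seed, "model_bspline", i))
  st
}

# warp the original scan through its accumulated chain onto the model grid
# (one interpolation from the original data, however long the chain)
warp_to_grid <- function(scan, chain_members, geom) {
  if (length(chain_members) == 0)
    return(apply_transform(scan, identity_transform(),
                           target_geometry = geom))
  apply_transform(scan, transform_chain(chain_members),
                  target_geometry = geom)
}

average_volumes <- function(vols) {
  acc <- vols[[1]]$data
  for (i in seq_along(vols)[-1]) acc <- acc + vols[[i]]$data
  out <- vols[[1]]
  out$data <- acc / length(vols)
  out
}

#' Build a groupwise average brain model template
#'
#' Iterative groupwise registration: at stage 0 every scan is registered
#' (affine family) to a designated seed scan and the warped scans are
#' averaged; at each following affine stage all scans are registered to the
#' previous average and re-averaged; four B-spline rounds against the
#' running average then sharpen the template. The output template is the
#' arithmetic voxelwise mean after the fourth B-spline round. No intensity
#' normalization is applied before averaging (toggle via
#' \code{normalize}).
#'
#' @param scans list of >= 2 preprocessed \code{icv_volume}s with one common
#'   orientation label and broadly similar head size (one age group).
#' @param params named list of 8 stage parameters (4 affine then 4
#'   B-spline), as from \code{\link{model_stage_params}}.
#' @param seed_index which scan serves as the stage-0 template.
#' @param age_group_label label stored on the result.
#' @param normalize if TRUE, scans are rescaled to a common mean intensity
#'   before averaging (off by default).
#' @param log_file optional audit log path.
#' @return object of class \code{model_build}: \code{template}
#'   (\code{icv_volume}), \code{chains} (per-scan \code{transform_chain}
#'   member lists, model grid to scan space), \code{stage_metrics}, and
#'   provenance fields. Attach a mask with \code{\link{attach_icv_mask}} to
#'   obtain a \code{\link{brain_model}}.
#' @export
build_model <- function(scans, params = model_stage_params(),
                        seed_index = 1L, age_group_label = "unspecified",
                        normalize = FALSE, log_file = NULL) {
  if (length(scans) < 2) stop("need at least 2 scans to build a model")
  ok <- vapply(scans, inherits, logical(1), what = "icv_volume")
  if (!all(ok)) stop("scans must be icv_volume objects")
  ori <- unique(vapply(scans, function(s) s$orientation_label, character(1)))
  if (length(ori) != 1)
    stop("mixed orientations in model cohort: ", paste(ori, collapse = ", "),
         "; canonicalize or split the cohort first")
  stopifnot(seed_index >= 1, seed_index <= length(scans))
  if (normalize) {
    target_mean <- mean(vapply(scans, function(s) mean(s$data), numeric(1)))
    scans <- lapply(scans, function(s) {
      s$data <- s$data * (target_mean / mean(s$data)); s })
  }
  geom <- geometry(scans[[seed_index]])
  n <- length(scans)
  chains <- rep(list(list()), n)
  warped <- lapply(scans, warp_to_grid, chain_members = list(), geom = geom)
  target <- scans[[seed_index]]
  stage_metrics <- list()
  for (s in seq_along(params)) {
    par <- params[[s]]
    sname <- names(params)[s] %||% paste0("stage", s)
    mets <- numeric(n)
    for (i in seq_len(n)) {
      res <- register(target, warped[[i]], par)
      if (!res$converged)
        log_line("build_model", sname, paste0("scan", i), "not converged",
                 file = log_file)
      if (!is.finite(res$final_metric))
        stop("registration failed at model stage ", s, " (", sname,
             ") for scan ", i)
      chains[[i]] <- c(list(res$transform), chains[[i]])
      warped[[i]] <- warp_to_grid(scans[[i]], chains[[i]], geom)
      mets[i] <- res$final_metric
      log_line("build_model", sname, paste0("scan", i),
               sprintf("metric %.5g", res$final_metric), file = log_file)
    }
    stage_metrics[[sname]] <- mets
    target <- average_volumes(warped)
  }
  structure(list(template = target, chains = lapply(chains, transform_chain),
                 stage_metrics = stage_metrics, n_subjects = n,
                 orientation_label = ori,
                 age_group_label = age_group_label,
                 seed_index = seed_index),
            class = "model_build")
}

#' Attach an ICV mask to a built model by label fusion
#'
#' Each cohort subject's ICV mask is propagated onto the model grid through
#' the subject's groupwise transform chain, the propagated masks are
#' averaged, thresholded at 0.5 (majority vote), and smoothed with the
#' repeated median filter.
#'
#' @param build \code{model_build} from \code{\link{build_model}}.
#' @param masks list of \code{icv_mask}s, one per cohort scan, on the
#'   scans' own grids.
#' @param smooth logical: apply \code{\link{smooth_mask}} (kernel 3, three
#'   passes) to the fused mask.
#' @return a \code{\link{brain_model}}.
#' @export
attach_icv_mask <- function(build, masks, smooth = TRUE) {
  stopifnot(inherits(build, "model_build"),
            length(masks) == build$n_subjects)
  geom <- geometry(build$template)
  acc <- array(0, geom$dim)
  for (i in seq_along(masks)) {
    w <- warp_mask(masks[[i]], build$chains[[i]], geom)
    acc <- acc + w$data
  }
  fused <- new_mask(array(as.numeric(acc / length(masks) >= 0.5), geom$dim),
                    geom$spacing, geom$origin, build$orientation_label)
  if (smooth) fused <- smooth_mask(fused)
  brain_model(build$template, fused, build$age_group_label,
              build$orientation_label, build$n_subjects)
}

#' Per-stage configuration of one measurement pipeline
#'
#' The two variants have fixed stage plans. \code{"minc_style"}: four
#' "affine" stages (each a full affine optimization, which subsumes the
#' translation and rotation components) followed by three B-spline stages;
#' an optional pre-blur can be enabled on the affine stages.
#' \code{"elastix_style"}: a translation stage, then a rigid stage that
#' escalates to a similarity (rigid + global scaling) stage when its result
#' fails the similarity-score check, then four B-spline stages. The two
#' variants also differ in optimizer and metric (standard-gain descent with
#' SSD vs adaptive-gain descent with NCC on the linear stages) so that
#' their failure modes are as independent as the consensus QC assumes.
#'
#' @param variant \code{"minc_style"} or \code{"elastix_style"}.
#' @param profile \code{"standard"} or \code{"fast"} (shorter pyramid and
#'   iteration counts for desk-scale studies).
#' @param seed master seed; stages draw derived sub-seeds.
#' @param similarity_floor floor for the rigid-stage escalation check and
#'   the final QC similarity (default 0.7).
#' @param pre_blur_sigma extra blur (voxels) on the minc-style affine
#'   stages (the first retry preset sets this to 2).
#' @param force_similarity elastix-style only: use the similarity family at
#'   stage 2 unconditionally (the second retry preset).
#' @param sp_a_scale multiplier on the linear-stage step size (used by the
#'   elastix-style retry preset).
#' @param optimizer_override optional optimizer forced on the linear stages.
#' @param stage_overrides named list of \code{\link{registration_params}}
#'   replacing individual stages by name.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(variant = c("minc_style", "elastix_style"),
                            profile = c("standard", "fast"), seed = 1L,
                            similarity_floor = 0.7, pre_blur_sigma = 0,
                            force_similarity = FALSE, sp_a_scale = 1,
                            optimizer_override = NULL,
                            stage_overrides = list()) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  lin_pyr <- if (profile == "fast") c(2, 0) else c(4, 2, 1, 0)
  bsp_pyr <- if (profile == "fast") c(1, 0) else c(2, 1, 0)
  it <- if (profile == "fast") 40L else 80L
  ns <- if (profile == "fast") 6000L else 16384L
  stages <- list()
  if (variant == "minc_style") {
    for (i in 1:4)
      stages[[paste0("affine", i)]] <-
        registration_params("affine", metric = "ssd",
                            optimizer = optimizer_override %||% "standard_gd",
                            sp_a = 1 * sp_a_scale,
                            pyramid_schedule = lin_pyr, max_iterations = it,
                            pre_blur_sigma = pre_blur_sigma,
                            max_samples = ns,
                            seed = derive_seed(seed, variant, "affine", i))
    for (i in 1:3)
      stages[[paste0("bspline", i)]] <-
        registration_params("bspline", metric = "ssd",
                            optimizer = "standard_gd", sp_a = 0.5,
                            pyramid_schedule = bsp_pyr, max_iterations = it,
                            max_samples = ns,
                            seed = derive_seed(seed, variant, "bspline", i))
  } else {
    stages[["translation"]] <-
      registration_params("translation", metric = "ncc",
                          optimizer = optimizer_override %||% "adaptive_gd",
                          sp_a = 1 * sp_a_scale,
                          pyramid_schedule = lin_pyr, max_iterations = it,
                          max_samples = ns,
                          seed = derive_seed(seed, variant, "translation"))
    stages[["rigid"]] <-
      registration_params(if (force_similarity) "similarity" else "rigid",
                          metric = "ncc",
                          optimizer = optimizer_override %||% "adaptive_gd",
                          sp_a = 1 * sp_a_scale,
                          pyramid_schedule = lin_pyr, max_iterations = it,
                          max_samples = ns,
                          seed = derive_seed(seed, variant, "rigid"))
    for (i in 1:4)
      stages[[paste0("bspline", i)]] <-
        registration_params("bspline", metric = "ssd",
                            optimizer = "adaptive_gd",
                            pyramid_schedule = bsp_pyr, max_iterations = it,
                            max_samples = ns,
                            seed = derive_seed(seed, variant, "bspline", i))
  }
  for (nm in names(stage_overrides)) {
    if (!nm %in% names(stages)) stop("unknown stage in overrides: ", nm)
    stages[[nm]] <- stage_overrides[[nm]]
  }
  structure(list(variant = variant, profile = profile, seed = seed,
                 stages = stages, similarity_floor = similarity_floor,
                 force_similarity = force_similarity,
                 preset_label = "default"),
            class = "pipeline_config")
}

#' Run one measurement pipeline on a subject
#'
#' Executes the variant's stage plan. Each stage registers the current
#' warped subject to the stage target; the target is the model template for
#' the first stage(s) (the model serves both as target and as one of the
#' averaged images) and the voxelwise mean of the template and the warped
#' subject thereafter, rebuilt after every stage. The full transform chain
#' maps model space to subject space; the subject ICV mask is obtained by
#' inverting the (collapsed) chain and propagating the model mask onto the
#' subject grid, and the ICV is exactly mask voxel count x voxel volume
#' (subject voxels).
#'
#' @param subject preprocessed \code{icv_volume} (zero voxels replaced),
#'   same orientation label as the model.
#' @param model \code{\link{brain_model}}.
#' @param config \code{\link{pipeline_config}}.
#' @param log_file optional audit log path.
#' @return object of class \code{icv_result}: \code{icv_cm3},
#'   \code{pipeline_variant}, \code{transform_chain}, \code{subject_mask}
#'   (\code{icv_mask} on the subject grid), \code{final_average},
#'   \code{final_warped}, \code{similarity} (warped subject vs final
#'   average), \code{converged}, \code{stages} (per-stage diagnostics),
#'   \code{escalated} (elastix-style: whether rigid was escalated to
#'   similarity).
#' @export
run_pipeline <- function(subject, model, config, log_file = NULL) {
  stopifnot(inherits(subject, "icv_volume"), inherits(model, "brain_model"),
            inherits(config, "pipeline_config"))
  if (subject$orientation_label != model$orientation_label)
    stop("subject orientation (", subject$orientation_label,
         ") does not match model orientation (", model$orientation_label,
         "); canonicalize the scan rather than pairing across orientations")
  geom <- geometry(model$template)
  template <- model$template
  chain <- list()
  warped <- warp_to_grid(subject, chain, geom)
  stages_info <- list()
  escalated <- FALSE
  stage_names <- names(config$stages)
  n_linear_head <- if (config$variant == "minc_style") 1L else 2L
  run_stage <- function(name, par, target, moving) {
    res <- register(target, moving, par)
    log_line(config$variant, name, config$preset_label,
             sprintf("metric %.5g iters %s%s", res$final_metric,
                     paste(res$iterations_used, collapse = "/"),
                     if (res$converged) "" else " NOT-CONVERGED"),
             file = log_file)
    res
  }
  for (s in seq_along(config$stages)) {
    name <- stage_names[s]
    par <- config$stages[[s]]
    # the model is the target while the head linear stages run; averaging
    # with the warped subject begins once both images roughly coincide
    target <- if (s <= n_linear_head) template
              else average_volumes(list(template, warped))
    res <- run_stage(name, par, target, warped)
    if (config$variant == "elastix_style" && name == "rigid" &&
        par$family == "rigid") {
      trial_chain <- c(list(res$transform), chain)
      trial_warped <- warp_to_grid(subject, trial_chain, geom)
      sim <- overlap_similarity(trial_warped, template)
      if (!similarity_gate(sim, config$similarity_floor)) {
        # large model-subject size difference: escalate to rigid + scaling
        escalated <- TRUE
        par_sim <- par; par_sim$family <- "similarity"
        res <- run_stage("rigid->similarity", par_sim, target, warped)
        log_line(config$variant, "rigid", config$preset_label,
                 sprintf("escalated to similarity (sim %.3f < %.2f)", sim,
                         config$similarity_floor), file = log_file)
      }
    }
    chain <- c(list(res$transform), chain)
    warped <- warp_to_grid(subject, chain, geom)
    stages_info[[name]] <- list(metric = res$final_metric,
                                iterations = res$iterations_used,
                                converged = res$converged,
                                family = res$transform$kind %||% "bspline")
  }
  final_average <- average_volumes(list(template, warped))
  similarity <- overlap_similarity(warped, final_average)
  full_chain <- compose(transform_chain(chain))
  inv <- invert(full_chain, spacing = subject$spacing)
  subject_mask <- warp_mask(model$icv_mask, inv, geometry(subject))
  subject_mask$orientation_label <- subject$orientation_label
  icv <- mask_volume_cm3(subject_mask)
  if (icv <= 0)
    warning("propagated ICV mask is empty; registration likely failed")
  converged <- all(vapply(stages_info, function(x) x$converged, logical(1)))
  structure(list(icv_cm3 = icv, pipeline_variant = config$variant,
                 transform_chain = full_chain, subject_mask = subject_mask,
                 final_average = final_average, final_warped = warped,
                 similarity = similarity, converged = converged,
                 stages = stages_info, escalated = escalated,
                 preset_label = config$preset_label),
            class = "icv_result")
}

#' @export
print.icv_result <- function(x, ...) {
  cat(sprintf("<icv result> %s: ICV %.2f cm^3, similarity %.3f%s%s\n",
              x$pipeline_variant, x$icv_cm3, x$similarity,
              if (x$converged) "" else ", NOT converged",
              if (x$escalated) ", escalated to similarity" else ""))
  invisible(x)
}

#' Default retry presets for the consensus QC loop
#'
#' Mirrors the parameter tweaks used when a stage fails: the minc-style
#' fallback enables pre-blurring of the affine stages; the elastix-style
#' fallbacks first switch the optimizer to standard-gain descent with a
#' doubled step size, then force the similarity (rigid + global scaling)
#' stage.
#'
#' @return named list of per-variant preset lists; each preset is a named
#'   list of \code{\link{pipeline_config}} argument overrides.
#' @export
default_retry_policy <- function() {
  list(minc_style = list(list(pre_blur_sigma = 2)),
       elastix_style = list(list(optimizer_override = "standard_gd",
                                 sp_a_scale = 2),
                            list(force_similarity = TRUE)))
}

apply_preset <- function(config, preset, label) {
  args <- list(variant = config$variant, profile = config$profile,
               seed = config$seed,
               similarity_floor = config$similarity_floor)
  cfg <- do.call(pipeline_config, modifyList(args, preset))
  cfg$preset_label <- label
  cfg
}

#' Measure ICV by dual-pipeline consensus with QC and retries
#'
#' Runs both pipeline variants independently (no intermediate sharing),
#' averages their ICVs, and applies the consensus QC: the two-value SD gate
#' and the similarity floor on the elastix-style final stage. When the QC
#' fails, the offending variant (the elastix-style one when its similarity
#' is below the floor, otherwise both) is re-run with the next fallback
#' preset, at most twice, after which the subject is marked excluded.
#' Exclusion is recorded as data, never silently.
#'
#' @param subject \code{icv_volume}; zero voxels are replaced automatically
#'   if present.
#' @param model \code{\link{brain_model}}.
#' @param config_minc,config_elastix the two \code{\link{pipeline_config}}s
#'   (defaults are built from \code{profile} and \code{seed}).
#' @param profile,seed used to build default configs when not supplied.
#' @param retry_policy per-variant preset lists (at most 2 each), as from
#'   \code{\link{default_retry_policy}}.
#' @param qc_rule,qc_threshold SD-gate rule and threshold passed to
#'   \code{\link{sd_gate}} (default: 10\% of the mean ICV).
#' @param similarity_floor QC similarity floor (default 0.7).
#' @param log_file optional audit log path.
#' @return object of class \code{consensus_result}: the two
#'   \code{icv_result}s, \code{mean_icv_cm3}, \code{sd_icv_cm3},
#'   \code{similarity_score}, and \code{qc} (list: \code{sd_value},
#'   \code{sd_threshold}, \code{threshold_rule}, \code{fraction},
#'   \code{similarity}, \code{verdict} in pass/excluded, \code{reason},
#'   \code{preset_used}, \code{attempts}).
#' @export
measure_icv_consensus <- function(subject, model,
                                  config_minc = NULL, config_elastix = NULL,
                                  profile = "standard", seed = 1L,
                                  retry_policy = default_retry_policy(),
                                  qc_rule = "fraction_of_mean",
                                  qc_threshold = 0.10,
                                  similarity_floor = 0.7,
                                  log_file = NULL) {
  stopifnot(inherits(subject, "icv_volume"), inherits(model, "brain_model"))
  if (any(subject$data == 0)) subject <- replace_zero_voxels(subject)
  if (is.null(config_minc))
    config_minc <- pipeline_config("minc_style", profile = profile,
                                   seed = seed,
                                   similarity_floor = similarity_floor)
  if (is.null(config_elastix))
    config_elastix <- pipeline_config("elastix_style", profile = profile,
                                      seed = seed,
                                      similarity_floor = similarity_floor)
  stopifnot(length(retry_policy$minc_style %||% list()) <= 2,
            length(retry_policy$elastix_style %||% list()) <= 2)
  run_variant <- function(cfg) {
    tryCatch(run_pipeline(subject, model, cfg, log_file = log_file),
             error = function(e) e)
  }
  res_m <- run_variant(config_minc)
  res_e <- run_variant(config_elastix)
  attempts <- list(list(minc = config_minc$preset_label,
                        elastix = config_elastix$preset_label))
  evaluate <- function(res_m, res_e) {
    if (inherits(res_m, "error") && inherits(res_e, "error"))
      return(list(ok = FALSE, fatal = TRUE,
                  reason = "both pipeline variants failed registration"))
    if (inherits(res_m, "error") || inherits(res_e, "error"))
      return(list(ok = FALSE, fatal = FALSE, offending =
                    if (inherits(res_m, "error")) "minc_style"
                    else "elastix_style",
                  reason = "pipeline error"))
    gate <- sd_gate(res_m$icv_cm3, res_e$icv_cm3, qc_rule, qc_threshold)
    sim_ok <- similarity_gate(res_e$similarity, similarity_floor)
    if (gate$verdict == "pass" && sim_ok)
      return(list(ok = TRUE, gate = gate))
    offending <- if (!sim_ok) "elastix_style" else "both"
    reason <- if (!sim_ok)
      sprintf("final similarity %.3f below floor %.2f", res_e$similarity,
              similarity_floor)
    else
      sprintf("ICV SD %.2f cm^3 above threshold %.2f cm^3", gate$sd_value,
              gate$sd_threshold)
    list(ok = FALSE, fatal = FALSE, gate = gate, offending = offending,
         reason = reason)
  }
  ev <- evaluate(res_m, res_e)
  round <- 0L
  while (!ev$ok && !isTRUE(ev$fatal) && round < 2L) {
    round <- round + 1L
    redo_m <- ev$offending %in% c("minc_style", "both") &&
      length(retry_policy$minc_style) >= round
    redo_e <- ev$offending %in% c("elastix_style", "both") &&
      length(retry_policy$elastix_style) >= round
    if (!redo_m && !redo_e) break
    if (redo_m) {
      config_minc <- apply_preset(config_minc,
                                  retry_policy$minc_style[[round]],
                                  paste0("preset", round))
      res_m <- run_variant(config_minc)
    }
    if (redo_e) {
      config_elastix <- apply_preset(config_elastix,
                                     retry_policy$elastix_style[[round]],
                                     paste0("preset", round))
      res_e <- run_variant(config_elastix)
    }
    attempts[[length(attempts) + 1L]] <-
      list(minc = config_minc$preset_label,
           elastix = config_elastix$preset_label)
    ev <- evaluate(res_m, res_e)
  }
  ok_pair <- !inherits(res_m, "error") && !inherits(res_e, "error")
  mean_icv <- if (ok_pair) mean(c(res_m$icv_cm3, res_e$icv_cm3)) else NA_real_
  sd_icv <- if (ok_pair) two_value_sd(res_m$icv_cm3, res_e$icv_cm3)
            else NA_real_
  sim <- if (!inherits(res_e, "error")) res_e$similarity else NA_real_
  verdict <- if (ev$ok) "pass" else "excluded"
  reason <- if (ev$ok) "" else ev$reason %||% "quality control failed"
  qc <- list(sd_value = sd_icv,
             sd_threshold = if (!is.null(ev$gate)) ev$gate$sd_threshold
                            else NA_real_,
             threshold_rule = qc_rule,
             fraction = if (qc_rule == "fraction_of_mean") qc_threshold
                        else NA_real_,
             similarity = sim, verdict = verdict, reason = reason,
             preset_used = attempts[[length(attempts)]],
             attempts = length(attempts))
  log_line("consensus", verdict,
           sprintf("mean %.2f sd %.2f sim %s", mean_icv, sd_icv,
                   ifelse(is.na(sim), "NA", sprintf("%.3f", sim))),
           reason, file = log_file)
  structure(list(result_minc_style = res_m, result_elastix_style = res_e,
                 mean_icv_cm3 = mean_icv, sd_icv_cm3 = sd_icv,
                 similarity_score = sim, qc = qc),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  fmt <- function(r) if (inherits(r, "error")) "failed"
                     else sprintf("%.2f", r$icv_cm3)
  cat(sprintf(paste0("<consensus> minc %s cm^3, elastix %s cm^3, mean %s, ",
                     "SD %s, similarity %s -> %s\n"),
              fmt(x$result_minc_style), fmt(x$result_elastix_style),
              ifelse(is.na(x$mean_icv_cm3), "NA",
                     sprintf("%.2f", x$mean_icv_cm3)),
              ifelse(is.na(x$sd_icv_cm3), "NA",
                     sprintf("%.2f", x$sd_icv_cm3)),
              ifelse(is.na(x$similarity_score), "NA",
                     sprintf("%.3f", x$similarity_score)),
              x$qc$verdict))
  if (nzchar(x$qc$reason)) cat("  reason:", x$qc$reason, "\n")
  invisible(x)
}
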