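#' Read and validate a run configuration
#'
#' One YAML (or JSON) file drives the whole pipeline. Recognized fields:
#' \describe{
#'   \item{seed}{integer master seed (default 1).}
#'   \item{profile}{\code{"standard"} or \code{"fast"}.}
#'   \item{age_group_label}{text label, e.g. "20w".}
#'   \item{target_orientation}{\code{"Left"} or \code{"Right"}: orientation
#'     every scan is canonicalized to.}
#'   \item{orientation}{named map file-name -> "Left"/"Right" (manual
#'     per-scan assignment; automatic detection is out of scope).}
#'   \item{paths}{\code{input_dir}, \code{output_dir}, optional
#'     \code{mask_dir} (per-scan ICV masks for model building),
#'     \code{model_template}, \code{model_mask}.}
#'   \item{qc}{\code{rule} ("fraction_of_mean"/"absolute"),
#'     \code{threshold}, \code{similarity_floor}.}
#' }
#'
#' @param path YAML or JSON config file.
#' @return object of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$profile <- cfg$profile %||% "standard"
  cfg$age_group_label <- cfg$age_group_label %||% "unspecified"
  cfg$target_orientation <- cfg$target_orientation %||% "Left"
  cfg$qc <- modifyList(list(rule = "fraction_of_mean", threshold = 0.10,
                            similarity_floor = 0.7), cfg$qc %||% list())
  if (cfg$qc$threshold <= 0 || cfg$qc$similarity_floor <= 0)
    stop("QC thresholds must be positive")
  if (is.null(cfg$paths$input_dir) || is.null(cfg$paths$output_dir))
    stop("config must provide paths$input_dir and paths$output_dir")
  if (!dir.exists(cfg$paths$input_dir))
    stop("input_dir does not exist: ", cfg$paths$input_dir)
  for (f in c(cfg$paths$model_template, cfg$paths$model_mask))
    if (!is.null(f) && !file.exists(f)) stop("missing file: ", f)
  structure(cfg, class = "run_config")
}

config_log <- function(config) {
  dir.create(config$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$paths$output_dir, "fetalicv.log")
}

input_scans <- function(config) {
  fs <- list.files(config$paths$input_dir, pattern = "\\.nii(\\.gz)?$",
                   full.names = TRUE)
  if (length(fs) == 0)
    stop("no NIfTI scans found in ", config$paths$input_dir)
  sort(fs)
}

scan_orientation <- function(config, file) {
  config$orientation[[basename(file)]] %||% "unknown"
}

#' Preprocess raw scans: zero-voxel replacement and orientation sorting
#'
#' Reads every NIfTI scan in \code{input_dir}, replaces zero voxels by the
#' nonzero-mean grayscale, mirrors each scan into the target orientation
#' (using the manual per-scan orientation assignment from the config), and
#' writes the results plus a manifest CSV under
#' \code{output_dir/preprocessed}.
#'
#' @param config a \code{\link{read_run_config}} object (or path to one).
#' @return manifest data frame, invisibly.
#' @export
cmd_preprocess <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  lf <- config_log(config)
  out_dir <- file.path(config$paths$output_dir, "preprocessed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- input_scans(config)
  rows <- list()
  for (f in files) {
    ori <- scan_orientation(config, f)
    v <- read_volume(f, orientation_label = ori)
    v <- replace_zero_voxels(v)
    v <- canonicalize_orientation(v, config$target_orientation)
    out <- file.path(out_dir, basename(f))
    write_volume(v, out, log_file = lf)
    log_line("preprocess", basename(f), ori, "->",
             config$target_orientation, file = lf)
    rows[[length(rows) + 1L]] <-
      data.frame(file = basename(f), source_orientation = ori,
                 orientation = config$target_orientation,
                 path = out)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Build the brain model from preprocessed scans
#'
#' Runs the groupwise template construction on all preprocessed scans and
#' writes \code{model_template.nii.gz} (and, when per-scan ICV masks are
#' available in \code{paths$mask_dir}, the fused \code{model_mask.nii.gz})
#' under \code{output_dir/model}. Stage metrics are logged.
#'
#' @param config a \code{run_config} (or path).
#' @return list with the \code{model_build} and output paths, invisibly.
#' @export
cmd_build_model <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  lf <- config_log(config)
  pre_dir <- file.path(config$paths$output_dir, "preprocessed")
  files <- list.files(pre_dir, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  if (length(files) < 2)
    stop("model building needs >= 2 preprocessed scans in ", pre_dir)
  scans <- lapply(files, read_volume,
                  orientation_label = config$target_orientation)
  build <- build_model(scans,
                       params = model_stage_params(config$profile,
                                                   seed = config$seed),
                       age_group_label = config$age_group_label,
                       log_file = lf)
  out_dir <- file.path(config$paths$output_dir, "model")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tpl_path <- file.path(out_dir, "model_template.nii.gz")
  write_volume(build$template, tpl_path, log_file = lf)
  mask_path <- NULL
  if (!is.null(config$paths$mask_dir)) {
    masks <- lapply(file.path(config$paths$mask_dir, basename(files)),
                    read_volume,
                    orientation_label = config$target_orientation,
                    mask = TRUE)
    model <- attach_icv_mask(build, masks)
    mask_path <- file.path(out_dir, "model_mask.nii.gz")
    write_volume(model$icv_mask, mask_path, log_file = lf)
  }
  log_line("build_model", "done", paste(length(files), "scans"), file = lf)
  invisible(list(build = build, template_path = tpl_path,
                 mask_path = mask_path))
}

#' Measure all subjects against a model with consensus QC
#'
#' Runs the dual-pipeline consensus measurement for every preprocessed
#' subject scan and writes a results ledger CSV (one row per subject: both
#' ICVs, mean, SD, similarity, QC verdict, preset used, reason) plus
#' per-subject propagated masks and transform files. Subjects whose
#' orientation does not match the model are skipped with a recorded reason;
#' excluded subjects are data, not errors.
#'
#' @param config a \code{run_config} (or path).
#' @return ledger data frame, invisibly.
#' @export
cmd_measure <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  lf <- config_log(config)
  if (is.null(config$paths$model_template) ||
      is.null(config$paths$model_mask))
    stop("cmd_measure requires paths$model_template and paths$model_mask")
  template <- read_volume(config$paths$model_template,
                          orientation_label = config$target_orientation)
  mmask <- read_volume(config$paths$model_mask,
                       orientation_label = config$target_orientation,
                       mask = TRUE)
  model <- brain_model(template, mmask, config$age_group_label,
                       config$target_orientation)
  pre_dir <- file.path(config$paths$output_dir, "preprocessed")
  files <- list.files(pre_dir, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no preprocessed subjects in ", pre_dir)
  res_dir <- file.path(config$paths$output_dir, "results")
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (f in files) {
    sid <- sub("\\.nii(\\.gz)?$", "", basename(f))
    subject <- read_volume(f, orientation_label = config$target_orientation)
    row <- data.frame(subject = sid, icv_minc = NA_real_,
                      icv_elastix = NA_real_, mean_icv = NA_real_,
                      sd_icv = NA_real_, similarity = NA_real_,
                      verdict = NA_character_, preset = NA_character_,
                      reason = "")
    if (subject$orientation_label != model$orientation_label) {
      row$verdict <- "skipped"
      row$reason <- "orientation mismatch with model"
    } else {
      cr <- measure_icv_consensus(subject, model,
                                  profile = config$profile,
                                  seed = derive_seed(config$seed, sid),
                                  qc_rule = config$qc$rule,
                                  qc_threshold = config$qc$threshold,
                                  similarity_floor =
                                    config$qc$similarity_floor,
                                  log_file = lf)
      rm_ok <- !inherits(cr$result_minc_style, "error")
      re_ok <- !inherits(cr$result_elastix_style, "error")
      row$icv_minc <- if (rm_ok) cr$result_minc_style$icv_cm3 else NA
      row$icv_elastix <- if (re_ok) cr$result_elastix_style$icv_cm3 else NA
      row$mean_icv <- cr$mean_icv_cm3
      row$sd_icv <- cr$sd_icv_cm3
      row$similarity <- cr$similarity_score
      row$verdict <- cr$qc$verdict
      row$preset <- paste(unlist(cr$qc$preset_used), collapse = ";")
      row$reason <- cr$qc$reason
      if (re_ok) {
        write_volume(cr$result_elastix_style$subject_mask,
                     file.path(res_dir, paste0(sid, "_mask.nii.gz")),
                     log_file = lf)
        write_transform(cr$result_elastix_style$transform_chain,
                        file.path(res_dir, paste0(sid, "_transform.json")))
      }
    }
    log_line("measure", sid, row$verdict, row$reason, file = lf)
    rows[[length(rows) + 1L]] <- row
  }
  ledger <- do.call(rbind, rows)
  write.csv(ledger, file.path(res_dir, "ledger.csv"), row.names = FALSE)
  invisible(ledger)
}

#' Summarize QC outcomes and render overlay images
#'
#' Reads the measurement ledger and writes a QC summary (pass / retry /
#' excluded counts and the SD distribution quartiles) plus per-subject
#' mask-contour overlays for visual inspection.
#'
#' @param config a \code{run_config} (or path).
#' @return summary data frame, invisibly. An empty ledger produces a
#'   warning and an empty report.
#' @export
cmd_qc_report <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  lf <- config_log(config)
  res_dir <- file.path(config$paths$output_dir, "results")
  ledger_path <- file.path(res_dir, "ledger.csv")
  if (!file.exists(ledger_path)) stop("no ledger at ", ledger_path)
  ledger <- read.csv(ledger_path)
  qc_dir <- file.path(config$paths$output_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(ledger) == 0) {
    warning("empty ledger: writing empty QC report")
    write.csv(ledger, file.path(qc_dir, "qc_summary.csv"),
              row.names = FALSE)
    return(invisible(ledger))
  }
  counts <- table(factor(ledger$verdict,
                         levels = c("pass", "excluded", "skipped")))
  sds <- ledger$sd_icv[is.finite(ledger$sd_icv)]
  summary_df <- data.frame(
    n_subjects = nrow(ledger),
    n_pass = as.integer(counts[["pass"]]),
    n_excluded = as.integer(counts[["excluded"]]),
    n_skipped = as.integer(counts[["skipped"]]),
    sd_q25 = if (length(sds)) quantile(sds, 0.25) else NA_real_,
    sd_median = if (length(sds)) median(sds) else NA_real_,
    sd_q75 = if (length(sds)) quantile(sds, 0.75) else NA_real_,
    sd_max = if (length(sds)) max(sds) else NA_real_)
  write.csv(summary_df, file.path(qc_dir, "qc_summary.csv"),
            row.names = FALSE)
  pre_dir <- file.path(config$paths$output_dir, "preprocessed")
  for (sid in ledger$subject[!is.na(ledger$icv_elastix)]) {
    mask_f <- file.path(res_dir, paste0(sid, "_mask.nii.gz"))
    scan_f <- list.files(pre_dir, pattern = paste0("^", sid, "\\.nii"),
                         full.names = TRUE)
    if (!file.exists(mask_f) || length(scan_f) == 0) next
    v <- read_volume(scan_f[1])
    m <- read_volume(mask_f, mask = TRUE)
    render_overlay(v, m, qc_dir, subject_id = sid)
  }
  log_line("qc_report", sprintf("pass %d excluded %d skipped %d",
                                summary_df$n_pass, summary_df$n_excluded,
                                summary_df$n_skipped), file = lf)
  invisible(summary_df)
}
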