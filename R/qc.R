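#' Overlap similarity between two grayscale volumes
#'
#' Normalized inner product of the two intensity arrays:
#' \deqn{S = \sum_{ijk} a_{ijk} b_{ijk} / (\sum a^2 \sum b^2)^{1/2}}
#' For non-negative images it ranges from 0 (disjoint support, no overlap)
#' to 1 (full overlap, identical up to a positive scale factor). It is the
#' quality-control score computed between the registered subject scan and
#' the last-stage registration average.
#'
#' @param a,b \code{icv_volume}s on identical grids, non-negative, each with
#'   at least one nonzero voxel.
#' @return scalar in [0, 1] for non-negative inputs.
#' @export
overlap_similarity <- function(a, b) {
  stopifnot(inherits(a, "icv_volume"), inherits(b, "icv_volume"))
  if (!same_geometry(a, b)) stop("overlap_similarity requires identical grids")
  x <- as.numeric(a$data); y <- as.numeric(b$data)
  sx <- sum(x * x); sy <- sum(y * y)
  if (sx == 0 || sy == 0)
    stop("overlap similarity undefined for an all-zero volume")
  sum(x * y) / sqrt(sx * sy)
}

#' Two-value standard deviation of the pipeline pair
#'
#' Sample SD of the two per-pipeline ICVs, \code{|a - b| / sqrt(2)}. The
#' sample (n-1) convention is the conservative (larger) choice of the two
#' possible two-value SDs; thresholds are configurable so the population
#' convention can be emulated by rescaling.
#'
#' @param a,b the two ICV values, cm^3.
#' @return SD in cm^3.
#' @export
two_value_sd <- function(a, b) abs(a - b) / sqrt(2)

#' SD-based consensus gate between the two pipelines
#'
#' Computes the two-value SD of the two pipeline ICVs and compares it with a
#' threshold: either a fixed absolute value in cm^3 (the study used 10 cm^3
#' at 20 weeks and 20 cm^3 at 30 weeks) or a fraction of the mean ICV
#' (recommended band 7.5-12\%; default fraction 0.10).
#'
#' @param icv_a,icv_b per-pipeline ICVs, cm^3 (> 0).
#' @param rule \code{"fraction_of_mean"} or \code{"absolute"}.
#' @param threshold_or_fraction threshold in cm^3 (absolute rule) or the
#'   dimensionless fraction (fraction rule; default 0.10).
#' @return list (QC fragment): \code{sd_value}, \code{sd_threshold},
#'   \code{threshold_rule}, \code{fraction}, \code{verdict} (\code{"pass"}
#'   or \code{"retry"}).
#' @export
sd_gate <- function(icv_a, icv_b, rule = c("fraction_of_mean", "absolute"),
                    threshold_or_fraction = 0.10) {
  rule <- match.arg(rule)
  if (!is.finite(icv_a) || !is.finite(icv_b) || icv_a <= 0 || icv_b <= 0)
    stop("sd_gate requires positive finite ICVs")
  stopifnot(threshold_or_fraction > 0)
  sd_value <- two_value_sd(icv_a, icv_b)
  thr <- if (rule == "absolute") threshold_or_fraction
         else threshold_or_fraction * mean(c(icv_a, icv_b))
  list(sd_value = sd_value, sd_threshold = thr, threshold_rule = rule,
       fraction = if (rule == "fraction_of_mean") threshold_or_fraction
                  else NA_real_,
       verdict = if (sd_value <= thr) "pass" else "retry")
}

#' Overlap-similarity floor
#'
#' A registered result whose similarity score falls below the floor (0.7 by
#' default) indicates a wrong ICV registration. The floor is inclusive:
#' exactly 0.7 passes, values below fail.
#'
#' @param sim similarity score in [0, 1].
#' @param floor pass floor (default 0.7).
#' @return logical: \code{TRUE} = pass.
#' @export
similarity_gate <- function(sim, floor = 0.7) {
  stopifnot(is.finite(sim), sim >= 0, sim <= 1)
  sim >= floor
}

#' Smooth a binary mask with a repeated 3D median filter
#'
#' A median filter with a cubic window of \code{kernel} voxels per side
#' (default 3 x 3 x 3) applied \code{repeats} times (default 3). The output
#' is binary; isolated single voxels vanish after one pass and large solid
#' shapes are nearly volume-preserving.
#'
#' @param m \code{icv_mask}.
#' @param kernel odd window width in voxels (>= 3).
#' @param repeats number of passes.
#' @return smoothed \code{icv_mask}.
#' @export
smooth_mask <- function(m, kernel = 3L, repeats = 3L) {
  stopifnot(inherits(m, "icv_mask"), repeats >= 1)
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    stop("kernel must be an odd voxel count >= 3")
  d <- dim(m$data)
  x <- as.numeric(m$data)
  for (i in seq_len(repeats)) x <- cpp_median3d(x, d, kernel)
  m$data <- array(as.numeric(x >= 0.5), d)
  m
}

# boundary voxels of a binary slice (2D), used for contour overlays
slice_contour <- function(sl) {
  if (!any(sl > 0)) return(sl * 0)
  p <- function(mat, dr, dc) {
    n <- dim(mat)
    out <- matrix(0, n[1], n[2])
    rs <- pmin(pmax(seq_len(n[1]) + dr, 1), n[1])
    cs <- pmin(pmax(seq_len(n[2]) + dc, 1), n[2])
    out[, ] <- mat[rs, cs]
    out
  }
  nb_min <- pmin(p(sl, 1, 0), p(sl, -1, 0), p(sl, 0, 1), p(sl, 0, -1))
  (sl > 0 & nb_min == 0) * 1
}

#' Write mask-contour overlay images for visual QC
#'
#' For each requested plane a PNG is written showing the grayscale slice
#' with the mask outline drawn in green, supporting the visual inspection
#' step that decides which pipeline a disagreeing pair came from. File names
#' are deterministic: \code{<subject_id>_<plane>_<index>.png}.
#'
#' @param v \code{icv_volume}.
#' @param m \code{icv_mask} on the same grid.
#' @param out_dir output directory (created if missing).
#' @param subject_id id used in file names.
#' @param planes subset of \code{c("axial", "coronal", "sagittal")}.
#' @param slice_index slice to draw per plane; default mid-slice. Axial
#'   slices fix the third axis, coronal the second, sagittal the first.
#' @return character vector of files written, invisibly. An empty mask
#'   produces contour-free images with a warning.
#' @export
render_overlay <- function(v, m, out_dir, subject_id = "subject",
                           planes = c("axial", "coronal", "sagittal"),
                           slice_index = NULL) {
  stopifnot(inherits(v, "icv_volume"), inherits(m, "icv_mask"))
  if (!same_geometry(v, m)) stop("volume and mask geometry differ")
  planes <- match.arg(planes, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (sum(m$data) == 0)
    warning("empty mask: overlays will have no contour")
  d <- dim(v$data)
  axis_of <- c(axial = 3L, coronal = 2L, sagittal = 1L)
  files <- character(0)
  vmax <- max(v$data, 1e-9)
  for (pl in planes) {
    ax <- axis_of[[pl]]
    si <- slice_index %||% ((d[ax] + 1L) %/% 2L)
    if (si < 1 || si > d[ax])
      stop("slice index ", si, " out of range for ", pl, " plane")
    gs <- switch(pl, axial = v$data[, , si], coronal = v$data[, si, ],
                 sagittal = v$data[si, , ])
    ms <- switch(pl, axial = m$data[, , si], coronal = m$data[, si, ],
                 sagittal = m$data[si, , ])
    ct <- slice_contour(ms)
    g <- pmin(gs / vmax, 1)
    rgb <- array(0, c(nrow(g), ncol(g), 3))
    rgb[, , 1] <- g * (1 - ct)
    rgb[, , 2] <- pmax(g, ct)
    rgb[, , 3] <- g * (1 - ct)
    f <- file.path(out_dir, sprintf("%s_%s_%03d.png", subject_id, pl, si))
    png::writePNG(aperm(rgb, c(2, 1, 3))[ncol(g):1, , , drop = FALSE], f)
    files <- c(files, f)
  }
  invisible(files)
}
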