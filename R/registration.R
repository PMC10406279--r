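#' Registration stage parameters
#'
#' Bundle of everything a single intensity-based registration stage needs.
#' The pyramid is smoothing-only: every level keeps the full grid and only
#' the Gaussian sigma changes (no down-sampling anywhere in the pipelines).
#'
#' @param family transform family: \code{"translation"}, \code{"rigid"},
#'   \code{"similarity"}, \code{"affine"} or \code{"bspline"}.
#' @param metric \code{"ssd"} (mean squared intensity difference, lower is
#'   better) or \code{"ncc"} (Pearson correlation, higher is better).
#'   Default: \code{"ncc"} for linear families, \code{"ssd"} for B-spline.
#' @param optimizer \code{"standard_gd"} (decaying-gain gradient descent
#'   whose first-step length in mm is \code{sp_a}) or \code{"adaptive_gd"}
#'   (same schedule with the gain auto-calibrated from the initial gradient
#'   so the first step moves about one voxel).
#' @param sp_a step-size scale for \code{standard_gd}: the length (mm) of
#'   the first descent step. Must be > 0.
#' @param pyramid_schedule nonincreasing vector of Gaussian sigmas in
#'   voxels; 0 means no smoothing at that level.
#' @param max_iterations iteration cap per pyramid level (>= 1).
#' @param pre_blur_sigma extra Gaussian blur (voxels) applied to both images
#'   before all levels; 0 disables. This is the "add pre-blurring" fallback
#'   used when a stage fails QC.
#' @param seed integer seed controlling the stochastic voxel subsample; two
#'   runs with the same inputs and seed are bit-identical.
#' @param bspline_grid_spacing control-point spacing in voxels for the
#'   B-spline family.
#' @param max_samples cap on the number of fixed-image voxels used per
#'   gradient/metric evaluation; the subsample is drawn once per pyramid
#'   level from the seeded stream. Volumes at or below this size are used in
#'   full.
#' @param step_target first-step length (mm) for \code{adaptive_gd};
#'   default: one voxel (linear) or half a voxel (B-spline).
#' @return object of class \code{registration_params}.
#' @export
registration_params <- function(family = c("affine", "translation", "rigid",
                                           "similarity", "bspline"),
                                metric = NULL,
                                optimizer = c("adaptive_gd", "standard_gd"),
                                sp_a = 1.0,
                                pyramid_schedule = c(4, 2, 1, 0),
                                max_iterations = 60L,
                                pre_blur_sigma = 0,
                                seed = 1L,
                                bspline_grid_spacing = 8,
                                max_samples = 8192L,
                                step_target = NULL) {
  family <- match.arg(family)
  optimizer <- match.arg(optimizer)
  if (is.null(metric)) metric <- if (family == "bspline") "ssd" else "ncc"
  metric <- match.arg(metric, c("ssd", "ncc"))
  stopifnot(sp_a > 0, max_iterations >= 1, pre_blur_sigma >= 0,
            bspline_grid_spacing > 0, max_samples >= 64)
  pyramid_schedule <- as.numeric(pyramid_schedule)
  if (length(pyramid_schedule) == 0 || any(pyramid_schedule < 0) ||
      is.unsorted(rev(pyramid_schedule)))
    stop("pyramid_schedule must be a nonincreasing vector of sigmas >= 0")
  structure(list(family = family, metric = metric, optimizer = optimizer,
                 sp_a = sp_a, pyramid_schedule = pyramid_schedule,
                 max_iterations = as.integer(max_iterations),
                 pre_blur_sigma = pre_blur_sigma, seed = as.integer(seed),
                 bspline_grid_spacing = bspline_grid_spacing,
                 max_samples = as.integer(max_samples),
                 step_target = step_target),
            class = "registration_params")
}

#' Gaussian-smooth a volume without changing its dimensions
#'
#' @param v \code{icv_volume}.
#' @param sigma smoothing sigma in voxels (scalar or per-axis); 0 returns
#'   the volume unchanged.
#' @return smoothed \code{icv_volume} with the same grid.
#' @export
blur <- function(v, sigma) {
  stopifnot(inherits(v, "icv_volume"))
  sigma <- rep_len(as.numeric(sigma), 3)
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (all(sigma == 0)) return(v)
  v$data <- array(cpp_gaussian_blur(as.numeric(v$data), dim(v$data), sigma),
                  dim(v$data))
  v
}

#' Intensity similarity between two volumes on the same grid
#'
#' @param fixed,moving volumes on identical grids.
#' @param metric \code{"ssd"} (mean squared difference) or \code{"ncc"}
#'   (Pearson correlation of intensities).
#' @return scalar metric value.
#' @export
intensity_metric <- function(fixed, moving, metric = c("ssd", "ncc")) {
  metric <- match.arg(metric)
  stopifnot(inherits(fixed, "icv_volume"), inherits(moving, "icv_volume"))
  if (!same_geometry(fixed, moving))
    stop("intensity_metric requires identical grids")
  a <- as.numeric(fixed$data); b <- as.numeric(moving$data)
  if (metric == "ssd") return(mean((a - b)^2))
  if (sd(a) == 0 || sd(b) == 0)
    stop("ncc undefined: constant image")
  cor(a, b)
}

# ---- internal registration machinery ---------------------------------------

n_linear_params <- function(family) {
  switch(family, translation = 3L, rigid = 6L, similarity = 7L, affine = 12L)
}

linear_from_params <- function(p, family, center) {
  if (family == "translation")
    return(linear_transform(diag(3), p[1:3], center, "translation"))
  if (family == "rigid")
    return(linear_transform(euler_matrix(p[4:6]), p[1:3], center, "rigid"))
  if (family == "similarity")
    return(linear_transform(exp(p[7]) * euler_matrix(p[4:6]), p[1:3], center,
                            "similarity"))
  m <- diag(3) + matrix(p[4:12], 3, 3)
  linear_transform(m, p[1:3], center, "affine")
}

params_from_linear <- function(t, family, center) {
  # re-express t about the requested center, then extract family parameters
  off <- as.numeric((t$matrix - diag(3)) %*% (center - t$center) + t$offset)
  m <- t$matrix
  if (family == "translation") {
    if (max(abs(m - diag(3))) > 1e-8)
      stop("cannot initialize a translation stage from a non-translation")
    return(off)
  }
  if (family == "affine") return(c(off, as.numeric(m - diag(3))))
  s <- det(m)^(1/3)
  r <- m / s
  ang <- c(atan2(r[3, 2], r[3, 3]), asin(max(-1, min(1, -r[3, 1]))),
           atan2(r[2, 1], r[1, 1]))
  if (family == "rigid") {
    if (abs(s - 1) > 1e-6)
      stop("cannot initialize a rigid stage from a scaled transform")
    return(c(off, ang))
  }
  c(off, ang, log(s))
}

# per-parameter scaling into a common mm-equivalent space: rotations, log
# scale and matrix entries are multiplied by the image half-extent so one
# unit of any scaled parameter moves a peripheral point about one mm
linear_param_scales <- function(family, half_extent) {
  switch(family,
         translation = rep(1, 3),
         rigid = c(rep(1, 3), rep(half_extent, 3)),
         similarity = c(rep(1, 3), rep(half_extent, 4)),
         affine = c(rep(1, 3), rep(half_extent, 9)))
}

metric_from_samples <- function(metric, fvals, mvals) {
  if (metric == "ssd") return(mean((mvals - fvals)^2))
  if (sd(fvals) == 0 || sd(mvals) == 0)
    stop("ncc undefined: constant image over the sampled voxels")
  -cor(fvals, mvals)   # minimized
}

# d(metric)/d(moving value at each sample); used by the B-spline chain rule
metric_dmdm <- function(metric, fvals, mvals) {
  n <- length(fvals)
  if (metric == "ssd") return(2 * (mvals - fvals) / n)
  fc <- fvals - mean(fvals); mc <- mvals - mean(mvals)
  sf <- sqrt(mean(fc^2)); sm <- sqrt(mean(mc^2))
  if (sf == 0 || sm == 0) stop("ncc undefined: constant image")
  rho <- mean(fc * mc) / (sf * sm)
  -(fc / (sf * sm) - rho * mc / sm^2) / n
}

gain_schedule <- function(k, alpha = 0.602, A = 50) {
  ((A + 1) / (A + k + 1))^alpha
}

#' Single-stage intensity-based registration
#'
#' Coarse-to-fine (smoothing-only pyramid) gradient descent on the chosen
#' transform family. Linear families use central finite differences on the
#' scaled parameters; the B-spline family uses the analytic chain rule
#' through the cubic basis. The gradient and metric are evaluated on a
#' seeded voxel subsample drawn once per pyramid level, so runs are
#' deterministic given the seed.
#'
#' @param fixed,moving \code{icv_volume}s with overlapping fields of view.
#' @param params \code{\link{registration_params}}.
#' @param init optional initial \code{linear_transform} (linear families
#'   only); default identity.
#' @return object of class \code{registration_result}: \code{transform},
#'   \code{final_metric} (on the finest level; sign convention: lower is
#'   better, NCC is negated), \code{iterations_used} per level, and a
#'   \code{converged} flag (FALSE when the metric worsened monotonically
#'   over a full level; the best-so-far transform is still returned).
#' @export
register <- function(fixed, moving, params, init = NULL) {
  stopifnot(inherits(fixed, "icv_volume"), inherits(moving, "icv_volume"),
            inherits(params, "registration_params"))
  if (params$family == "bspline") {
    if (!is.null(init)) stop("B-spline stages start from identity")
    reg_bspline(fixed, moving, params)
  } else {
    reg_linear(fixed, moving, params, init)
  }
}

reg_linear <- function(fixed, moving, params, init) {
  geomF <- geometry(fixed); geomM <- geometry(moving)
  center <- geomF$origin + geomF$spacing * (geomF$dim - 1) / 2
  half_extent <- mean((geomF$dim - 1) * geomF$spacing) / 2
  sc <- linear_param_scales(params$family, half_extent)
  np <- n_linear_params(params$family)
  p0 <- if (is.null(init)) rep(0, np)
        else params_from_linear(init, params$family, center)
  q <- p0 * sc
  bgM <- nonzero_mean(moving)
  min_sp <- min(geomF$spacing)
  h <- 0.25 * min_sp                       # finite-difference step, mm-equiv
  if (params$pre_blur_sigma > 0) {
    fixed <- blur(fixed, params$pre_blur_sigma)
    moving <- blur(moving, params$pre_blur_sigma)
  }
  nvox <- prod(geomF$dim)
  iterations_used <- integer(0)
  converged <- TRUE
  final_metric <- NA_real_
  for (lev in seq_along(params$pyramid_schedule)) {
    sg <- params$pyramid_schedule[lev]
    fx <- if (sg > 0) blur(fixed, sg) else fixed
    mv <- if (sg > 0) blur(moving, sg) else moving
    nsamp <- min(nvox, params$max_samples)
    idx <- with_seed(derive_seed(params$seed, "sample", lev),
                     sort(sample.int(nvox, nsamp)))
    fvals <- as.numeric(fx$data)[idx]
    pts <- voxel_centers(geomF, idx)
    mdata <- as.numeric(mv$data); mdim <- dim(mv$data)
    eval_metric <- function(qv) {
      tr <- linear_from_params(qv / sc, params$family, center)
      mi <- world_to_index0(geomM, transform_points(tr, pts))
      mvals <- cpp_sample_volume(mdata, mdim, mi, 0L, bgM)
      metric_from_samples(params$metric, fvals, mvals)
    }
    grad_fd <- function(qv) {
      g <- numeric(np)
      for (j in seq_len(np)) {
        e <- numeric(np); e[j] <- h
        g[j] <- (eval_metric(qv + e) - eval_metric(qv - e)) / (2 * h)
      }
      g
    }
    m_start <- eval_metric(q)
    m_best <- m_start; q_best <- q
    g0 <- grad_fd(q)
    scale0 <- max(abs(g0))
    k_used <- 0L
    if (scale0 > 0) {
      target <- params$step_target %||% min_sp
      first_step <- if (params$optimizer == "adaptive_gd") target
                    else params$sp_a
      base_gain <- first_step / scale0
      g <- g0
      last_improve <- 0L
      fails <- 0L
      for (k in seq_len(params$max_iterations)) {
        gain <- gain_schedule(k - 1)
        step <- base_gain * gain * g
        # decaying trust-region clamp on the step length (mm-equivalent)
        cap <- first_step * gain
        smax <- max(abs(step))
        if (smax > cap) step <- step * (cap / smax)
        q <- q - step
        m_k <- eval_metric(q)
        if (m_k < m_best) {
          m_best <- m_k; q_best <- q; last_improve <- k; fails <- 0L
        } else {
          fails <- fails + 1L
          if (fails %% 2L == 0L) {   # persistent overshoot: refine finer
            base_gain <- base_gain * 0.7
            first_step <- first_step * 0.7
          }
        }
        k_used <- k
        if (first_step < 0.02 * min_sp) break
        if (k - last_improve > 12L) break   # stalled
        if (k < params$max_iterations) g <- grad_fd(q)
      }
    }
    if (k_used == params$max_iterations && m_best >= m_start)
      converged <- FALSE   # a full level without improvement
    q <- q_best
    iterations_used <- c(iterations_used, k_used)
    final_metric <- m_best
  }
  structure(list(transform = linear_from_params(q / sc, params$family,
                                                center),
                 final_metric = final_metric,
                 iterations_used = iterations_used,
                 converged = converged),
            class = "registration_result")
}

reg_bspline <- function(fixed, moving, params) {
  geomF <- geometry(fixed); geomM <- geometry(moving)
  min_sp <- min(geomF$spacing)
  grid_mm <- params$bspline_grid_spacing * geomF$spacing
  proto <- bspline_transform(grid_mm, world_bbox(geomF))
  ncp <- proto$ncp
  nq <- prod(ncp) * 3
  q <- numeric(nq)
  bgM <- nonzero_mean(moving)
  if (params$pre_blur_sigma > 0) {
    fixed <- blur(fixed, params$pre_blur_sigma)
    moving <- blur(moving, params$pre_blur_sigma)
  }
  nvox <- prod(geomF$dim)
  iterations_used <- integer(0)
  converged <- TRUE
  final_metric <- NA_real_
  for (lev in seq_along(params$pyramid_schedule)) {
    sg <- params$pyramid_schedule[lev]
    fx <- if (sg > 0) blur(fixed, sg) else fixed
    mv <- if (sg > 0) blur(moving, sg) else moving
    mgrad <- cpp_image_gradient(as.numeric(mv$data), dim(mv$data),
                                geomM$spacing)
    nmv <- prod(dim(mv$data))
    nsamp <- min(nvox, params$max_samples)
    idx <- with_seed(derive_seed(params$seed, "bspl", lev),
                     sort(sample.int(nvox, nsamp)))
    fvals <- as.numeric(fx$data)[idx]
    pts <- voxel_centers(geomF, idx)
    mdata <- as.numeric(mv$data); mdim <- dim(mv$data)
    eval_state <- function(qv) {
      disp <- cpp_bspline_disp(qv, ncp, proto$grid_origin,
                               proto$grid_spacing, pts)
      y <- pts + disp
      mi <- world_to_index0(geomM, y)
      mvals <- cpp_sample_volume(mdata, mdim, mi, 0L, bgM)
      list(y = y, mi = mi, mvals = mvals,
           metric = metric_from_samples(params$metric, fvals, mvals))
    }
    grad_at <- function(st) {
      dm <- metric_dmdm(params$metric, fvals, st$mvals)
      gm <- rbind(cpp_sample_volume(mgrad[seq_len(nmv)], mdim, st$mi, 0L, 0),
                  cpp_sample_volume(mgrad[nmv + seq_len(nmv)], mdim, st$mi,
                                    0L, 0),
                  cpp_sample_volume(mgrad[2 * nmv + seq_len(nmv)], mdim,
                                    st$mi, 0L, 0))
      cpp_bspline_grad(ncp, proto$grid_origin, proto$grid_spacing, pts, dm,
                       gm)
    }
    st <- eval_state(q)
    m_start <- st$metric
    m_best <- m_start; q_best <- q
    g0 <- grad_at(st)
    scale0 <- max(abs(g0))
    k_used <- 0L
    if (scale0 > 0) {
      target <- params$step_target %||% (0.5 * min_sp)
      first_step <- if (params$optimizer == "adaptive_gd") target
                    else params$sp_a
      base_gain <- first_step / scale0
      g <- g0
      last_improve <- 0L
      fails <- 0L
      velocity <- numeric(nq)   # heavy-ball momentum: the deformation is
      mu <- 0.9                 # high-dimensional and locally quadratic
      for (k in seq_len(params$max_iterations)) {
        gain <- gain_schedule(k - 1)
        step <- base_gain * gain * g
        velocity <- mu * velocity + step
        # decaying trust-region clamp on the accumulated update (mm)
        cap <- first_step * gain
        vmax <- max(abs(velocity))
        if (vmax > cap) velocity <- velocity * (cap / vmax)
        q <- q - velocity
        st <- eval_state(q)
        if (st$metric < m_best) {
          m_best <- st$metric; q_best <- q; last_improve <- k; fails <- 0L
        } else {
          fails <- fails + 1L
          if (fails %% 2L == 0L) {   # persistent overshoot: refine finer
            base_gain <- base_gain * 0.7
            first_step <- first_step * 0.7
          }
        }
        k_used <- k
        if (first_step < 0.02 * min_sp) break
        if (k - last_improve > 20L) break
        if (k < params$max_iterations) g <- grad_at(st)
      }
    }
    if (k_used == params$max_iterations && m_best >= m_start)
      converged <- FALSE   # a full level without improvement
    q <- q_best
    iterations_used <- c(iterations_used, k_used)
    final_metric <- m_best
  }
  structure(list(transform = bspline_transform(grid_mm, world_bbox(geomF),
                                               array(q, c(ncp, 3))),
                 final_metric = final_metric,
                 iterations_used = iterations_used,
                 converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration result> metric %.6g, iterations %s, %s\n",
              x$final_metric, paste(x$iterations_used, collapse = "/"),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
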