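#' Synthetic fetal-head phantom specification
#'
#' Describes a seeded synthetic 3D-ultrasound head phantom: an ellipsoidal
#' bright cranial shell ("skull") enclosing textured brain-like tissue with
#' darker ventricle-like inclusions and a bright midline band (falx-like),
#' multiplicative log-normal speckle, an acoustic-shadow sector, and
#' zero-valued padding outside a conical sweep field of view. The inclusions
#' are placed asymmetrically (as the fetal brain is), so a phantom and its
#' mirror image are genuinely different objects. Ground-truth ICV is exact
#' by construction: the mask is the set of voxel centers inside the inner
#' ellipsoid.
#'
#' Two size presets bracket the study's two gestational-age groups:
#' \code{"20w"} (semi-axes 26 x 33 x 28 mm, about 125 cm^3 scale at the
#' ellipsoid level, chosen near the ~20-week cohort) and \code{"30w"}
#' (38 x 48 x 41 mm). The presets are labels of size class, not claims of
#' anatomical fidelity.
#'
#' @param preset \code{"20w"} or \code{"30w"}; sets semi-axes, spacing and
#'   grid defaults which individual arguments may override.
#' @param semi_axes inner cranial ellipsoid semi-axes, mm.
#' @param shell_thickness bright skull shell thickness, mm (> 0, smaller
#'   than every semi-axis).
#' @param tissue_mean,shell_mean,background_mean mean grayscale of interior
#'   tissue, shell and exterior tissue.
#' @param speckle_sigma log-normal multiplicative speckle scale (0 = off).
#' @param shadow_sector \code{NULL} or list with \code{axis} (beam plane
#'   normal axis, 1-3), \code{width_deg} (angular width) and optionally
#'   \code{angle_deg} (central azimuth): a zeroed wedge mimicking acoustic
#'   shadowing.
#' @param orientation_label \code{"Left"} or \code{"Right"}; the
#'   \code{"Right"} phantom is the mirror image of the \code{"Left"} one.
#' @param spacing voxel spacing, mm.
#' @param grid_shape volume dimensions in voxels.
#' @param internal_structures number (0-3) of ellipsoidal inclusions.
#' @param taper fronto-occipital egg asymmetry: fractional radial widening
#'   of the anterior half and narrowing of the posterior half (axis 2).
#' @param petalia length-2 fractional amplitudes of two unequal
#'   petalia-like bulges (right-frontal and left-occipital), the torque
#'   that makes the cranial shape chiral; set \code{c(0, 0)} (with
#'   \code{taper = 0}) for a pure ellipsoid.
#' @param center_offset head center offset from the grid center, mm.
#' @param rotation_deg head rotation (Euler angles, degrees).
#' @param sweep logical: zero everything outside a conical sweep region.
#' @param seed integer; the phantom is bit-reproducible given the spec.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(preset = c("20w", "30w"),
                         semi_axes = NULL, shell_thickness = 3,
                         tissue_mean = 90, shell_mean = 200,
                         background_mean = 60, speckle_sigma = 0.25,
                         shadow_sector = list(axis = 3, width_deg = 90,
                                              angle_deg = 10),
                         orientation_label = c("Left", "Right"),
                         spacing = NULL, grid_shape = c(48, 48, 48),
                         internal_structures = 3L,
                         taper = 0.12, petalia = c(0.15, 0.08),
                         center_offset = c(0, 0, 0),
                         rotation_deg = c(0, 0, 0),
                         sweep = TRUE, seed = 1L) {
  preset <- match.arg(preset)
  orientation_label <- match.arg(orientation_label)
  if (is.null(semi_axes))
    semi_axes <- switch(preset, "20w" = c(26, 33, 28), "30w" = c(38, 48, 41))
  if (is.null(spacing))
    spacing <- switch(preset, "20w" = c(2, 2, 2), "30w" = c(3, 3, 3))
  semi_axes <- as.numeric(semi_axes)
  spacing <- rep_len(as.numeric(spacing), 3)
  grid_shape <- as.integer(rep_len(grid_shape, 3))
  stopifnot(length(semi_axes) == 3, shell_thickness > 0,
            all(semi_axes > shell_thickness), all(spacing > 0),
            all(grid_shape >= 8), internal_structures %in% 0:3)
  # sphere bound: rotated outer surface (incl. taper/petalia bulges) must
  # fit with >= 2 voxel margin
  r_out <- (max(semi_axes) * (1 + taper + 0.5 * max(petalia, 0))) +
    shell_thickness
  half_box <- spacing * (grid_shape - 1) / 2
  if (any(r_out + abs(center_offset) > half_box - 2 * spacing))
    stop("grid does not contain the outer cranial surface with a 2-voxel margin")
  structure(list(preset = preset, semi_axes = semi_axes,
                 shell_thickness = shell_thickness,
                 tissue_mean = tissue_mean, shell_mean = shell_mean,
                 background_mean = background_mean,
                 speckle_sigma = speckle_sigma,
                 shadow_sector = shadow_sector,
                 orientation_label = orientation_label, spacing = spacing,
                 grid_shape = grid_shape,
                 internal_structures = as.integer(internal_structures),
                 taper = taper, petalia = rep_len(as.numeric(petalia), 2),
                 center_offset = as.numeric(center_offset),
                 rotation_deg = as.numeric(rotation_deg), sweep = sweep,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# fixed asymmetric inclusion table (fractions of the semi-axes); entry 3 is
# a bright choroid-like body, 1-2 are dark ventricle-like cavities
phantom_structures <- function() {
  list(list(center = c(0.28, 0.08, 0.12), semi = c(0.42, 0.20, 0.18),
            level = 0.30),
       list(center = c(-0.24, -0.18, 0.06), semi = c(0.28, 0.16, 0.14),
            level = 0.40),
       list(center = c(0.12, 0.32, -0.15), semi = c(0.16, 0.22, 0.12),
            level = 1.70))
}

#' Generate a synthetic head phantom with exact ground-truth ICV
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{volume} (\code{icv_volume}), \code{mask}
#'   (\code{icv_mask} of the inner ellipsoid), \code{true_icv_cm3} (mask
#'   voxel count times voxel volume) and \code{spec}.
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$spacing
  geom <- list(dim = d, spacing = sp, origin = c(0, 0, 0))
  ctr <- sp * (d - 1) / 2 + spec$center_offset
  pts <- voxel_centers(geom)                      # 3 x N
  rot <- euler_matrix(spec$rotation_deg * pi / 180)
  u <- crossprod(rot, pts - ctr)                  # body coordinates
  a <- spec$semi_axes
  # direction-dependent surface radius: egg taper along the AP axis plus
  # two unequal petalia-like bulges (right-frontal, left-occipital) that
  # make the cranial shape chiral, as real fetal heads are
  n1 <- u[1, ] / a[1]; n2 <- u[2, ] / a[2]; n3 <- u[3, ] / a[3]
  rho <- sqrt(n1^2 + n2^2 + n3^2)
  d1 <- ifelse(rho > 0, n1 / rho, 0); d2 <- ifelse(rho > 0, n2 / rho, 0)
  rr <- 1 + spec$taper * d2 +
    spec$petalia[1] * pmax(0, d1) * pmax(0, d2) +
    spec$petalia[2] * pmax(0, -d1) * pmax(0, -d2)
  q_in <- (rho / rr)^2
  ao <- a + spec$shell_thickness
  no <- sqrt((u[1, ] / ao[1])^2 + (u[2, ] / ao[2])^2 + (u[3, ] / ao[3])^2)
  q_out <- (no / rr)^2
  inside <- q_in <= 1
  shell <- !inside & q_out <= 1
  vals <- rep(spec$background_mean, length(q_in))
  vals[shell] <- spec$shell_mean
  # smooth low-frequency texture over the brain tissue
  tex <- with_seed(derive_seed(spec$seed, "texture"), {
    n <- array(rnorm(prod(d)), d)
    array(cpp_gaussian_blur(as.numeric(n), d, c(2, 2, 2)), d)
  })
  tex <- as.numeric(tex) / max(1e-9, sd(tex))
  vals[inside] <- spec$tissue_mean * (1 + 0.15 * tex[inside])
  # bright midline band (falx-like)
  falx <- inside & abs(u[1, ]) <= 0.9
  vals[falx] <- spec$shell_mean * 0.7
  if (spec$internal_structures > 0) {
    st <- phantom_structures()[seq_len(spec$internal_structures)]
    for (s in st) {
      cc <- s$center * a
      ss <- s$semi * a
      qs <- ((u[1, ] - cc[1]) / ss[1])^2 + ((u[2, ] - cc[2]) / ss[2])^2 +
        ((u[3, ] - cc[3]) / ss[3])^2
      sel <- qs <= 1 & inside
      vals[sel] <- spec$tissue_mean * s$level
    }
  }
  if (spec$speckle_sigma > 0) {
    z <- with_seed(derive_seed(spec$seed, "speckle"), rnorm(length(vals)))
    vals <- vals * exp(spec$speckle_sigma * z - spec$speckle_sigma^2 / 2)
  }
  if (!is.null(spec$shadow_sector)) {
    sh <- spec$shadow_sector
    axs <- setdiff(1:3, sh$axis)
    phi <- atan2(pts[axs[2], ] - ctr[axs[2]], pts[axs[1], ] - ctr[axs[1]])
    phi0 <- (sh$angle_deg %||% 40) * pi / 180
    dphi <- atan2(sin(phi - phi0), cos(phi - phi0))
    r <- sqrt((pts[axs[1], ] - ctr[axs[1]])^2 +
                (pts[axs[2], ] - ctr[axs[2]])^2)
    vals[abs(dphi) < (sh$width_deg / 2) * pi / 180 & r > 0.6 * min(a)] <- 0
  }
  if (isTRUE(spec$sweep)) {
    # conical sweep with apex below the head along axis 3, wide enough to
    # contain the whole outer ellipsoid (so padding never crops the head)
    ao_eff <- ao * (1 + spec$taper + 0.5 * max(spec$petalia, 0))
    apex_z <- ctr[3] - max(ao_eff) - 0.35 * sp[3] * (d[3] - 1)
    A <- max(ao_eff[1:2]); C <- ao_eff[3]
    w <- seq(-1, 1, by = 0.01)
    tan_th <- 1.05 * max(A * sqrt(1 - w^2) / (ctr[3] - apex_z + C * w))
    r_xy <- sqrt((pts[1, ] - ctr[1])^2 + (pts[2, ] - ctr[2])^2)
    vals[r_xy > tan_th * pmax(0, pts[3, ] - apex_z)] <- 0
  }
  vol <- new_volume(array(pmax(vals, 0), d), sp, c(0, 0, 0), "Left")
  msk <- new_mask(array(as.numeric(inside), d), sp, c(0, 0, 0), "Left")
  if (spec$orientation_label == "Right") {
    vol$data <- vol$data[d[1]:1, , , drop = FALSE]
    msk$data <- msk$data[d[1]:1, , , drop = FALSE]
    vol$orientation_label <- msk$orientation_label <- "Right"
  }
  list(volume = vol, mask = msk, true_icv_cm3 = mask_volume_cm3(msk),
       spec = spec)
}

#' Generate a seeded phantom cohort with recorded ground truth
#'
#' Per-subject isotropic scale is drawn uniformly from \code{scale_range},
#' a small rigid pose perturbation is applied, and the speckle realization
#' is independent per subject. Everything is deterministic per seed.
#'
#' @param n number of subjects (>= 2).
#' @param base_spec \code{\link{phantom_spec}} the cohort varies around.
#' @param scale_range length-2 range for the isotropic size factor.
#' @param jitter list with \code{translation_mm} and \code{rotation_deg}
#'   bounds for the uniform rigid pose perturbation, or \code{FALSE} for
#'   none.
#' @param seed integer master seed for the cohort.
#' @return list with \code{subjects} (list of \code{make_head_phantom}
#'   outputs) and \code{manifest} (data frame: subject_id, seed, scale,
#'   true_icv_cm3).
#' @export
make_cohort <- function(n, base_spec, scale_range = c(0.9, 1.1),
                        jitter = list(translation_mm = 2, rotation_deg = 4),
                        seed = 1L) {
  stopifnot(n >= 2, inherits(base_spec, "phantom_spec"))
  scale_range <- as.numeric(scale_range)
  if (length(scale_range) != 2 || diff(scale_range) < 0 ||
      any(scale_range <= 0))
    stop("scale_range must be a nondecreasing pair of positive factors")
  if (isFALSE(jitter)) jitter <- list(translation_mm = 0, rotation_deg = 0)
  subjects <- vector("list", n)
  manifest <- data.frame(subject_id = sprintf("P%03d", seq_len(n)),
                         seed = NA_integer_, scale = NA_real_,
                         true_icv_cm3 = NA_real_)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, "subject", i)
    draws <- with_seed(si, list(
      scale = runif(1, scale_range[1], scale_range[2]),
      tr = runif(3, -jitter$translation_mm, jitter$translation_mm),
      rot = runif(3, -jitter$rotation_deg, jitter$rotation_deg)))
    sp_i <- base_spec
    sp_i$semi_axes <- base_spec$semi_axes * draws$scale
    sp_i$center_offset <- base_spec$center_offset + draws$tr
    sp_i$rotation_deg <- base_spec$rotation_deg + draws$rot
    sp_i$seed <- si
    class(sp_i) <- "phantom_spec"
    subjects[[i]] <- make_head_phantom(sp_i)
    manifest$seed[i] <- si
    manifest$scale[i] <- draws$scale
    manifest$true_icv_cm3[i] <- subjects[[i]]$true_icv_cm3
  }
  list(subjects = subjects, manifest = manifest)
}
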