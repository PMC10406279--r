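#' Linear spatial transform (translation / rigid / similarity / affine)
#'
#' Maps a world point x (mm) to \code{matrix \%*\% (x - center) + center +
#' offset}. In the pull-back resampling convention used throughout, a
#' transform maps fixed-space points to moving-space points.
#'
#' @param matrix 3x3 matrix; must be invertible. Identity for
#'   \code{kind = "translation"}; \code{s * R} with R orthonormal, s > 0 for
#'   \code{kind = "similarity"}; orthonormal for \code{kind = "rigid"}.
#' @param offset length-3 translation, mm.
#' @param center length-3 rotation/scaling center, mm.
#' @param kind one of \code{"translation"}, \code{"rigid"},
#'   \code{"similarity"}, \code{"affine"}.
#' @return object of class \code{c("linear_transform", "icv_transform")}.
#' @export
linear_transform <- function(matrix = diag(3), offset = c(0, 0, 0),
                             center = c(0, 0, 0),
                             kind = c("affine", "translation", "rigid",
                                      "similarity")) {
  kind <- match.arg(kind)
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  offset <- as.numeric(offset); center <- as.numeric(center)
  stopifnot(length(offset) == 3, length(center) == 3,
            all(is.finite(matrix)), all(is.finite(offset)),
            all(is.finite(center)))
  dt <- det(matrix)
  if (abs(dt) <= 1e-12) stop("singular linear transform (|det| <= 1e-12)")
  if (kind == "translation" && max(abs(matrix - diag(3))) > 1e-10)
    stop("translation transform must have an identity matrix")
  if (kind %in% c("rigid", "similarity")) {
    mtm <- crossprod(matrix)
    s2 <- mean(diag(mtm))
    if (max(abs(mtm - s2 * diag(3))) > 1e-6 * s2)
      stop(kind, " transform matrix must be s*R with R orthonormal")
    if (kind == "rigid" && abs(s2 - 1) > 1e-6)
      stop("rigid transform matrix must be orthonormal (scale 1)")
  }
  structure(list(kind = kind, matrix = matrix, offset = offset,
                 center = center),
            class = c("linear_transform", "icv_transform"))
}

#' @rdname linear_transform
#' @param t length-3 translation in mm.
#' @export
translation_transform <- function(t) {
  linear_transform(diag(3), t, c(0, 0, 0), kind = "translation")
}

identity_transform <- function() translation_transform(c(0, 0, 0))

# Rz(c) Ry(b) Rx(a) Euler rotation matrix, angles in radians
euler_matrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Cubic B-spline free-form deformation transform
#'
#' \code{T(x) = x + d(x)} where the displacement d interpolates per-control-
#' point displacement vectors with a cubic B-spline basis. The control grid
#' covers \code{domain} with at least one control point of margin per side.
#'
#' @param grid_spacing length-3 control-point spacing, mm.
#' @param domain list with \code{lo}, \code{hi}: world bounding box (mm) of
#'   the fixed image the transform is defined over.
#' @param coefficients optional array \code{c(n1, n2, n3, 3)} of control
#'   point displacements (mm); zeros (identity) when omitted.
#' @return object of class \code{c("bspline_transform", "icv_transform")}.
#' @export
bspline_transform <- function(grid_spacing, domain, coefficients = NULL) {
  grid_spacing <- rep_len(as.numeric(grid_spacing), 3)
  stopifnot(all(grid_spacing > 0))
  lo <- as.numeric(domain$lo); hi <- as.numeric(domain$hi)
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi >= lo))
  # node (0,0,0) one spacing before the domain; enough nodes that the cubic
  # support (l-1 .. l+2) stays in range over the whole domain
  grid_origin <- lo - grid_spacing
  ncp <- floor((hi - lo) / grid_spacing + 1e-9) + 4L
  if (is.null(coefficients)) {
    coefficients <- array(0, c(ncp, 3))
  } else {
    coefficients <- array(as.numeric(coefficients), dim(coefficients))
    if (!identical(dim(coefficients)[1:3], as.integer(ncp)) ||
        dim(coefficients)[4] != 3L)
      stop("coefficients must have dim c(", paste(ncp, collapse = ","),
           ", 3) for this domain and grid spacing")
    if (!all(is.finite(coefficients))) stop("displacements must be finite")
  }
  structure(list(grid_spacing = grid_spacing, grid_origin = grid_origin,
                 ncp = as.integer(ncp), coefficients = coefficients,
                 domain = list(lo = lo, hi = hi)),
            class = c("bspline_transform", "icv_transform"))
}

# Dense displacement-field transform T(x) = x + field(x); used as the
# numeric inverse of a B-spline member. Field stored as array (nx,ny,nz,3).
displacement_field_transform <- function(field, spacing, origin) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L,
            all(is.finite(field)))
  structure(list(field = field, spacing = rep_len(as.numeric(spacing), 3),
                 origin = as.numeric(origin), dim = dim(field)[1:3]),
            class = c("dfield_transform", "icv_transform"))
}

#' Ordered chain of transforms
#'
#' Members are applied in sequence: a fixed-space point goes through the
#' first member, the result through the second, and so on, ending in
#' moving-space.
#'
#' @param ... transforms, or a single list of transforms.
#' @return object of class \code{c("transform_chain", "icv_transform")}.
#' @export
transform_chain <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1]]) &&
      !inherits(members[[1]], "icv_transform"))
    members <- members[[1]]
  if (length(members) == 0L) stop("transform chain must be nonempty")
  ok <- vapply(members, inherits, logical(1), what = "icv_transform")
  if (!all(ok)) stop("all chain members must be transforms")
  structure(list(members = members),
            class = c("transform_chain", "icv_transform"))
}

#' Map world points through a transform
#'
#' @param t a transform or transform chain.
#' @param pts 3 x N matrix of world coordinates (mm).
#' @return 3 x N matrix of mapped coordinates.
#' @export
transform_points <- function(t, pts) UseMethod("transform_points")

#' @export
transform_points.linear_transform <- function(t, pts) {
  shift <- as.numeric(t$center + t$offset - t$matrix %*% t$center)
  t$matrix %*% pts + shift
}

#' @export
transform_points.bspline_transform <- function(t, pts) {
  disp <- cpp_bspline_disp(as.numeric(t$coefficients), t$ncp, t$grid_origin,
                           t$grid_spacing, pts)
  pts + disp
}

#' @export
transform_points.dfield_transform <- function(t, pts) {
  disp <- cpp_field_interp(as.numeric(t$field), t$dim, t$origin, t$spacing,
                           pts)
  pts + disp
}

#' @export
transform_points.transform_chain <- function(t, pts) {
  for (m in t$members) pts <- transform_points(m, pts)
  pts
}

#' Resample a volume through a transform
#'
#' Pull-back convention: output voxel at fixed-space position x receives the
#' input value interpolated at \code{t(x)}. Samples falling outside the
#' input grid take the input's nonzero-mean background value (masks: 0).
#'
#' @param v \code{icv_volume} or \code{icv_mask} (the moving image).
#' @param t transform or chain mapping fixed-space to \code{v}'s space.
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @param target_geometry optional list \code{(dim, spacing, origin)} of the
#'   fixed grid; defaults to \code{v}'s own grid.
#' @param background out-of-domain fill value; default nonzero mean of
#'   \code{v} (0 for masks).
#' @return resampled \code{icv_volume} on the fixed grid.
#' @export
apply_transform <- function(v, t, interpolation = c("linear", "nearest"),
                            target_geometry = NULL, background = NULL) {
  stopifnot(inherits(v, "icv_volume"), inherits(t, "icv_transform"))
  interpolation <- match.arg(interpolation)
  geom <- target_geometry %||% geometry(v)
  if (is.null(background))
    background <- if (inherits(v, "icv_mask")) 0 else nonzero_mean(v)
  pts <- voxel_centers(geom)
  mapped <- transform_points(t, pts)
  idx <- world_to_index0(geometry(v), mapped)
  mode <- if (interpolation == "nearest") 1L else 0L
  vals <- cpp_sample_volume(as.numeric(v$data), dim(v$data), idx, mode,
                            background)
  new_volume(array(vals, geom$dim), geom$spacing, geom$origin,
             v$orientation_label)
}

#' Collapse adjacent linear members of a chain
#'
#' Runs of consecutive linear transforms are merged into a single
#' \code{linear_transform} (matrix product with exact center/offset
#' algebra); B-spline and displacement-field members are kept as-is. The
#' collapsed chain maps every point identically to the original.
#'
#' @param chain a \code{transform_chain} (or a single transform, returned
#'   unchanged).
#' @return a \code{transform_chain}.
#' @export
compose <- function(chain) {
  if (!inherits(chain, "transform_chain")) return(transform_chain(chain))
  kinds_rank <- c(translation = 1, rigid = 2, similarity = 3, affine = 4)
  merge2 <- function(t1, t2) {
    # t1 applied first, then t2
    m <- t2$matrix %*% t1$matrix
    off <- as.numeric(t2$matrix %*% (t1$center + t1$offset - t2$center) +
                        t2$center + t2$offset - t1$center)
    rk <- max(kinds_rank[t1$kind], kinds_rank[t2$kind])
    kind <- names(kinds_rank)[rk]
    # a composed rigid pair can accumulate rounding; re-validate leniently
    out <- try(linear_transform(m, off, t1$center, kind), silent = TRUE)
    if (inherits(out, "try-error"))
      out <- linear_transform(m, off, t1$center, "affine")
    out
  }
  members <- list()
  pending <- NULL
  for (m in chain$members) {
    if (inherits(m, "linear_transform")) {
      pending <- if (is.null(pending)) m else merge2(pending, m)
    } else {
      if (!is.null(pending)) { members <- c(members, list(pending)); pending <- NULL }
      members <- c(members, list(m))
    }
  }
  if (!is.null(pending)) members <- c(members, list(pending))
  transform_chain(members)
}

#' Invert a transform
#'
#' Linear members are inverted in closed form. B-spline (and displacement
#' field) members are inverted numerically as a dense displacement field by
#' fixed-point iteration: for each grid point y the correction v solving
#' \code{T(y + v) = y} is iterated as \code{v <- -d(y + v)}. After
#' convergence the round-trip residual \code{|T(invert(t)(y)) - y|} is
#' checked against \code{tolerance} at every field grid point. Chains are
#' inverted member-wise in reverse order.
#'
#' @param t transform or chain.
#' @param tolerance maximum allowed round-trip residual, mm. Default: 5\% of
#'   the inverse-field grid spacing.
#' @param spacing grid spacing (mm) of the dense inverse field for nonlinear
#'   members; default one eighth of the B-spline control spacing. Pass the
#'   subject voxel spacing for voxel-accurate mask propagation.
#' @param max_iter fixed-point iteration cap (default 100).
#' @return the inverse transform (linear, displacement field, or chain).
#' @export
invert <- function(t, tolerance = NULL, spacing = NULL, max_iter = 100L) {
  UseMethod("invert")
}

#' @export
invert.linear_transform <- function(t, tolerance = NULL, spacing = NULL,
                                    max_iter = 100L) {
  mi <- solve(t$matrix)
  linear_transform(mi, as.numeric(-mi %*% t$offset), t$center, t$kind)
}

# shared numeric inversion for displacement-based transforms
invert_displacement <- function(t, domain, tolerance, spacing, max_iter) {
  disp_at <- function(pts) transform_points(t, pts) - pts
  lo <- domain$lo; hi <- domain$hi
  spacing <- rep_len(as.numeric(spacing), 3)
  if (is.null(tolerance)) tolerance <- 0.05 * min(spacing)
  stopifnot(tolerance > 0)
  # pad the field domain so the inverse is defined slightly beyond the box
  lo <- lo - spacing; hi <- hi + spacing
  nd <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  geom <- list(dim = nd, spacing = spacing, origin = lo)
  y <- voxel_centers(geom)
  v <- matrix(0, 3, ncol(y))
  # damped fixed-point iteration: v <- v - omega*(v + d(y+v)); the damping
  # keeps the iteration contractive for displacement gradients up to ~2
  omega <- 0.5
  for (it in seq_len(max_iter)) {
    delta_v <- v + disp_at(y + v)
    v <- v - omega * delta_v
    if (max(abs(delta_v)) < tolerance / 10) break
  }
  resid <- sqrt(colSums((v + disp_at(y + v))^2))
  worst <- max(resid)
  if (worst > tolerance)
    stop(sprintf(paste0("displacement inversion did not converge within %d ",
                        "iterations: worst residual %.4g mm > tolerance %.4g mm"),
                 max_iter, worst, tolerance))
  displacement_field_transform(array(t(v), c(nd, 3))
                               , spacing, lo)
}

#' @export
invert.bspline_transform <- function(t, tolerance = NULL, spacing = NULL,
                                     max_iter = 100L) {
  if (is.null(spacing)) spacing <- t$grid_spacing / 8
  # the inverse must cover points displaced outside the nominal domain
  pad <- max(abs(t$coefficients))
  dom <- list(lo = t$domain$lo - pad, hi = t$domain$hi + pad)
  invert_displacement(t, dom, tolerance, spacing, max_iter)
}

#' @export
invert.dfield_transform <- function(t, tolerance = NULL, spacing = NULL,
                                    max_iter = 100L) {
  if (is.null(spacing)) spacing <- t$spacing
  pad <- max(abs(t$field))
  lo <- t$origin - pad
  hi <- t$origin + t$spacing * (t$dim - 1) + pad
  invert_displacement(t, list(lo = lo, hi = hi), tolerance, spacing, max_iter)
}

#' @export
invert.transform_chain <- function(t, tolerance = NULL, spacing = NULL,
                                   max_iter = 100L) {
  inv <- lapply(rev(t$members), invert, tolerance = tolerance,
                spacing = spacing, max_iter = max_iter)
  transform_chain(inv)
}

#' Warp a binary mask through a transform
#'
#' The mask is resampled with linear interpolation and thresholded at 0.5,
#' which gives smoother propagated boundaries (lower discretization noise in
#' volume estimates) than nearest-neighbour sampling.
#'
#' @param m \code{icv_mask} (moving).
#' @param t transform mapping target-space points into \code{m}'s space.
#' @param target_geometry list \code{(dim, spacing, origin)} of the output
#'   grid; defaults to \code{m}'s grid.
#' @return \code{icv_mask} on the target grid.
#' @export
warp_mask <- function(m, t, target_geometry = NULL) {
  stopifnot(inherits(m, "icv_mask"))
  geom <- target_geometry %||% geometry(m)
  pts <- voxel_centers(geom)
  mapped <- transform_points(t, pts)
  idx <- world_to_index0(geometry(m), mapped)
  vals <- cpp_sample_volume(as.numeric(m$data), dim(m$data), idx, 0L, 0)
  new_mask(array(as.numeric(vals >= 0.5), geom$dim), geom$spacing,
           geom$origin, m$orientation_label)
}

# ---- plain-text (JSON) transform serialization -----------------------------

transform_to_list <- function(t) {
  if (inherits(t, "linear_transform"))
    list(type = "linear", kind = t$kind, matrix = as.numeric(t$matrix),
         offset = t$offset, center = t$center)
  else if (inherits(t, "bspline_transform"))
    list(type = "bspline", grid_spacing = t$grid_spacing,
         domain = list(lo = t$domain$lo, hi = t$domain$hi),
         ncp = t$ncp, coefficients = as.numeric(t$coefficients))
  else if (inherits(t, "dfield_transform"))
    list(type = "dfield", spacing = t$spacing, origin = t$origin,
         dim = t$dim, field = as.numeric(t$field))
  else if (inherits(t, "transform_chain"))
    list(type = "chain", members = lapply(t$members, transform_to_list))
  else stop("unknown transform class")
}

transform_from_list <- function(x) {
  switch(x$type,
    linear = linear_transform(matrix(x$matrix, 3, 3), x$offset, x$center,
                              x$kind),
    bspline = bspline_transform(x$grid_spacing, x$domain,
                                array(x$coefficients, c(x$ncp, 3))),
    dfield = displacement_field_transform(array(x$field, c(x$dim, 3)),
                                          x$spacing, x$origin),
    chain = transform_chain(lapply(x$members, transform_from_list)),
    stop("unknown transform type: ", x$type))
}

#' Write / read a transform as a JSON parameter file
#'
#' Enables pipeline resumption and audit of every registration stage.
#'
#' @param t transform or chain.
#' @param path output (input) file path.
#' @return \code{path} (\code{write_transform}) or the transform
#'   (\code{read_transform}).
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(transform_to_list(t), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE,
                                          simplifyMatrix = FALSE))
}
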