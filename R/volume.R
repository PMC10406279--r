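#' 3D scalar volume with voxel geometry
#'
#' Container for a grayscale ultrasound volume: a 3D array plus voxel
#' spacing (mm), world origin (mm) and a head-orientation label. Voxel
#' indices are 0-based in world mapping: voxel \code{(i,j,k)} (0-based) sits
#' at \code{origin + spacing * (i,j,k)}.
#'
#' @param data 3D numeric array of finite, non-negative grayscale values.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param orientation_label one of \code{"Left"}, \code{"Right"},
#'   \code{"unknown"}: which of the two primary fetal head orientations the
#'   scan is in.
#' @return An object of class \code{icv_volume}.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation_label = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D: 'data' must be a 3-dimensional array")
  if (!all(is.finite(data)))
    stop("grayscale values must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing: all three components must be finite and > 0")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin: must be three finite numbers")
  orientation_label <- match.arg(orientation_label,
                                 c("Left", "Right", "unknown"))
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation_label = orientation_label),
            class = "icv_volume")
}

#' Binary mask sharing a volume's geometry
#'
#' @param data 3D array with values in \{0, 1\}.
#' @inheritParams new_volume
#' @return An object of class \code{icv_mask}.
#' @export
new_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     orientation_label = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D: mask 'data' must be a 3-dimensional array")
  if (!all(data %in% c(0, 1)))
    stop("mask values must all be 0 or 1")
  v <- new_volume(data + 0, spacing, origin, orientation_label)
  class(v) <- c("icv_mask", "icv_volume")
  v
}

#' @export
print.icv_volume <- function(x, ...) {
  kind <- if (inherits(x, "icv_mask")) "binary mask" else "volume"
  cat(sprintf("<icv %s> %s voxels, spacing %s mm, origin %s mm, orientation %s\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              x$orientation_label))
  if (inherits(x, "icv_mask"))
    cat(sprintf("  %d foreground voxels (%.3f cm^3)\n", sum(x$data),
                mask_volume_cm3(x)))
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param v an \code{icv_volume} or \code{icv_mask}.
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(v) prod(v$spacing)

#' Total mask volume in cm^3 (voxel count times voxel volume)
#' @param m an \code{icv_mask}.
#' @return scalar, cm^3.
#' @export
mask_volume_cm3 <- function(m) sum(m$data) * voxel_volume_mm3(m) / 1000

# geometry descriptor shared by volumes and masks
geometry <- function(v) list(dim = dim(v$data), spacing = v$spacing,
                             origin = v$origin)

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geometry(a); gb <- geometry(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

# 3 x N world coordinates of all (or selected linear-index) voxel centers
voxel_centers <- function(geom, idx = NULL) {
  d <- geom$dim
  if (is.null(idx)) idx <- seq_len(prod(d))
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  rbind(geom$origin[1] + geom$spacing[1] * i,
        geom$origin[2] + geom$spacing[2] * j,
        geom$origin[3] + geom$spacing[3] * k)
}

world_to_index0 <- function(geom, pts) {
  (pts - geom$origin) / geom$spacing
}

# world bounding box (voxel centers) of a geometry
world_bbox <- function(geom) {
  list(lo = geom$origin,
       hi = geom$origin + geom$spacing * (geom$dim - 1))
}

# mean of nonzero voxels; the background fill value used throughout
nonzero_mean <- function(v) {
  nz <- v$data[v$data != 0]
  if (length(nz) == 0) stop("volume is all zero: nonzero mean undefined")
  mean(nz)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a NIfTI-1 file into an \code{\link{new_volume}} container, taking
#' spacing from the header pixdim and the origin from the qform/sform
#' translation. Units are mm.
#'
#' @param path path to a readable \code{.nii} or \code{.nii.gz} file
#'   containing a 3D image.
#' @param orientation_label head-orientation label to attach (the file
#'   format does not carry it); default \code{"unknown"}.
#' @param mask logical; read as a binary \code{icv_mask} (values are
#'   validated to be 0/1).
#' @return \code{icv_volume} (or \code{icv_mask}).
#' @export
read_volume <- function(path, orientation_label = "unknown", mask = FALSE) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected 3D image in ", path, " but found ", length(d), " axes")
  }
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(spacing <= 0))
    stop("non-positive spacing in header of ", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  arr <- array(as.numeric(img), d)
  if (mask) new_mask(round(arr), spacing, origin, orientation_label)
  else new_volume(arr, spacing, origin, orientation_label)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks are stored with an 8-bit integer scalar type; volumes as float32.
#' Overwrites an existing file (logged).
#'
#' @param v \code{icv_volume} or \code{icv_mask}.
#' @param path output path (\code{.nii} or \code{.nii.gz}); parent directory
#'   must exist and be writable.
#' @param log_file optional path of a plain-text audit log.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(v, path, log_file = NULL) {
  stopifnot(inherits(v, "icv_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  if (file.exists(path))
    log_line("overwrite", path, file = log_file)
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  m <- diag(c(v$spacing, 1))
  m[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  dtype <- if (inherits(v, "icv_mask")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Replace zero voxels by the average grayscale
#'
#' Sweep-boundary preprocessing: zero voxels (the padding outside the
#' ultrasound sweep field of view, plus acoustic-shadow dropout) are filled
#' with the mean grayscale of the scan so the sharp black border does not
#' attract the intensity-based registration. The mean is computed over the
#' nonzero voxels: the zeros being replaced are padding, and including them
#' would drag the fill value toward black, partially recreating the edge the
#' step is meant to remove.
#'
#' @param v \code{icv_volume} with at least one nonzero voxel.
#' @return the volume with every exactly-zero voxel set to the nonzero mean;
#'   all other voxels unchanged.
#' @export
replace_zero_voxels <- function(v) {
  stopifnot(inherits(v, "icv_volume"))
  m <- nonzero_mean(v)   # errors on an all-zero volume
  z <- v$data == 0
  if (any(z)) v$data[z] <- m
  v
}

#' Mirror a scan into a target head orientation
#'
#' The two primary fetal head orientations ("Left"/"Right") are related by a
#' mirror flip about the first (left-right) voxel axis. The flip permutes
#' voxels only, so the grayscale histogram is preserved exactly. The source
#' orientation must be known (it is assigned manually per scan); mirroring
#' is performed about the grid center and the world origin is kept, i.e.
#' orientation handling is an index-space operation.
#'
#' @param v \code{icv_volume} (or \code{icv_mask}) with a known
#'   \code{orientation_label}.
#' @param target \code{"Left"} or \code{"Right"}.
#' @return the volume in the target orientation.
#' @export
canonicalize_orientation <- function(v, target = c("Left", "Right")) {
  stopifnot(inherits(v, "icv_volume"))
  target <- match.arg(target)
  if (v$orientation_label == "unknown")
    stop("unknown source orientation: label this scan 'Left' or 'Right' ",
         "manually (e.g. in the run config) before canonicalizing")
  if (v$orientation_label == target) return(v)
  n1 <- dim(v$data)[1]
  v$data <- v$data[n1:1, , , drop = FALSE]
  v$orientation_label <- target
  v
}
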