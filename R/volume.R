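#' @useDynLib auxdose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd coef lm dnorm dist
NULL

VOLUME_KINDS <- c("HU", "DENSITY", "DOSE", "MR")

# Default value used for space outside the source grid when resampling,
# chosen per physical unit: air for HU, vacuum/zero otherwise.
default_fill <- function(kind) {
  switch(kind, HU = -1000, DENSITY = 0, DOSE = 0, MR = 0)
}

#' Voxel volume on a regular axis-aligned grid
#'
#' A scalar 3-D volume in patient coordinates. The grid is axis aligned:
#' +x is the patient's left, +y anterior, +z superior (supine, head first).
#' All positions are in mm and the coordinate of voxel `[1,1,1]` (its center)
#' is `origin`.
#'
#' @param values 3-D numeric array. Units depend on `kind`: Hounsfield units,
#'   relative mass density (g/cm^3), Gy, or arbitrary MR intensity.
#' @param spacing Per-axis voxel size in mm (length 3, all > 0).
#' @param origin Position (mm) of the center of voxel `[1,1,1]`.
#' @param kind One of `"HU"`, `"DENSITY"`, `"DOSE"`, `"MR"`.
#' @return An object of class `rt_volume`.
#' @export
rt_volume <- function(values, spacing, origin = c(0, 0, 0),
                      kind = c("HU", "DENSITY", "DOSE", "MR")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(!is.finite(values)))
    stop("volume values must be finite")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin,
                 kind = kind),
            class = "rt_volume")
}

#' @export
print.rt_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rt_volume %s> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              x$kind, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

vol_dim <- function(vol) dim(vol$values)

#' Grid description (dimensions, spacing, origin) of a volume or ROI
#' @param x An `rt_volume` or `rt_roi`.
#' @return A list with elements `dim`, `spacing`, `origin`.
#' @export
vol_grid <- function(x) {
  if (inherits(x, "rt_roi"))
    return(list(dim = dim(x$mask), spacing = x$spacing, origin = x$origin))
  list(dim = dim(x$values), spacing = x$spacing, origin = x$origin)
}

as_grid <- function(g) {
  if (inherits(g, c("rt_volume", "rt_roi"))) g <- vol_grid(g)
  stopifnot(is.list(g), all(c("dim", "spacing", "origin") %in% names(g)))
  g$dim <- as.integer(g$dim)
  g$spacing <- as.numeric(g$spacing)
  g$origin <- as.numeric(g$origin)
  g
}

grids_equal <- function(a, b, tol = 1e-6) {
  a <- as_grid(a); b <- as_grid(b)
  identical(a$dim, b$dim) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

# per-axis voxel center coordinates (mm)
grid_axis_coords <- function(grid, axis) {
  grid <- as_grid(grid)
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing[axis]
}

# n x 3 matrix of world coordinates of all voxel centers (column-major
# order); the last result is memoized since resampling repeatedly targets
# the same planning grid
.coords_cache <- new.env(parent = emptyenv())

grid_coords <- function(grid) {
  grid <- as_grid(grid)
  key <- paste(c(grid$dim, grid$spacing, grid$origin), collapse = "/")
  if (identical(.coords_cache$key, key)) return(.coords_cache$pts)
  pts <- grid_coords_impl(grid)
  .coords_cache$key <- key
  .coords_cache$pts <- pts
  pts
}

grid_coords_impl <- function(grid) {
  x <- grid_axis_coords(grid, 1)
  y <- grid_axis_coords(grid, 2)
  z <- grid_axis_coords(grid, 3)
  nx <- length(x); ny <- length(y); nz <- length(z)
  cbind(rep(x, times = ny * nz),
        rep(rep(y, each = nx), times = nz),
        rep(z, each = nx * ny))
}

# ---------------------------------------------------------------------------
# Rigid transforms
# ---------------------------------------------------------------------------

#' Rigid (proper) spatial transform
#'
#' Maps a point `p` (mm) to `rotation %*% p + translation`.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (det +1), not a reflection")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` applies `b` first, then `a` (i.e. `a %o% b`).
#' @param a,b `rigid_transform` objects.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @export
rt_invert <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points
#' @param t A `rigid_transform`.
#' @param pts n x 3 matrix (or length-3 vector) of points in mm.
#' @return n x 3 matrix of transformed points.
#' @export
rt_apply <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  sweep(pts %*% t(t$rotation), 2, t$translation, "+")
}

#' Elementary rotations about the patient axes
#'
#' @param deg Rotation angle in degrees (right-handed about the axis).
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Rotation angle (degrees) of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @export
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

# ---------------------------------------------------------------------------
# Resampling
# ---------------------------------------------------------------------------

#' Resample a volume onto a target grid under a rigid transform
#'
#' The transform maps source coordinates to target coordinates; each target
#' voxel center is pulled back through the inverse transform and the source
#' volume is interpolated there. Positions outside the source grid receive
#' `fill` (by default the kind-specific background: -1000 HU, otherwise 0).
#'
#' Placement transforms should be composed analytically and applied in a
#' single resampling step: repeated nearest-neighbor resampling erodes small
#' structures (see [cumulative_resample_report()]).
#'
#' @param vol An `rt_volume`.
#' @param transform A `rigid_transform` mapping source to target coordinates.
#' @param target_grid Grid description (see [vol_grid()]) or an
#'   `rt_volume`/`rt_roi` whose grid is used.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill Fill value outside the source grid.
#' @return An `rt_volume` on the target grid.
#' @export
resample_volume <- function(vol, transform = rt_identity(), target_grid = vol,
                            interpolation = c("trilinear", "nearest"),
                            fill = NULL) {
  if (!interpolation[1] %in% c("trilinear", "nearest"))
    stop("unknown interpolation: ", interpolation[1])
  interpolation <- match.arg(interpolation)
  grid <- as_grid(target_grid)
  if (is.null(fill)) fill <- default_fill(vol$kind)
  pts <- grid_coords(grid)
  src <- rt_apply(rt_invert(transform), pts)
  sampler <- if (interpolation == "trilinear") cpp_sample_trilinear else cpp_sample_nearest
  vals <- sampler(vol$values, vol_dim(vol), vol$spacing, vol$origin, src, fill)
  rt_volume(array(vals, dim = grid$dim), grid$spacing, grid$origin, vol$kind)
}

# ---------------------------------------------------------------------------
# NIfTI I/O (axis-aligned volumes + JSON sidecar carrying the kind tag)
# ---------------------------------------------------------------------------

#' Read / write volumes as NIfTI-1
#'
#' Volumes are stored as `.nii.gz` with a diagonal (axis-aligned) affine and a
#' JSON sidecar (`<path>.json`) recording the `kind` tag. Reading a file with
#' an oblique orientation matrix or with more than 3 dimensions is an error.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param kind Override for the kind tag when no sidecar is present.
#' @return `read_volume`: an `rt_volume`; `write_volume`: the path, invisibly.
#' @export
read_volume <- function(path, kind = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3D volume, got ", length(dim(img)), "D")
  a <- array(as.vector(img, mode = "double"), dim = dim(img))
  aff <- RNifti::xform(img)
  for (i in 1:3) for (j in 1:3) {
    if (i != j && abs(aff[i, j]) > 1e-4 * max(abs(diag(aff[1:3, 1:3]))))
      stop(sprintf("oblique orientation: axis %d has off-diagonal component", j))
  }
  if (any(diag(aff[1:3, 1:3]) <= 0))
    stop("expected positive axis-aligned orientation on all axes")
  spacing <- diag(aff[1:3, 1:3])
  origin <- aff[1:3, 4]
  sidecar <- paste0(path, ".json")
  if (is.null(kind)) {
    kind <- if (file.exists(sidecar))
      jsonlite::read_json(sidecar)$kind
    else "HU"
  }
  rt_volume(a, spacing, origin, kind)
}

#' @rdname read_volume
#' @param vol An `rt_volume`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(kind = vol$kind), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
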