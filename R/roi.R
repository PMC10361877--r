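#' Region of interest: a named binary mask on a volume grid
#'
#' @param mask Logical (or 0/1) 3-D array on the grid.
#' @param spacing,origin Grid geometry (mm), as in [rt_volume()].
#' @param name ROI name.
#' @param meta Free-form list of nominal-geometry metadata (e.g. nominal
#'   sphere diameter or shell thickness in mm).
#' @return An object of class `rt_roi`.
#' @export
rt_roi <- function(mask, spacing, origin = c(0, 0, 0), name = "roi",
                   meta = list()) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (!is.logical(mask)) mask <- array(mask != 0, dim = dim(mask))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(list(mask = mask, spacing = spacing, origin = as.numeric(origin),
                 name = as.character(name), meta = meta),
            class = "rt_roi")
}

#' Build an ROI on the grid of an existing volume
#' @param vol An `rt_volume` supplying the grid.
#' @param mask Logical array, same dimensions as `vol`.
#' @inheritParams rt_roi
#' @export
roi_from_volume <- function(vol, mask, name = "roi", meta = list()) {
  stopifnot(identical(dim(mask), dim(vol$values)))
  rt_roi(mask, vol$spacing, vol$origin, name, meta)
}

#' @export
print.rt_roi <- function(x, ...) {
  cat(sprintf("<rt_roi '%s'> %d voxels (%.2f cc) on %s grid\n",
              x$name, sum(x$mask), volume_cc(x),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!grids_equal(a, b))
    stop("ROIs/volumes are not on the same grid")
  invisible(TRUE)
}

#' Voxelwise set algebra on two ROIs
#'
#' Union, difference (`a` minus `b`) or intersection of two ROIs defined on
#' the same grid. This is the ROI-algebra primitive used to carve a
#' mask shell out of an expanded external contour.
#'
#' @param a,b `rt_roi` objects on the same grid.
#' @param op One of `"union"`, `"difference"`, `"intersection"`.
#' @param name Name for the result.
#' @return An `rt_roi` on the same grid.
#' @export
roi_algebra <- function(a, b, op = c("union", "difference", "intersection"),
                        name = NULL) {
  op <- match.arg(op)
  check_same_grid(a, b)
  m <- switch(op,
              union = a$mask | b$mask,
              difference = a$mask & !b$mask,
              intersection = a$mask & b$mask)
  if (is.null(name)) name <- sprintf("(%s %s %s)", a$name, op, b$name)
  rt_roi(m, a$spacing, a$origin, name, a$meta)
}

#' Isotropic margin expansion of an ROI
#'
#' Adds every voxel whose Euclidean center-to-center distance to the ROI is at
#' most `margin` mm, computed with an exact (anisotropy-aware) distance
#' transform. This implements a metric expansion "ROI + d" rather than a
#' structuring-element dilation, because the margin is specified in mm.
#' Expansion is monotone in the margin and `margin = 0` is the identity.
#'
#' @param roi An `rt_roi`.
#' @param margin Margin in mm, `>= 0` (erosion is not supported).
#' @param name Name for the result.
#' @return Expanded `rt_roi`.
#' @export
expand_roi <- function(roi, margin, name = NULL) {
  if (!is.finite(margin) || margin < 0)
    stop("margin must be >= 0 mm (erosion is out of scope)")
  if (is.null(name)) name <- sprintf("%s+%gmm", roi$name, margin)
  if (margin == 0 || !any(roi$mask)) {
    out <- roi
    out$name <- name
    return(out)
  }
  d2 <- cpp_edt_sq(roi$mask, dim(roi$mask), roi$spacing)
  m <- array(d2 <= margin^2 + 1e-9, dim = dim(roi$mask))
  rt_roi(m, roi$spacing, roi$origin, name,
         c(roi$meta, list(expanded_by_mm = margin)))
}

#' Centroid (mm) of an ROI
#'
#' Mean of the member-voxel center coordinates, in patient coordinates.
#' @param roi A non-empty `rt_roi`.
#' @return Length-3 numeric vector (mm).
#' @export
roi_centroid <- function(roi) {
  idx <- which(roi$mask)
  if (length(idx) == 0) stop("empty ROI")
  d <- dim(roi$mask)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  c(roi$origin[1] + mean(i) * roi$spacing[1],
    roi$origin[2] + mean(j) * roi$spacing[2],
    roi$origin[3] + mean(k) * roi$spacing[3])
}

#' Volume of an ROI in cc
#' @param roi An `rt_roi`.
#' @export
volume_cc <- function(roi) {
  sum(roi$mask) * prod(roi$spacing) / 1000
}

# Resample an ROI mask (nearest neighbor) onto a target grid under a rigid
# transform; used by template placement.
resample_roi <- function(roi, transform = rt_identity(), target_grid,
                         name = roi$name) {
  vol <- rt_volume(array(as.double(roi$mask), dim = dim(roi$mask)),
                   roi$spacing, roi$origin, "DENSITY")
  res <- resample_volume(vol, transform, target_grid, "nearest", fill = 0)
  rt_roi(res$values > 0.5, res$spacing, res$origin, name, roi$meta)
}

# voxelize a sphere on a grid
voxelize_sphere <- function(grid, center, diameter, name = "sphere") {
  grid <- as_grid(grid)
  x <- grid_axis_coords(grid, 1) - center[1]
  y <- grid_axis_coords(grid, 2) - center[2]
  z <- grid_axis_coords(grid, 3) - center[3]
  r2 <- (diameter / 2)^2
  m2 <- outer(x^2, y^2, "+")
  m <- array(FALSE, grid$dim)
  for (k in seq_along(z)) m[, , k] <- (m2 + z[k]^2) <= r2
  rt_roi(m, grid$spacing, grid$origin, name,
         meta = list(nominal_diameter_mm = diameter, center_mm = center))
}

# voxelize an axis-aligned box given as c(x0,x1,y0,y1,z0,z1) in mm;
# half-open on the upper face so abutting boxes partition without overlap
voxelize_box <- function(grid, box, name = "box") {
  grid <- as_grid(grid)
  x <- grid_axis_coords(grid, 1)
  y <- grid_axis_coords(grid, 2)
  z <- grid_axis_coords(grid, 3)
  inx <- x >= box[1] & x < box[2]
  iny <- y >= box[3] & y < box[4]
  inz <- z >= box[5] & z < box[6]
  m <- array(FALSE, grid$dim)
  if (any(inx) && any(iny) && any(inz))
    m[inx, iny, inz] <- TRUE
  rt_roi(m, grid$spacing, grid$origin, name, meta = list(box_mm = box))
}

# voxelize a y-axis-aligned cylinder (height along y)
voxelize_cylinder_y <- function(grid, center, diameter, height, name = "cyl") {
  grid <- as_grid(grid)
  x <- grid_axis_coords(grid, 1) - center[1]
  y <- grid_axis_coords(grid, 2) - center[2]
  z <- grid_axis_coords(grid, 3) - center[3]
  r2 <- (diameter / 2)^2
  iny <- abs(y) <= height / 2
  mxz <- outer(x^2, z^2, "+") <= r2   # nx x nz
  m <- array(FALSE, grid$dim)
  for (j in which(iny)) m[, j, ] <- mxz
  rt_roi(m, grid$spacing, grid$origin, name,
         meta = list(nominal_diameter_mm = diameter,
                     nominal_height_mm = height, center_mm = center))
}
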