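#' Default auxiliary structure template specification
#'
#' Geometry and densities of the immobilization devices modeled by the
#' template: a two-material mask holder (carbon board at 1.2 g/cm^3 over a
#' 1.0 g/cm^3 backing), a two-material flat tabletop (1.7 g/cm^3 shell over
#' 0.11 g/cm^3 foam core), and four MR-visible cylindrical silicone markers
#' (height 5 mm, diameter 3 mm) embedded near the corners of the holder
#' board, each surrounded by a 5 mm diameter spherical marker ROI used as the
#' placement search region. Boxes are `c(x0, x1, y0, y1, z0, z1)` in mm in
#' the template frame (head center at the origin, +y anterior).
#'
#' @return A list understood by [define_template()].
#' @export
default_ast_spec <- function() {
  list(
    spacing = 1,
    components = list(
      holder_high = list(density = 1.2,  box = c(-120, 120, -116, -104, -95, 40)),
      holder_low  = list(density = 1.0,  box = c(-120, 120, -128, -116, -95, 40)),
      table_high  = list(density = 1.7,  box = c(-120, 120, -132, -128, -98, 68)),
      table_low   = list(density = 0.11, box = c(-120, 120, -162, -132, -98, 68))
    ),
    markers = list(
      positions = rbind(c(-70, -110, -85),
                        c( 70, -110, -85),
                        c(-70, -110,  30),
                        c( 70, -113,  30)),
      roi_diameter = 5,
      marker_diameter = 3,
      marker_height = 5,
      marker_density = 1.05
    )
  )
}

#' Define the auxiliary structure template (AST)
#'
#' Voxelizes the device components and marker ROIs of a template
#' specification onto the template's own isotropic source grid (1 mm by
#' default). The template carries, for each component, a binary mask and a
#' relative mass density; placement later resamples these masks once, from
#' this source grid, onto the planning grid.
#'
#' @param spec Template specification: a list as returned by
#'   [default_ast_spec()], or a path to a JSON file with the same structure.
#' @return An object of class `aux_template` with elements `grid`,
#'   `components` (named list of `rt_roi` + density), `marker_rois` (list of
#'   4 `rt_roi`), `marker_points` (4 x 3 matrix) and `spec`.
#' @export
define_template <- function(spec = default_ast_spec()) {
  if (is.character(spec)) spec <- read_ast_spec(spec)
  mk <- spec$markers
  pts <- as.matrix(mk$positions)
  if (nrow(pts) != 4) stop("template must define exactly 4 markers, got ", nrow(pts))
  if (points_collinear(pts)) stop("template markers must not be collinear")
  # canonical (z, y, x) order, matching the sort used by detect_markers
  pts <- pts[order(pts[, 3], pts[, 2], pts[, 1]), , drop = FALSE]
  sp <- spec$spacing %||% 1
  boxes <- do.call(rbind, lapply(spec$components, function(cc) cc$box))
  # generous pad so small placement adjustments do not clip the grid
  pad <- max(mk$roi_diameter %||% 5, 12)
  lo <- pmin(apply(boxes[, c(1, 3, 5), drop = FALSE], 2, min),
             apply(pts, 2, min) - mk$roi_diameter) - pad
  hi <- pmax(apply(boxes[, c(2, 4, 6), drop = FALSE], 2, max),
             apply(pts, 2, max) + mk$roi_diameter) + pad
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  grid <- list(dim = dims, spacing = rep(sp, 3), origin = lo)

  components <- lapply(names(spec$components), function(nm) {
    cc <- spec$components[[nm]]
    roi <- voxelize_box(grid, cc$box, name = nm)
    list(roi = roi, density = cc$density)
  })
  names(components) <- names(spec$components)

  marker_rois <- lapply(seq_len(4), function(i) {
    voxelize_sphere(grid, pts[i, ], mk$roi_diameter %||% 5,
                    name = sprintf("marker_roi_%d", i))
  })

  structure(list(grid = grid, components = components,
                 marker_rois = marker_rois, marker_points = pts, spec = spec),
            class = "aux_template")
}

#' @export
print.aux_template <- function(x, ...) {
  cat(sprintf("<aux_template> %s grid at %g mm, %d components, 4 marker ROIs\n",
              paste(x$grid$dim, collapse = "x"), x$grid$spacing[1],
              length(x$components)))
  for (nm in names(x$components))
    cat(sprintf("  %-12s rho = %5.2f g/cm^3, %8.1f cc\n", nm,
                x$components[[nm]]$density, volume_cc(x$components[[nm]]$roi)))
  invisible(x)
}

#' Read / write a template specification as JSON
#' @param path File path.
#' @export
read_ast_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$markers$positions <- as.matrix(s$markers$positions)
  for (nm in names(s$components))
    s$components[[nm]]$box <- as.numeric(s$components[[nm]]$box)
  s
}

#' @rdname read_ast_spec
#' @param spec Template specification list.
#' @export
write_ast_spec <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

points_collinear <- function(pts, tol = 1e-6) {
  c0 <- sweep(pts, 2, colMeans(pts))
  s <- svd(c0)$d
  s[2] < tol * max(s[1], 1)
}

#' Detect MR-visible markers in a pseudo-MR volume
#'
#' Thresholds the MR volume to the display band
#' `[level - width/2, level + width/2]` in which the silicone markers are
#' visible (defaults: level 100, width 200 in arbitrary display units),
#' optionally removes voxels inside the patient external contour, labels the
#' remaining voxels into 6-connected components, and keeps components whose
#' volume is consistent with a 5 mm x diameter-3 mm marker cylinder (within
#' +/-50% by default). Exactly four surviving candidates are required.
#'
#' @param mr An `rt_volume` of kind `"MR"`.
#' @param level,width Display-band center and width.
#' @param external Optional `rt_roi` external contour to exclude.
#' @param nominal_volume_mm3 Expected marker volume (default: 5 mm cylinder of
#'   diameter 3 mm).
#' @param volume_tol Relative tolerance on blob volume.
#' @return 4 x 3 matrix of marker centroids (mm), sorted lexicographically by
#'   (z, y, x) so correspondence with template markers is canonical.
#' @export
detect_markers <- function(mr, level = 100, width = 200, external = NULL,
                           nominal_volume_mm3 = pi * 1.5^2 * 5,
                           volume_tol = 0.5) {
  lo <- level - width / 2
  hi <- level + width / 2
  m <- mr$values >= lo & mr$values <= hi
  if (!is.null(external)) {
    check_same_grid(mr, external)
    m <- m & !external$mask
  }
  lab <- cpp_label3d(m, dim(mr$values))
  if (!any(lab > 0)) stop("marker detection failed: 0 candidates in band")
  vox_mm3 <- prod(mr$spacing)
  counts <- tabulate(lab)
  # voxel-count bounds (floor/ceiling) so grid discretization of the small
  # cylinder cannot push a true marker just outside the tolerance band
  lo_n <- max(1, floor(nominal_volume_mm3 * (1 - volume_tol) / vox_mm3))
  hi_n <- ceiling(nominal_volume_mm3 * (1 + volume_tol) / vox_mm3)
  keep <- which(counts >= lo_n & counts <= hi_n)
  if (length(keep) != 4)
    stop(sprintf("marker detection failed: %d candidates after volume filtering (expected 4)",
                 length(keep)))
  cent <- t(vapply(keep, function(l) {
    roi <- rt_roi(array(lab == l, dim(mr$values)), mr$spacing, mr$origin)
    roi_centroid(roi)
  }, numeric(3)))
  cent[order(cent[, 3], cent[, 2], cent[, 1]), , drop = FALSE]
}

#' Least-squares rigid registration of corresponding point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing
#' `sum_i || R p_i + t - q_i ||^2` via SVD of the cross-covariance, with the
#' determinant correction that turns a reflection-optimal solution into the
#' best proper rotation. Points correspond by row order; if the residual of
#' the canonical ordering exceeds `permute_threshold_mm`, all 24 permutations
#' of the detected set are tried and the minimum-residual one is used (the
#' four markers are well separated, so this fallback rarely triggers).
#'
#' @param template_points n x 3 matrix of source points (n >= 3, not
#'   collinear).
#' @param detected_points n x 3 matrix of target points.
#' @param permute_threshold_mm RMS residual above which correspondence by
#'   permutation search is attempted (only for n = 4).
#' @return A `rigid_transform` with attribute `rms_mm` (root-mean-square
#'   residual).
#' @export
fit_rigid <- function(template_points, detected_points,
                      permute_threshold_mm = 3) {
  p <- as.matrix(template_points)
  q <- as.matrix(detected_points)
  stopifnot(nrow(p) == nrow(q), ncol(p) == 3, ncol(q) == 3, nrow(p) >= 3)
  if (points_collinear(p) || points_collinear(q))
    stop("degenerate (collinear) point set: rigid fit is not unique")
  fit <- kabsch(p, q)
  if (attr(fit, "rms_mm") > permute_threshold_mm && nrow(p) == 4) {
    perms <- perm4()
    fits <- lapply(perms, function(pr) kabsch(p, q[pr, , drop = FALSE]))
    rms <- vapply(fits, attr, numeric(1), "rms_mm")
    fit <- fits[[which.min(rms)]]
  }
  fit
}

kabsch <- function(p, q) {
  pc <- colMeans(p); qc <- colMeans(q)
  H <- crossprod(sweep(p, 2, pc), sweep(q, 2, qc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - as.numeric(R %*% pc)
  tr <- rigid_transform(R, t)
  res <- rt_apply(tr, p) - q
  attr(tr, "rms_mm") <- sqrt(mean(rowSums(res^2)))
  tr
}

perm4 <- function() {
  out <- list()
  for (a in 1:4) for (b in 1:4) for (c in 1:4) for (d in 1:4)
    if (length(unique(c(a, b, c, d))) == 4)
      out[[length(out) + 1]] <- c(a, b, c, d)
  out
}

#' Place the template onto a target grid
#'
#' Applies a single rigid placement transform to every template component and
#' marker ROI and voxelizes them onto the target grid with one
#' nearest-neighbor resampling from the template's source grid. Composing the
#' placement analytically and resampling once (instead of iterating
#' translate-rotate-resample) avoids the cumulative interpolation loss that
#' makes small structures disappear.
#'
#' @param template An `aux_template`.
#' @param transform A `rigid_transform` mapping template to target
#'   coordinates.
#' @param target_grid Target grid (see [vol_grid()]).
#' @param detected_points Optional 4 x 3 matrix of detected marker centroids;
#'   if given, a containment check records whether each lies inside its
#'   placed marker ROI.
#' @return List with `rois` (placed component `rt_roi`s), `overrides`
#'   (density overrides for [compose_density_map()]), `marker_rois`,
#'   `marker_points` (transformed template marker positions) and
#'   `containment` (logical 4-vector or NULL).
#' @export
place_template <- function(template, transform = rt_identity(), target_grid,
                           detected_points = NULL) {
  grid <- as_grid(target_grid)
  glo <- grid$origin - 0.5 * grid$spacing
  ghi <- grid$origin + (grid$dim - 0.5) * grid$spacing

  place_one <- function(roi) {
    box <- roi$meta$box_mm
    if (!is.null(box)) {
      corners <- as.matrix(expand.grid(box[1:2], box[3:4], box[5:6]))
      tc <- rt_apply(transform, corners)
      if (any(sweep(tc, 2, glo, "<") ) || any(sweep(tc, 2, ghi, ">")))
        stop(sprintf("placed component '%s' is clipped by the target grid",
                     roi$name))
    }
    resample_roi(roi, transform, grid, name = roi$name)
  }

  rois <- lapply(template$components, function(cc) place_one(cc$roi))
  overrides <- lapply(names(template$components), function(nm) {
    density_override(rois[[nm]], template$components[[nm]]$density,
                     priority_of(nm))
  })
  names(overrides) <- names(template$components)
  marker_rois <- lapply(template$marker_rois, function(r)
    resample_roi(r, transform, grid, name = r$name))
  marker_points <- rt_apply(transform, template$marker_points)

  containment <- NULL
  if (!is.null(detected_points)) {
    containment <- vapply(seq_len(nrow(detected_points)), function(i) {
      r <- marker_rois[[i]]
      v <- cpp_sample_nearest(array(as.double(r$mask), dim(r$mask)),
                              dim(r$mask), r$spacing, r$origin,
                              matrix(detected_points[i, ], 1), 0)
      v > 0.5
    }, logical(1))
  }
  list(rois = rois, overrides = overrides, marker_rois = marker_rois,
       marker_points = marker_points, containment = containment)
}

# override priority convention: markers > mask > holder > table > anatomy
priority_of <- function(name) {
  if (grepl("^marker", name)) return(4L)
  if (grepl("^mask", name)) return(3L)
  if (grepl("^holder", name)) return(2L)
  if (grepl("^table", name)) return(1L)
  0L
}

#' Small random placement adjustments around the template center
#'
#' Draws `n` rigid transforms emulating interactive placement nudges: a
#' rotation of up to `rot_deg` about each axis through the template's
#' geometric center plus a translation of up to `trans_mm` per axis.
#'
#' @param template An `aux_template`.
#' @param n Number of transforms.
#' @param rot_deg,trans_mm Maximum per-axis rotation (degrees) and
#'   translation (mm).
#' @param seed Seed for the draw.
#' @return List of `rigid_transform`s.
#' @export
placement_jitter <- function(template, n = 10, rot_deg = 1, trans_mm = 1,
                             seed = 1) {
  g <- as_grid(template$grid)
  center <- g$origin + (g$dim - 1) * g$spacing / 2
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    R <- rot_z(runif(1, -rot_deg, rot_deg)) %*%
      rot_y(runif(1, -rot_deg, rot_deg)) %*%
      rot_x(runif(1, -rot_deg, rot_deg))
    t <- runif(3, -trans_mm, trans_mm)
    # rotate about the template center, then translate
    rigid_transform(R, center - as.numeric(R %*% center) + t)
  })
}

#' Volume retention under sequential vs composed resampling
#'
#' Resamples every template component (and the small marker ROIs) through a
#' sequence of rigid transforms in two ways: sequentially, re-voxelizing onto
#' the template grid after each step (as an interactive translate/rotate
#' placement does), and in a single pass with the analytically composed
#' transform. Reports the fraction of the original voxel volume retained in
#' each mode; small structures lose volume under sequential interpolation
#' while a single composed resampling preserves them.
#'
#' The default resampling emulates partial-volume voxel-volume resampling
#' (trilinear interpolation of the binary mask, thresholded at 0.5), which
#' erodes high-curvature structures a little on every pass - the mechanism
#' that makes small structures vanish under repeated interactive
#' repositioning. `interpolation = "nearest"` reproduces the label-preserving
#' placement path instead, whose volume changes are unbiased boundary
#' jitter.
#'
#' @param template An `aux_template`.
#' @param transforms List of `rigid_transform`s, applied in order (e.g. from
#'   [placement_jitter()]).
#' @param items Optional character vector selecting components / marker ROIs
#'   (default: all four components and all four marker ROIs).
#' @param interpolation `"threshold"` (trilinear + 0.5, partial-volume) or
#'   `"nearest"`.
#' @return data.frame with columns `component`, `volume_cc`,
#'   `retention_sequential`, `retention_composed`.
#' @export
cumulative_resample_report <- function(template, transforms, items = NULL,
                                       interpolation = c("threshold",
                                                         "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(transforms) >= 1)
  grid <- template$grid
  all_items <- c(lapply(template$components, function(cc) cc$roi),
                 stats::setNames(template$marker_rois,
                                 paste0("marker_roi_", 1:4)))
  if (is.null(items)) items <- names(all_items)
  stopifnot(all(items %in% names(all_items)))
  items <- all_items[items]
  composed <- Reduce(function(acc, t) rt_compose(t, acc), transforms,
                     rt_identity())
  resample1 <- function(roi, transform) {
    if (interpolation == "nearest")
      return(resample_roi(roi, transform, grid))
    vol <- rt_volume(array(as.double(roi$mask), dim = dim(roi$mask)),
                     roi$spacing, roi$origin, "DENSITY")
    res <- resample_volume(vol, transform, grid, "trilinear", fill = 0)
    rt_roi(res$values >= 0.5, res$spacing, res$origin, roi$name, roi$meta)
  }
  out <- lapply(names(items), function(nm) {
    r0 <- items[[nm]]
    v0 <- volume_cc(r0)
    rs <- r0
    for (t in transforms) rs <- resample1(rs, t)
    rc <- resample1(r0, composed)
    data.frame(component = nm, volume_cc = v0,
               retention_sequential = volume_cc(rs) / v0,
               retention_composed = volume_cc(rc) / v0)
  })
  do.call(rbind, out)
}
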