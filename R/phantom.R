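#' Phantom generator parameters
#'
#' Describes one synthetic "patient": an ellipsoidal head (outer soft-tissue
#' scalp layer, skull shell, interior brain) immobilized in a thermoplastic
#' mask shell and resting on the mask holder / tabletop stack defined by the
#' template specification. The phantom stands in for a planning CT acquired
#' in the treatment setup; the paired synthetic CT and pseudo-MR derived from
#' it emulate an MRI-only workflow (devices invisible, anatomy HU perturbed).
#'
#' @param head_semiaxes Ellipsoid semi-axes (x = lateral, y = AP,
#'   z = SI) in mm.
#' @param scalp_thickness_mm,skull_thickness_mm Soft-tissue and skull shell
#'   thicknesses (mm).
#' @param mask_thickness_mm,mask_density True molded mask shell thickness
#'   (mm) and density (g/cm^3).
#' @param spacing Isotropic grid spacing in mm (default 1.5, the planning-MR
#'   resolution emulated here).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param ast_spec Device template specification ([default_ast_spec()]);
#'   also defines the true device geometry and the marker positions.
#' @param perturbation Default [sct_perturbation()] used for the synthetic-CT
#'   arm.
#' @param lut HU LUT used to express device densities as HU.
#' @param hu,mr Tissue HU values and pseudo-MR intensities (arbitrary
#'   units; the scale is chosen so the markers fall inside the level/width =
#'   100/200 display band while air sits far below it).
#' @export
phantom_params <- function(head_semiaxes = c(70, 90, 80),
                           scalp_thickness_mm = 5,
                           skull_thickness_mm = 6,
                           mask_thickness_mm = 3,
                           mask_density = 1.2,
                           spacing = 1.5,
                           seed = 1,
                           ast_spec = default_ast_spec(),
                           perturbation = sct_perturbation(),
                           lut = default_hu_lut(),
                           hu = list(air = -1000, soft = 30, brain = 40,
                                     skull = 700),
                           mr = list(air = -200, soft = 400, brain = 380,
                                     bone = 60, marker = 150, noise_sd = 5)) {
  head_semiaxes <- as.numeric(head_semiaxes)
  stopifnot(length(head_semiaxes) == 3, all(head_semiaxes > 0),
            mask_thickness_mm >= 0, spacing > 0)
  pts <- as.matrix(ast_spec$markers$positions)
  if (nrow(pts) != 4) stop("exactly 4 marker positions required")
  spread <- max(dist(pts))
  if (spread <= 50) stop("marker spread must exceed 50 mm")
  if (points_collinear(pts)) stop("markers must not be collinear")
  structure(list(head_semiaxes = head_semiaxes,
                 scalp_thickness_mm = scalp_thickness_mm,
                 skull_thickness_mm = skull_thickness_mm,
                 mask_thickness_mm = mask_thickness_mm,
                 mask_density = mask_density,
                 spacing = spacing, seed = as.integer(seed),
                 ast_spec = ast_spec, perturbation = perturbation,
                 lut = lut, hu = hu, mr = mr),
            class = "phantom_params")
}

#' Synthetic-CT perturbation model
#'
#' Emulates deep-learning synthetic-CT error as a class-wise HU bias (soft
#' tissue, bone, air) plus Gaussian voxel noise and a Gaussian smoothing
#' kernel; air outside the external contour is left untouched. Magnitudes
#' are free parameters, not claims about any particular sCT algorithm.
#'
#' @param bias_soft_hu,bias_bone_hu,bias_air_hu Class-wise HU biases.
#' @param noise_sd_hu Gaussian noise standard deviation (HU), `>= 0`.
#' @param fwhm_mm Smoothing kernel FWHM (mm), `>= 0`.
#' @param seed Optional seed for the noise draw.
#' @export
sct_perturbation <- function(bias_soft_hu = 5, bias_bone_hu = -20,
                             bias_air_hu = 0, noise_sd_hu = 10,
                             fwhm_mm = 3, seed = NULL) {
  if (!is.finite(noise_sd_hu) || noise_sd_hu < 0)
    stop("noise sd must be >= 0")
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("FWHM must be >= 0")
  structure(list(bias_soft_hu = bias_soft_hu, bias_bone_hu = bias_bone_hu,
                 bias_air_hu = bias_air_hu, noise_sd_hu = noise_sd_hu,
                 fwhm_mm = fwhm_mm, seed = seed),
            class = "sct_perturbation")
}

#' @rdname sct_perturbation
#' @export
no_perturbation <- function() {
  sct_perturbation(0, 0, 0, 0, 0)
}

# derive the phantom grid so that head + mask + devices fit with margin
phantom_grid <- function(params) {
  sp <- params$spacing
  ax <- params$head_semiaxes
  m <- params$mask_thickness_mm + 9
  boxes <- do.call(rbind, lapply(params$ast_spec$components, function(cc) cc$box))
  # device margin generous enough that moderate template misplacements
  # (a few degrees / mm) keep every placed component inside the grid
  lo <- pmin(c(-ax[1] - m, -ax[2] - m, -ax[3] - m),
             apply(boxes[, c(1, 3, 5), drop = FALSE], 2, min) - 9)
  hi <- pmax(c(ax[1] + m, ax[2] + m, ax[3] + m),
             apply(boxes[, c(2, 4, 6), drop = FALSE], 2, max) + 9)
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  list(dim = dims, spacing = rep(sp, 3), origin = lo)
}

ellipsoid_mask <- function(grid, center, semiaxes) {
  grid <- as_grid(grid)
  x <- (grid_axis_coords(grid, 1) - center[1]) / semiaxes[1]
  y <- (grid_axis_coords(grid, 2) - center[2]) / semiaxes[2]
  z <- (grid_axis_coords(grid, 3) - center[3]) / semiaxes[3]
  m2 <- outer(x^2, y^2, "+")
  m <- array(FALSE, grid$dim)
  for (k in seq_along(z)) m[, , k] <- (m2 + z[k]^2) <= 1
  m
}

#' Generate one phantom case
#'
#' Builds the paired volumes of one synthetic patient:
#' \describe{
#'   \item{ct}{Reference CT (HU) with every device physically present: mask
#'     shell, holder, tabletop (HU from their densities through the LUT) and
#'     the four silicone markers.}
#'   \item{sct}{Synthetic CT: same anatomy with all devices absent and the
#'     configured HU perturbation applied.}
#'   \item{mr}{Pseudo-MR at the grid resolution in which only the head and
#'     the four markers are visible.}
#' }
#' plus ground-truth structures, true marker centroids and the isocenter
#' (head center). Deterministic given `params$seed`. The device ROIs are
#' voxelized by placing the device template at identity, so the reference CT
#' and an exactly-placed template describe identical device geometry.
#'
#' @param params A [phantom_params()].
#' @return An object of class `phantom_case`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  set.seed(params$seed)
  grid <- phantom_grid(params)
  ctr <- c(0, 0, 0)
  ax <- params$head_semiaxes

  glo <- grid$origin
  ghi <- grid$origin + (grid$dim - 1) * grid$spacing
  if (any(ctr - ax - params$mask_thickness_mm < glo[1:3]) ||
      any(ctr + ax + params$mask_thickness_mm > ghi[1:3]))
    stop("grid too small to contain head and devices")

  ext_m <- ellipsoid_mask(grid, ctr, ax)
  skull_out <- ellipsoid_mask(grid, ctr, ax - params$scalp_thickness_mm)
  skull_in <- ellipsoid_mask(grid, ctr,
                             ax - params$scalp_thickness_mm -
                               params$skull_thickness_mm)
  external <- rt_roi(ext_m, grid$spacing, grid$origin, "external")
  skull <- rt_roi(skull_out & !skull_in, grid$spacing, grid$origin, "skull")
  brain <- rt_roi(skull_in, grid$spacing, grid$origin, "brain")

  true_mask <- roi_algebra(expand_roi(external, params$mask_thickness_mm),
                           external, "difference", name = "true_mask")
  true_mask$meta <- list(thickness_mm = params$mask_thickness_mm,
                         density = params$mask_density)

  template <- define_template(params$ast_spec)
  placed <- place_template(template, rt_identity(), grid)

  mk <- params$ast_spec$markers
  # canonical (z, y, x) order, matching detect_markers and the template
  mk$positions <- mk$positions[order(mk$positions[, 3], mk$positions[, 2],
                                     mk$positions[, 1]), , drop = FALSE]
  marker_rois <- lapply(seq_len(4), function(i) {
    voxelize_cylinder_y(grid, mk$positions[i, ], mk$marker_diameter %||% 3,
                        mk$marker_height %||% 5,
                        name = sprintf("marker_%d", i))
  })

  hu <- params$hu
  lut <- params$lut
  anat <- array(hu$air, grid$dim)
  anat[ext_m] <- hu$soft
  anat[skull$mask] <- hu$skull
  anat[brain$mask] <- hu$brain
  ct_anatomy <- rt_volume(anat, grid$spacing, grid$origin, "HU")

  ct_vals <- anat
  dev_order <- c("table_low", "table_high", "holder_low", "holder_high")
  for (nm in dev_order) {
    dens <- template$components[[nm]]$density
    ct_vals[placed$rois[[nm]]$mask] <- density_to_hu(lut, dens)
  }
  ct_vals[true_mask$mask] <- density_to_hu(lut, params$mask_density)
  for (r in marker_rois)
    ct_vals[r$mask] <- density_to_hu(lut, mk$marker_density %||% 1.05)
  ct <- rt_volume(ct_vals, grid$spacing, grid$origin, "HU")

  classes <- list(soft = ext_m & !skull$mask, bone = skull$mask,
                  air = !ext_m)
  pert <- params$perturbation
  if (is.null(pert$seed)) pert$seed <- derive_seed(params$seed, 77L)
  sct <- degrade_to_sct(ct_anatomy, pert, classes)

  mrp <- params$mr
  mr_vals <- array(mrp$air, grid$dim)
  mr_vals[ext_m] <- mrp$soft
  mr_vals[skull$mask] <- mrp$bone
  mr_vals[brain$mask] <- mrp$brain
  for (r in marker_rois) mr_vals[r$mask] <- mrp$marker
  if (mrp$noise_sd > 0)
    mr_vals <- mr_vals + array(rnorm(length(mr_vals), 0, mrp$noise_sd),
                               grid$dim)
  mr <- rt_volume(mr_vals, grid$spacing, grid$origin, "MR")

  structures <- c(list(external = external, brain = brain, skull = skull,
                       true_mask = true_mask),
                  placed$rois)
  structures$markers <- marker_rois

  structure(list(ct = ct, sct = sct, mr = mr, ct_anatomy = ct_anatomy,
                 structures = structures,
                 true_marker_centroids = t(vapply(marker_rois, roi_centroid,
                                                  numeric(3))),
                 isocenter = ctr, template = template, params = params),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- vol_dim(x$ct)
  cat(sprintf("<phantom_case seed %d> grid %dx%dx%d at %g mm\n",
              x$params$seed, d[1], d[2], d[3], x$params$spacing))
  cat(sprintf("  head semi-axes (%s) mm, mask d=%g mm rho=%g g/cm^3\n",
              paste(format(x$params$head_semiaxes), collapse = ", "),
              x$params$mask_thickness_mm, x$params$mask_density))
  invisible(x)
}

#' Degrade an anatomy-only CT into a synthetic CT
#'
#' Applies the class-wise HU bias, adds Gaussian noise, smooths with the
#' configured kernel, then restores the air voxels outside the external
#' contour so the background stays clean. With zero bias, zero noise and
#' zero FWHM the output equals the input exactly.
#'
#' @param ct An `rt_volume` of kind `"HU"` without devices.
#' @param pert An [sct_perturbation()].
#' @param classes List of logical arrays `soft`, `bone`, `air` on the CT
#'   grid.
#' @return An `rt_volume` of kind `"HU"`.
#' @export
degrade_to_sct <- function(ct, pert, classes) {
  stopifnot(ct$kind == "HU")
  if (pert$noise_sd_hu < 0) stop("noise sd must be >= 0")
  v <- ct$values
  v[classes$soft] <- v[classes$soft] + pert$bias_soft_hu
  v[classes$bone] <- v[classes$bone] + pert$bias_bone_hu
  v[classes$air] <- v[classes$air] + pert$bias_air_hu
  if (pert$noise_sd_hu > 0) {
    if (!is.null(pert$seed)) set.seed(pert$seed)
    v <- v + array(rnorm(length(v), 0, pert$noise_sd_hu), dim(v))
  }
  if (pert$fwhm_mm > 0)
    v <- gaussian_smooth3(v, pert$fwhm_mm, ct$spacing)
  v[classes$air] <- ct$values[classes$air]
  rt_volume(v, ct$spacing, ct$origin, "HU")
}

#' Place the sixteen artificial PTVs
#'
#' Sixteen spheres of diameter 2 cm, four per opposing-beam axis (90-270,
#' 0-180, 45-225, 135-315 degrees), centered on the axis through the
#' isocenter in the isocenter's axial plane at fractions (-0.6, -0.2, +0.2,
#' +0.6) of the brain extent along that axis. Every sphere must lie fully
#' inside the brain.
#'
#' @param case A `phantom_case`.
#' @param fractions Signed fractions of the brain extent along each axis.
#' @param diameter_mm PTV diameter (mm).
#' @return List with `rois` (named list of 16 `rt_roi`) and `table`
#'   (data.frame mapping each PTV to its axis, angles and fraction).
#' @export
place_artificial_ptvs <- function(case, fractions = c(-0.6, -0.2, 0.2, 0.6),
                                  diameter_mm = 20) {
  brain <- case$structures$brain
  if (!any(brain$mask)) stop("brain ROI is empty")
  iso <- case$isocenter
  pairs <- opposing_pairs()
  grid <- vol_grid(brain)
  bm <- array(as.double(brain$mask), dim(brain$mask))

  inside <- function(p) {
    cpp_sample_nearest(bm, dim(brain$mask), brain$spacing, brain$origin,
                       matrix(p, 1), 0) > 0.5
  }
  axis_extent <- function(dir) {
    step <- 0.5
    tp <- 0
    while (inside(iso + (tp + step) * dir)) tp <- tp + step
    tm <- 0
    while (inside(iso - (tm + step) * dir)) tm <- tm + step
    c(plus = tp, minus = tm)
  }

  rois <- list()
  rows <- list()
  for (pname in names(pairs)) {
    ang <- pairs[[pname]]
    dir <- beam_source_direction(ang[1])
    ext <- axis_extent(dir)
    for (f in fractions) {
      t <- if (f >= 0) f * ext["plus"] else f * ext["minus"]
      center <- iso + as.numeric(t) * dir
      nm <- sprintf("ptv_%s_%+.1f", pname, f)
      sph <- voxelize_sphere(grid, center, diameter_mm, name = nm)
      if (any(sph$mask & !brain$mask))
        stop("PTV sphere '", nm, "' is not fully inside the brain; ",
             "use a larger head or smaller fractions")
      sph$meta$axis <- pname
      sph$meta$fraction <- f
      rois[[nm]] <- sph
      rows[[length(rows) + 1]] <-
        data.frame(ptv = nm, pair = pname, angle_lo = ang[1],
                   angle_hi = ang[2], fraction = f,
                   cx = center[1], cy = center[2], cz = center[3])
    }
  }
  list(rois = rois, table = do.call(rbind, rows))
}

#' Opposing static-field pairs
#'
#' The four opposing-beam axes used in the static-field test: SF1 = (90, 270),
#' SF2 = (0, 180), SF3 = (225, 45), SF4 = (135, 315) degrees.
#' @export
opposing_pairs <- function() {
  list(sf1 = c(90, 270), sf2 = c(0, 180), sf3 = c(225, 45),
       sf4 = c(135, 315))
}
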