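#' Static rectangular photon field
#'
#' One parallel (non-divergent) rectangular field. Gantry convention: the
#' beam rotates in the axial plane about the superior axis; 0 degrees means
#' the source is anterior of the patient, 90 degrees patient-left, 180
#' posterior (through the tabletop), 270 patient-right. The field is `w x h`
#' cm at the isocenter, `w` lateral in the axial plane and `h` along the
#' superior axis, with a hard aperture edge (no penumbra).
#'
#' @param angle_deg Gantry angle in `[0, 360)`.
#' @param field_cm Field size `c(w, h)` in cm.
#' @param mu Monitor units (> 0).
#' @param isocenter Isocenter (mm).
#' @export
beam_spec <- function(angle_deg, field_cm = c(5, 5), mu = 1000,
                      isocenter = c(0, 0, 0)) {
  stopifnot(is.finite(angle_deg), angle_deg >= 0, angle_deg < 360,
            length(field_cm) %in% c(1, 2), all(field_cm > 0), mu > 0)
  if (length(field_cm) == 1) field_cm <- rep(field_cm, 2)
  structure(list(angle_deg = angle_deg, field_cm = as.numeric(field_cm),
                 mu = mu, isocenter = as.numeric(isocenter)),
            class = "beam_spec")
}

# unit vector from isocenter toward the source, axial plane; components are
# snapped so cardinal angles are exact (sin(pi) etc. leave 1e-16 residues
# that would break the symmetry of opposing beams)
beam_source_direction <- function(angle_deg) {
  a <- angle_deg * pi / 180
  v <- c(sin(a), cos(a), 0)
  v[abs(v) < 1e-12] <- 0
  v[abs(v - 1) < 1e-12] <- 1
  v[abs(v + 1) < 1e-12] <- -1
  v / sqrt(sum(v^2))
}

# orthonormal beam frame: w = propagation direction, u = lateral (field
# width), v = superior (field height)
beam_frame <- function(beam) {
  w <- -beam_source_direction(beam$angle_deg)
  v <- c(0, 0, 1)
  u <- c(-w[2], w[1], 0)   # v x w, so that (u, v, w) is right-handed
  list(u = u, v = v, w = w)
}

#' Percent-depth-dose model parameters
#'
#' Build-up times exponential attenuation:
#' `pdd(d) = N (1 - exp(-beta d)) exp(-mu d)`, normalized so the maximum over
#' depth is 1. `beta > mu` is required (otherwise there is no build-up
#' peak). Defaults give a 6-MV-like curve with d_max around 15 mm. The
#' engine's constants are internal conventions used for contrasts between
#' matched calculations, not claims about any clinical beam.
#'
#' @param mu Effective attenuation coefficient (1/mm).
#' @param beta Build-up rate (1/mm).
#' @param k_cal Calibration, Gy per MU at d_max.
#' @export
pdd_params <- function(mu = 0.005, beta = 0.25, k_cal = 0.01) {
  stopifnot(mu > 0, k_cal > 0)
  if (beta <= mu) stop("beta must exceed mu (no build-up peak otherwise)")
  structure(list(mu = mu, beta = beta, k_cal = k_cal), class = "pdd_params")
}

#' Percent depth dose at water-equivalent depth
#'
#' @param depth_mm Radiological depth(s) in mm, `>= 0`.
#' @param p A [pdd_params()].
#' @return Fraction of the d_max dose (0 at the surface, 1 at d_max).
#' @export
pdd <- function(depth_mm, p = pdd_params()) {
  if (any(depth_mm < 0, na.rm = TRUE)) stop("depth must be >= 0")
  dmax <- pdd_dmax(p)
  fmax <- (1 - exp(-p$beta * dmax)) * exp(-p$mu * dmax)
  (1 - exp(-p$beta * depth_mm)) * exp(-p$mu * depth_mm) / fmax
}

#' Depth of maximum dose of the depth-dose model
#' @param p A [pdd_params()].
#' @export
pdd_dmax <- function(p = pdd_params()) {
  log(p$beta / p$mu + 1) / p$beta
}

#' Radiological (water-equivalent) depth along a ray
#'
#' Line integral of relative mass density from `entry_point` to `point`
#' using exact Siddon voxel traversal; in a uniform unit-density volume this
#' equals the geometric distance. Space outside the grid contributes zero.
#'
#' @param density An `rt_volume` of kind `"DENSITY"`.
#' @param entry_point Ray start (mm).
#' @param direction Beam direction (need not be normalized).
#' @param point Evaluation point; must be downstream of `entry_point`.
#' @return Water-equivalent depth in mm.
#' @export
radiological_depth <- function(density, entry_point, direction, point) {
  direction <- direction / sqrt(sum(direction^2))
  if (sum((point - entry_point) * direction) < 0)
    stop("point is upstream of the entry point")
  as.numeric(cpp_ray_integral(density$values, vol_dim(density),
                              density$spacing, density$origin,
                              matrix(entry_point, 1), matrix(point, 1)))
}

#' Beam entrance point on the central axis
#'
#' First crossing of the central axis into `{density > threshold}`, scanning
#' from the source side; with a mask present the crossing lies on the mask's
#' outer surface. The crossing is refined by linear interpolation between
#' samples.
#'
#' @param density An `rt_volume` of kind `"DENSITY"`.
#' @param beam A [beam_spec()].
#' @param threshold Relative density threshold (default 0.2).
#' @param step_mm Scan step along the axis.
#' @return Entrance point (mm).
#' @export
beam_entrance_point <- function(density, beam, threshold = 0.2,
                                step_mm = 0.1) {
  fr <- beam_frame(beam)
  g <- vol_grid(density)
  corners <- as.matrix(expand.grid(
    g$origin[1] + c(0, (g$dim[1] - 1)) * g$spacing[1],
    g$origin[2] + c(0, (g$dim[2] - 1)) * g$spacing[2],
    g$origin[3] + c(0, (g$dim[3] - 1)) * g$spacing[3]))
  cw <- as.numeric(sweep(corners, 2, beam$isocenter) %*% fr$w)
  cs <- seq(min(cw) - 1, max(cw) + 1, by = step_mm)
  pts <- cbind(beam$isocenter[1] + cs * fr$w[1],
               beam$isocenter[2] + cs * fr$w[2],
               beam$isocenter[3] + cs * fr$w[3])
  rho <- cpp_sample_trilinear(density$values, g$dim, g$spacing, g$origin,
                              pts, 0)
  i <- match(TRUE, rho > threshold)
  if (is.na(i)) stop("central axis does not cross the density threshold")
  if (i == 1) return(pts[1, ])
  f <- (threshold - rho[i - 1]) / (rho[i] - rho[i - 1])
  c0 <- cs[i - 1] + f * step_mm
  beam$isocenter + c0 * fr$w
}

#' Compute the dose of one static field
#'
#' Parallel-beam dose: the density volume is sampled on a beam-aligned grid,
#' each ray's entrance into `{density > entry_threshold}` is located, the
#' radiological depth beyond the entrance is accumulated (trapezoidal Siddon
#' approximation at sub-voxel steps along the ray), and the depth-dose model
#' gives `D = MU * k_cal * pdd(depth)` inside the rectangular aperture and
#' zero outside. The result is resampled onto the density grid. The
#' computation is deterministic.
#'
#' @param density An `rt_volume` of kind `"DENSITY"`.
#' @param beam A [beam_spec()].
#' @param p A [pdd_params()].
#' @param entry_threshold Relative density defining the entrance surface.
#' @param step_mm Sampling step along the beam; default a quarter of the
#'   smallest grid spacing.
#' @return An `rt_volume` of kind `"DOSE"` (Gy) on the density grid.
#' @export
compute_dose <- function(density, beam, p = pdd_params(),
                         entry_threshold = 0.2, step_mm = NULL) {
  stopifnot(density$kind == "DENSITY")
  g <- vol_grid(density)
  glo <- g$origin
  ghi <- g$origin + (g$dim - 1) * g$spacing
  iso <- beam$isocenter
  if (any(iso < glo) || any(iso > ghi))
    stop("isocenter outside the density grid")
  fr <- beam_frame(beam)
  if (is.null(step_mm)) step_mm <- min(g$spacing) / 4

  halfw <- beam$field_cm[1] * 10 / 2
  halfh <- beam$field_cm[2] * 10 / 2
  da <- min(g$spacing)

  corners <- as.matrix(expand.grid(glo[1] + c(0, ghi[1] - glo[1]),
                                   glo[2] + c(0, ghi[2] - glo[2]),
                                   glo[3] + c(0, ghi[3] - glo[3])))
  cw <- as.numeric(sweep(corners, 2, iso) %*% fr$w)
  cvals <- seq(min(cw) - 2 * step_mm, max(cw) + 2 * step_mm, by = step_mm)
  avals <- seq(-(halfw + 2 * da), halfw + 2 * da, by = da)
  bvals <- seq(-(halfh + 2 * da), halfh + 2 * da, by = da)
  nc <- length(cvals); na <- length(avals); nb <- length(bvals)

  # beam-grid sample positions, (c, a, b) order with c fastest
  nray <- na * nb
  pts <- matrix(0, nc * nray, 3)
  for (ax in 1:3) {
    pts[, ax] <- iso[ax] + rep(cvals * fr$w[ax], times = nray) +
      rep(rep(avals * fr$u[ax], each = nc), times = nb) +
      rep(bvals * fr$v[ax], each = nc * na)
  }
  rho <- cpp_sample_trilinear(density$values, g$dim, g$spacing, g$origin,
                              pts, 0)
  rm(pts)
  rho <- matrix(rho, nrow = nc)   # rays in columns

  above <- rho > entry_threshold
  if (!any(above)) stop("beam misses the density volume entirely")
  entry <- apply(above, 2, function(z) match(TRUE, z))
  hit <- which(!is.na(entry) & entry > 1)

  # column-wise cumulative sums without apply/aperm copies
  cumv <- cumsum(as.numeric(rho))
  S <- matrix(cumv, nc, nray)
  if (nray > 1)
    S <- S - rep(c(0, cumv[nc * seq_len(nray - 1)]), each = nc)

  dosegrid <- matrix(0, nc, nray)
  if (length(hit)) {
    e <- entry[hit]
    Se <- S[cbind(e, hit)]
    rhoe <- rho[cbind(e, hit)]
    rho0 <- rho[cbind(e - 1L, hit)]
    frac <- (entry_threshold - rho0) / pmax(rhoe - rho0, 1e-12)
    frac <- pmin(pmax(frac, 0), 1)
    # trapezoidal integral from sample e to sample i, plus the partial
    # segment from the interpolated entrance to sample e
    partial <- (1 - frac) * step_mm * (entry_threshold + rhoe) / 2
    nh <- length(hit)
    Dh <- step_mm * (S[, hit, drop = FALSE] - rep(Se, each = nc) +
                       (rep(rhoe, each = nc) -
                          rho[, hit, drop = FALSE]) / 2) +
      rep(partial, each = nc)
    mask_down <- matrix(seq_len(nc), nc, nh) >= rep(e, each = nc)
    Dh[!mask_down | Dh < 0] <- 0
    dosegrid[, hit] <- beam$mu * p$k_cal * pdd(Dh, p) * mask_down
  }
  dosegrid <- array(dosegrid, c(nc, na, nb))

  # map patient voxels into the beam frame; inside the aperture only
  xc <- grid_axis_coords(g, 1) - iso[1]
  yc <- grid_axis_coords(g, 2) - iso[2]
  zc <- grid_axis_coords(g, 3) - iso[3]
  frame_coord <- function(v) {
    rep(v[1] * xc, times = g$dim[2] * g$dim[3]) +
      rep(rep(v[2] * yc, each = g$dim[1]), times = g$dim[3]) +
      rep(v[3] * zc, each = g$dim[1] * g$dim[2])
  }
  aa <- frame_coord(fr$u)
  bb <- frame_coord(fr$v)
  inside <- abs(aa) <= halfw + 1e-9 & abs(bb) <= halfh + 1e-9
  dose <- numeric(length(aa))
  if (any(inside)) {
    cc <- frame_coord(fr$w)[inside]
    bpts <- cbind(cc, aa[inside], bb[inside])
    dose[inside] <- cpp_sample_trilinear(
      dosegrid, c(nc, na, nb), c(step_mm, da, da),
      c(cvals[1], avals[1], bvals[1]), bpts, 0)
  }
  rt_volume(array(dose, g$dim), g$spacing, g$origin, "DOSE")
}

#' Sum the dose of several static fields
#'
#' @param density An `rt_volume` of kind `"DENSITY"`.
#' @param beams List of [beam_spec()]s.
#' @param p A [pdd_params()].
#' @param ... Passed to [compute_dose()].
#' @return An `rt_volume` of kind `"DOSE"`.
#' @export
compute_plan_dose <- function(density, beams, p = pdd_params(), ...) {
  doses <- lapply(beams, function(b) compute_dose(density, b, p, ...))
  out <- doses[[1]]
  if (length(doses) > 1)
    for (i in 2:length(doses)) out$values <- out$values + doses[[i]]$values
  out
}
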