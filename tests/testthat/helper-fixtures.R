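# Compact device template + head so unit-test phantoms stay small; the
# acceptance tests use the full default geometry.
small_ast_spec <- function() {
  s <- default_ast_spec()
  s$components$holder_high$box <- c(-60, 60, -116, -104, -70, 30)
  s$components$holder_low$box  <- c(-60, 60, -128, -116, -70, 30)
  s$components$table_high$box  <- c(-60, 60, -132, -128, -72, 40)
  s$components$table_low$box   <- c(-60, 60, -162, -132, -72, 40)
  s$markers$positions <- rbind(c(-50, -110, -60), c(50, -110, -60),
                               c(-50, -110, 20), c(50, -113, 20))
  s
}

small_phantom_params <- function(seed = 1, ...) {
  phantom_params(head_semiaxes = c(55, 70, 60), seed = seed,
                 ast_spec = small_ast_spec(), ...)
}

# centered uniform water cube (n^3 voxels)
water_cube <- function(n = 81, spacing = 1.5, density = 1) {
  half <- (n - 1) / 2 * spacing
  rt_volume(array(density, c(n, n, n)), spacing, rep(-half, 3), "DENSITY")
}

centered_grid <- function(n, spacing) {
  half <- (n - 1) / 2 * spacing
  list(dim = rep(as.integer(n), 3), spacing = rep(spacing, 3),
       origin = rep(-half, 3))
}

sphere_roi <- function(n = 76, spacing = 1.5, radius = 50,
                       center = c(0, 0, 0)) {
  auxdose:::voxelize_sphere(centered_grid(n, spacing), center, 2 * radius,
                            name = sprintf("sphere_r%g", radius))
}

# uniformly random proper rotation (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotation_about_axis <- function(axis, angle_deg) {
  ax <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# dense midpoint-sampling oracle for the Siddon line integral; the step must
# be much finer than a voxel so boundary-crossing misassignment stays far
# below the comparison tolerance
dense_ray_integral <- function(vol, p0, p1, step = min(vol$spacing) / 2000) {
  L <- sqrt(sum((p1 - p0)^2))
  n <- max(2, ceiling(L / step))
  t <- (seq_len(n) - 0.5) / n
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]),
               p0[2] + t * (p1[2] - p0[2]),
               p0[3] + t * (p1[3] - p0[3]))
  vals <- auxdose:::cpp_sample_nearest(vol$values, dim(vol$values),
                                       vol$spacing, vol$origin, pts, 0)
  sum(vals) * L / n
}
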