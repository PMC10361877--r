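test_that("template definition voxelizes components and validates markers", {
  tpl <- define_template()
  expect_length(tpl$marker_rois, 4)
  expect_equal(vapply(tpl$components, function(c) c$density, numeric(1)),
               c(holder_high = 1.2, holder_low = 1.0, table_high = 1.7,
                 table_low = 0.11))
  for (r in tpl$marker_rois) {
    expect_equal(r$meta$nominal_diameter_mm, 5)
    nominal <- 4 / 3 * pi * 2.5^3 / 1000
    expect_lt(abs(volume_cc(r) - nominal) / nominal, 0.35)
  }
  # components disjoint; markers inside the holder board
  comp <- lapply(tpl$components, function(c) c$roi$mask)
  for (i in seq_along(comp)) for (j in seq_len(i - 1))
    expect_false(any(comp[[i]] & comp[[j]]))
  for (r in tpl$marker_rois)
    expect_true(all(comp$holder_high[r$mask] | comp$holder_low[r$mask]))

  bad <- default_ast_spec()
  bad$markers$positions <- bad$markers$positions[1:3, ]
  expect_error(define_template(bad), "4 markers")
  col <- default_ast_spec()
  col$markers$positions <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(define_template(col), "collinear")
})

test_that("template specification survives a JSON round trip", {
  f <- tempfile(fileext = ".json")
  write_ast_spec(default_ast_spec(), f)
  tpl1 <- define_template(default_ast_spec())
  tpl2 <- define_template(f)
  expect_equal(tpl2$marker_points, tpl1$marker_points, tolerance = 1e-12)
  expect_equal(vapply(tpl2$components, function(c) c$density, numeric(1)),
               vapply(tpl1$components, function(c) c$density, numeric(1)))
})

test_that("marker detection finds exactly four cylinders or reports counts", {
  case <- generate_phantom(small_phantom_params(seed = 31))
  det <- detect_markers(case$mr, external = case$structures$external)
  expect_equal(dim(det), c(4, 3))
  expect_lt(max(sqrt(rowSums((det - case$true_marker_centroids)^2))), 1.5)
  # canonical ordering: non-decreasing z
  expect_true(all(diff(det[, 3]) >= 0))

  empty <- rt_volume(array(-200, c(20, 20, 20)), 1.5, c(0, 0, 0), "MR")
  expect_error(detect_markers(empty), "0 candidates")

  mr3 <- case$mr
  mr3$values[case$structures$markers[[2]]$mask] <- -200
  expect_error(detect_markers(mr3, external = case$structures$external),
               "3 candidates")
})

test_that("rigid fit is exact on noise-free correspondences", {
  tpl <- define_template()
  p <- tpl$marker_points

  ident <- fit_rigid(p, p)
  expect_lt(attr(ident, "rms_mm"), 1e-9)
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)

  tr <- rigid_transform(rot_z(90), c(10, 0, 0))
  fit <- fit_rigid(p, rt_apply(tr, p))
  expect_lt(max(abs(rt_apply(fit, p) - rt_apply(tr, p))), 1e-9)

  set.seed(6)
  for (i in 1:500) {
    R <- random_rotation()
    tv <- rnorm(3, sd = 20)
    q <- rt_apply(rigid_transform(R, tv), p)
    fit <- fit_rigid(p, q)
    expect_lt(attr(fit, "rms_mm"), 1e-8)
    expect_lt(max(abs(fit$rotation - R)), 1e-8)
  }

  line <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(fit_rigid(line, line), "collinear")
})

test_that("placement voxelizes once, contains markers and conserves volume", {
  tpl <- define_template()
  same <- place_template(tpl, rt_identity(), tpl$grid)
  for (nm in names(tpl$components))
    expect_identical(same$rois[[nm]]$mask, tpl$components[[nm]]$roi$mask)

  case <- generate_phantom(small_phantom_params(seed = 32))
  det <- detect_markers(case$mr, external = case$structures$external)
  fit <- fit_rigid(case$template$marker_points, det)
  placed <- place_template(case$template, fit, vol_grid(case$ct),
                           detected_points = det)
  expect_true(all(placed$containment))

  rot <- rigid_transform(rot_z(1.5), c(0, 0, 0))
  placed_rot <- place_template(case$template, rot, vol_grid(case$ct))
  v0 <- volume_cc(case$template$components$table_high$roi)
  expect_lt(abs(volume_cc(placed_rot$rois$table_high) - v0) / v0, 0.05)

  far <- rigid_transform(diag(3), c(500, 0, 0))
  expect_error(place_template(case$template, far, vol_grid(case$ct)),
               "clipped")
})

test_that("one resampling step is identical in sequential and composed mode", {
  tpl <- define_template()
  tr <- placement_jitter(tpl, n = 1, rot_deg = 1, trans_mm = 1, seed = 3)
  rep1 <- cumulative_resample_report(tpl, tr,
                                     items = c("table_high", "marker_roi_1"))
  expect_equal(rep1$retention_sequential, rep1$retention_composed,
               tolerance = 1e-12)
})
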