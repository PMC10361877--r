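test_that("external extraction recovers the head and rejects bad inputs", {
  case <- generate_phantom(small_phantom_params(seed = 21))
  devices <- c(list(case$structures$true_mask, case$structures$holder_low,
                    case$structures$holder_high, case$structures$table_low,
                    case$structures$table_high), case$structures$markers)
  ext <- extract_external(case$ct, -400, exclude = devices)
  expect_identical(ext$mask, case$structures$external$mask)

  # devices absent: plain extraction on the synthetic CT matches too
  # (unperturbed anatomy here, so the contour is exact)
  case0 <- generate_phantom(small_phantom_params(
    seed = 21, perturbation = no_perturbation()))
  ext0 <- extract_external(case0$sct)
  expect_identical(ext0$mask, case0$structures$external$mask)

  air <- rt_volume(array(-1000, c(12, 12, 12)), 2, c(0, 0, 0), "HU")
  expect_error(extract_external(air), "no voxels")
  # threshold below air: everything above threshold, touches the boundary
  expect_error(extract_external(case$ct, -1001), "boundary")
})

test_that("mask shell is the expanded-minus-original contour", {
  s50 <- sphere_roi(radius = 50)
  shell <- build_mask_shell(s50, mask_spec(3, 1.2))
  analytic_cc <- 4 * pi / 3 * (53^3 - 50^3) / 1000
  # the center-to-center metric expansion carries a sub-voxel surface bias
  # (~0.4 mm effective radius), which on a 2-voxel-thick shell amounts to
  # some 15% of the shell volume
  expect_lt(abs(volume_cc(shell) - analytic_cc) / analytic_cc, 0.20)
  expect_false(any(shell$mask & s50$mask))
  expect_identical(shell$meta$density, 1.2)

  thin <- build_mask_shell(s50, mask_spec(2.5, 1.1))
  expect_lt(volume_cc(thin), volume_cc(shell))

  off <- build_mask_shell(s50, mask_spec(enabled = FALSE))
  expect_false(any(off$mask))
  expect_false(off$meta$enabled)
})

test_that("density composition applies LUT then prioritized overrides", {
  lut <- default_hu_lut()
  set.seed(5)
  hu <- array(runif(16^3, -1000, 1500), c(16, 16, 16))
  vol <- rt_volume(hu, 2, c(0, 0, 0), "HU")

  plain <- compose_density_map(vol, lut)
  expect_equal(plain$values, hu_to_density(lut, hu), tolerance = 1e-12)
  expect_identical(plain$kind, "DENSITY")

  m1 <- array(FALSE, c(16, 16, 16)); m1[1:8, , ] <- TRUE
  m2 <- array(FALSE, c(16, 16, 16)); m2[5:12, , ] <- TRUE
  r1 <- roi_from_volume(vol, m1, "table_low")
  r2 <- roi_from_volume(vol, m2, "holder_high")
  o1 <- density_override(r1, 0.11, 1L)
  o2 <- density_override(r2, 1.2, 2L)

  out <- compose_density_map(vol, lut, list(o1, o2))
  expect_true(all(out$values[m2] == 1.2))               # higher priority wins
  expect_true(all(out$values[m1 & !m2] == 0.11))

  twice <- compose_density_map(vol, lut, list(o1, o2, o2))
  expect_identical(twice$values, out$values)             # idempotent

  conflict <- density_override(r2, 0.5, 1L)
  expect_error(compose_density_map(vol, lut, list(o1, conflict)),
               "equal priority")

  scaled <- compose_density_map(vol, lut, list(o2), anatomy_scale = 0.98)
  expect_equal(scaled$values[!m2], 0.98 * plain$values[!m2],
               tolerance = 1e-12)
  expect_true(all(scaled$values[m2] == 1.2))             # overrides unscaled
})

test_that("device density overrides reproduce the template densities", {
  case <- generate_phantom(small_phantom_params(seed = 22))
  placed <- place_template(case$template, rt_identity(), vol_grid(case$sct))
  dens <- compose_density_map(case$sct, default_hu_lut(),
                              unname(placed$overrides))
  expect_equal(mean(dens$values[placed$rois$table_low$mask]), 0.11)
  expect_equal(mean(dens$values[placed$rois$table_high$mask]), 1.7)
  expect_equal(mean(dens$values[placed$rois$holder_low$mask]), 1.0)
  expect_equal(mean(dens$values[placed$rois$holder_high$mask]), 1.2)
})
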