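test_that("NIfTI round trip preserves values, grid geometry and kind", {
  set.seed(1)
  vals <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  vol <- rt_volume(vals, c(1.5, 2, 2.5), c(-10, -20, -30), "DOSE")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$values, vol$values, tolerance = 1e-12)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)
  expect_identical(back$kind, "DOSE")

  const <- rt_volume(array(7, c(8, 8, 8)), 1.5, c(0, 0, 0), "HU")
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(const, f2)
  expect_equal(read_volume(f2)$values, const$values, tolerance = 1e-12)
})

test_that("non-3D images and invalid volumes are rejected", {
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
  expect_error(read_volume(f), "3D")

  expect_error(rt_volume(matrix(0, 4, 4), 1), "3D")
  expect_error(rt_volume(array(0, c(4, 4, 4)), c(1, -1, 1)), "spacing")
  expect_error(rt_volume(array(NA_real_, c(4, 4, 4)), 1), "finite")
})

test_that("rigid transforms compose, invert and validate", {
  set.seed(2)
  for (i in 1:20) {
    tr <- rigid_transform(random_rotation(), rnorm(3, sd = 10))
    comp <- rt_compose(tr, rt_invert(tr))
    expect_lt(max(abs(comp$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(comp$translation)), 1e-9)
    pts <- matrix(rnorm(30, sd = 50), 10, 3)
    expect_equal(rt_apply(rt_invert(tr), rt_apply(tr, pts)), pts,
                 tolerance = 1e-9)
  }
  expect_error(rigid_transform(matrix(rnorm(9), 3), c(0, 0, 0)),
               "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl, c(0, 0, 0)), "proper")
})

test_that("resampling: identity is exact, integer shifts relabel voxels", {
  set.seed(3)
  vol <- rt_volume(array(rnorm(24^3), c(24, 24, 24)), 2, c(-23, -23, -23),
                   "MR")
  same <- resample_volume(vol, rt_identity(), vol, "nearest")
  expect_equal(same$values, vol$values, tolerance = 0)

  shift <- rigid_transform(diag(3), c(2, 0, 0))  # exactly one voxel in x
  out <- resample_volume(vol, shift, vol, "nearest")
  expect_equal(out$values[2:24, , ], vol$values[1:23, , ], tolerance = 0)
  expect_true(all(out$values[1, , ] == 0))

  expect_error(resample_volume(vol, rt_identity(), vol, "cubic"),
               "interpolation")
})

test_that("two-pass interpolation loses information a composed pass keeps", {
  # structured volume: smooth but non-constant
  n <- 32
  co <- seq(-1, 1, length.out = n)
  vals <- array(0, c(n, n, n))
  for (k in 1:n) vals[, , k] <- outer(sin(3 * co), cos(2 * co)) + co[k]
  vol <- rt_volume(vals, 2, rep(-(n - 1), 3), "MR")

  r10 <- rigid_transform(rot_z(10), c(0, 0, 0))
  rm10 <- rigid_transform(rot_z(-10), c(0, 0, 0))
  two_pass <- resample_volume(resample_volume(vol, r10, vol), rm10, vol)
  composed <- resample_volume(vol, rt_compose(rm10, r10), vol)

  core <- 9:24  # interior, unaffected by border fill
  expect_equal(composed$values[core, core, core],
               vol$values[core, core, core], tolerance = 1e-9)
  expect_gt(max(abs(two_pass$values[core, core, core] -
                      vol$values[core, core, core])), 1e-3)
})
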