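test_that("depth-dose model: build-up peak location and shape", {
  p <- pdd_params()
  expect_equal(pdd(0, p), 0)
  expect_equal(max(pdd(seq(0, 300, by = 0.01), p)), 1, tolerance = 1e-6)

  # bisection oracle on the derivative of (1 - e^{-bd}) e^{-md}
  dfun <- function(d) p$beta * exp(-p$beta * d) -
    p$mu * (1 - exp(-p$beta * d))
  root <- uniroot(dfun, c(0.1, 100), tol = 1e-10)$root
  expect_lt(abs(pdd_dmax(p) - root), 1e-6)
  grid_argmax <- seq(0, 60, by = 0.01)[which.max(pdd(seq(0, 60, by = 0.01), p))]
  expect_lt(abs(grid_argmax - root), 0.5)

  dmax <- pdd_dmax(p)
  expect_lt(pdd(dmax + 50, p), pdd(dmax + 10, p))
  expect_error(pdd_params(mu = 0.3, beta = 0.25), "beta")
  expect_error(pdd(-1, p), ">= 0")
})

test_that("radiological depth: exact traversal on closed-form cases", {
  wat <- water_cube(n = 41, spacing = 2)
  set.seed(7)
  for (i in 1:20) {
    p0 <- runif(3, -35, 35)
    p1 <- runif(3, -35, 35)
    expect_equal(radiological_depth(wat, p0, p1 - p0, p1),
                 sqrt(sum((p1 - p0)^2)), tolerance = 1e-6)
  }

  # two slabs along y: 30 mm of 1.0 then 20 mm of 0.5
  vals <- array(0, c(21, 50, 21))
  vals[, 1:30, ] <- 1
  vals[, 31:50, ] <- 0.5
  slab <- rt_volume(vals, 1, c(-10, 0.5, -10), "DENSITY")
  expect_equal(radiological_depth(slab, c(0, 0, 0), c(0, 1, 0), c(0, 50, 0)),
               30 * 1 + 20 * 0.5, tolerance = 1e-9)

  expect_error(radiological_depth(wat, c(0, 0, 0), c(0, 1, 0), c(0, -5, 0)),
               "upstream")
})

test_that("Siddon integral matches a dense-sampling oracle on random grids", {
  set.seed(8)
  for (g in 1:3) {
    vol <- rt_volume(array(runif(16^3, 0.1, 2), c(16, 16, 16)), 1.5,
                     c(-11.25, -11.25, -11.25), "DENSITY")
    for (r in 1:5) {
      p0 <- runif(3, -10, 10); p1 <- runif(3, -10, 10)
      if (sqrt(sum((p1 - p0)^2)) < 5) next
      sid <- radiological_depth(vol, p0, p1 - p0, p1)
      ora <- dense_ray_integral(vol, p0, p1)
      expect_lt(abs(sid - ora) / ora, 0.001)
    }
  }
})

test_that("dose: closed-form water depth dose, linearity, determinism", {
  wat <- water_cube(n = 101, spacing = 1.5)
  p <- pdd_params()
  beam <- beam_spec(0, c(5, 5), 1000, c(0, 0, 0))
  dose <- compute_dose(wat, beam, p)
  surface <- 75  # voxel-center hull edge, y = +75 mm
  yc <- seq(-75, 75, by = 1.5)
  for (depth in seq(12, 120, by = 12)) {
    iy <- which.min(abs((surface - yc) - depth))
    d_here <- surface - yc[iy]
    engine <- dose$values[51, iy, 51]
    expect_lt(abs(engine - 1000 * p$k_cal * pdd(d_here, p)) /
                (1000 * p$k_cal * pdd(d_here, p)), 0.01)
  }

  # hard aperture edge: zero outside the 5 x 5 cm field
  xc <- seq(-75, 75, by = 1.5)
  outside <- abs(xc) > 25 + 1e-9
  expect_true(all(dose$values[outside, , ] == 0))
  expect_gt(min(dose$values[abs(xc) < 24, yc < 60, abs(xc) < 24]), 0)

  double <- compute_dose(wat, beam_spec(0, c(5, 5), 2000, c(0, 0, 0)), p)
  expect_equal(double$values, 2 * dose$values, tolerance = 1e-12)

  again <- compute_dose(wat, beam, p)
  expect_identical(again$values, dose$values)

  air <- rt_volume(array(0, c(21, 21, 21)), 2, c(-20, -20, -20), "DENSITY")
  expect_error(compute_dose(air, beam_spec(0, c(5, 5), 1000, c(0, 0, 0)), p),
               "misses")
  expect_error(compute_dose(wat, beam_spec(0, c(5, 5), 1000, c(500, 0, 0)),
                            p), "isocenter")
})

test_that("upstream material never increases downstream dose", {
  wat <- water_cube(n = 61, spacing = 2)
  p <- pdd_params()
  beam <- beam_spec(0, c(5, 5), 1000, c(0, 0, 0))
  base <- compute_dose(wat, beam, p)

  blocked <- wat
  blocked$values[26:36, 45:50, 26:36] <- 2.0   # dense block, upstream (+y)
  with_block <- compute_dose(blocked, beam, p)
  downstream <- 1:40
  expect_true(all(with_block$values[, downstream, ] <=
                    base$values[, downstream, ] + 1e-9))
})

test_that("opposing beams on a symmetric phantom give symmetric dose", {
  wat <- water_cube(n = 61, spacing = 2)
  p <- pdd_params()
  da <- compute_dose(wat, beam_spec(90, c(5, 5), 1000, c(0, 0, 0)), p)
  db <- compute_dose(wat, beam_spec(270, c(5, 5), 1000, c(0, 0, 0)), p)
  s <- da$values + db$values
  mirrored <- s[61:1, , ]
  expect_lt(max(abs(s - mirrored)) / max(s), 5e-3)
})

test_that("translation equivariance for integer-voxel shifts", {
  set.seed(9)
  vals <- array(0, c(41, 41, 41))
  vals[11:31, 11:31, 11:31] <- 1
  vals[16:26, 16:26, 16:26] <- 1.3
  vol <- rt_volume(vals, 2, c(-40, -40, -40), "DENSITY")
  p <- pdd_params()
  d0 <- compute_dose(vol, beam_spec(0, c(4, 4), 1000, c(2, 2, 2)), p)

  shifted <- rt_volume(vals, 2, c(-40, -40, -40) + c(4, -6, 2), "DENSITY")
  d1 <- compute_dose(shifted, beam_spec(0, c(4, 4), 1000,
                                        c(2, 2, 2) + c(4, -6, 2)), p)
  expect_equal(d1$values, d0$values, tolerance = 1e-9)
})

test_that("beam entrance sits on the surface, or on the mask when present", {
  s <- sphere_roi(n = 81, spacing = 1.5, radius = 50)
  dens <- rt_volume(array(as.double(s$mask), dim(s$mask)), 1.5,
                    s$origin, "DENSITY")
  ent <- beam_entrance_point(dens, beam_spec(90, c(5, 5), 1000, c(0, 0, 0)))
  expect_lt(abs(ent[1] - 50), 1.5)
  expect_lt(max(abs(ent[2:3])), 1e-6)

  shell <- roi_algebra(expand_roi(s, 3), s, "difference")
  masked <- dens
  masked$values[shell$mask] <- 1.2
  ent2 <- beam_entrance_point(masked, beam_spec(90, c(5, 5), 1000,
                                                c(0, 0, 0)))
  expect_gt(ent2[1] - ent[1], 1.5)
  expect_lt(ent2[1] - ent[1], 4.5)

  expect_error(beam_entrance_point(dens, beam_spec(90, c(5, 5), 1000,
                                                   c(0, 0, 0)),
                                   threshold = 2), "does not cross")
})
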