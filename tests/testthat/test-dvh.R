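make_dose_roi <- function(values) {
  n <- length(values)
  dims <- c(n, 1L, 1L)
  dose <- rt_volume(array(values, dims), 1, c(0, 0, 0), "DOSE")
  roi <- rt_roi(array(TRUE, dims), 1, c(0, 0, 0), "ptv")
  list(dose = dose, roi = roi)
}

test_that("D50 is the interpolated median of voxel doses", {
  u <- make_dose_roi(rep(10, 64))
  expect_equal(d50(compute_dvh(u$dose, u$roi)), 10)

  x <- make_dose_roi(sample(1:100))
  expect_equal(d50(compute_dvh(x$dose, x$roi)), 50.5)

  h <- make_dose_roi(c(rep(0, 32), rep(10, 32)))
  expect_equal(d50(compute_dvh(h$dose, h$roi)), 5)

  # permutation invariance and linear scaling
  set.seed(10)
  v <- runif(101, 0, 60)
  a <- make_dose_roi(v)
  b <- make_dose_roi(sample(v))
  expect_equal(d50(compute_dvh(a$dose, a$roi)), d50(compute_dvh(b$dose, b$roi)))
  s <- make_dose_roi(3 * v)
  expect_equal(d50(compute_dvh(s$dose, s$roi)),
               3 * d50(compute_dvh(a$dose, a$roi)))

  dvh <- compute_dvh(a$dose, a$roi)
  fr <- dvh_volume_fraction(dvh, c(-1, d50(dvh), 1e9))
  expect_equal(fr[1], 1)
  expect_equal(fr[3], 0)
  expect_gte(fr[2], 0.5)

  empty <- rt_roi(array(FALSE, c(101, 1, 1)), 1, c(0, 0, 0))
  expect_error(compute_dvh(a$dose, empty), "empty")
})

test_that("percent D50 deviation has the documented sign convention", {
  expect_equal(delta_d50_pct(10, 10), 0)
  expect_equal(delta_d50_pct(10, 10.2), 2)
  expect_equal(delta_d50_pct(60, 58.8), -2)
  expect_error(delta_d50_pct(0, 1), "> 0")
})

test_that("PTV-to-entrance distance follows the beam geometry", {
  s <- sphere_roi(n = 81, spacing = 1.5, radius = 60)
  dens <- rt_volume(array(as.double(s$mask), dim(s$mask)), 1.5, s$origin,
                    "DENSITY")
  ptv <- sphere_roi(n = 81, spacing = 1.5, radius = 10, center = c(30, 0, 0))
  b90 <- beam_spec(90, c(5, 5), 1000, c(0, 0, 0))
  b270 <- beam_spec(270, c(5, 5), 1000, c(0, 0, 0))
  expect_lt(abs(d_ptv(ptv, b90, dens) - 30), 1.6)
  expect_lt(abs(d_ptv(ptv, b270, dens) - 90), 1.6)

  at_surface <- sphere_roi(n = 81, spacing = 1.5, radius = 6,
                           center = c(57, 0, 0))
  expect_lt(d_ptv(at_surface, b90, dens), 4)
})

test_that("depth-gradient fit is ordinary least squares", {
  x <- seq(10, 150, by = 10)
  f <- fit_slope(x, 0.01 * x + 0.1)
  expect_equal(f$m, 0.01, tolerance = 1e-12)
  expect_equal(f$intercept, 0.1, tolerance = 1e-12)

  expect_equal(fit_slope(x, rep(2, length(x)))$m, 0)
  expect_error(fit_slope(rep(1, 5), 1:5), "distinct")

  set.seed(11)
  xr <- runif(100, 0, 100)
  yr <- xr + rnorm(100, 0, 0.01)
  fit <- fit_slope(xr, yr)
  se <- summary(lm(yr ~ xr))$coefficients[2, 2]
  expect_lt(abs(fit$m - 1), 3 * se)
})

test_that("opposing-beam sums cancel antisymmetric member errors", {
  n <- 64
  base <- make_dose_roi(runif(n, 4, 6))
  other <- make_dose_roi(runif(n, 4, 6))
  scale_dose <- function(d, f) {
    out <- d
    out$values <- d$values * f
    out
  }
  same <- opposing_sum_eval(base$dose, other$dose, base$dose, other$dose,
                            base$roi)
  expect_equal(same$delta_pct, 0)

  # equal D50 contributions scaled in opposite directions nearly cancel
  u1 <- make_dose_roi(rep(5, n))
  u2 <- make_dose_roi(rep(5, n))
  cancel <- opposing_sum_eval(u1$dose, u2$dose, scale_dose(u1$dose, 1.02),
                              scale_dose(u2$dose, 0.98), u1$roi)
  expect_lt(abs(cancel$delta_pct), 0.1)

  both <- opposing_sum_eval(base$dose, other$dose,
                            scale_dose(base$dose, 1.02),
                            scale_dose(other$dose, 1.02), base$roi)
  expect_equal(both$delta_pct, 2, tolerance = 1e-9)
})

test_that("summary statistics reproduce the cohort worked example", {
  tab <- example_cohort_table()
  expect_equal(summarize_values(tab$ptv_cc)$median, 10.17)
  expect_equal(summarize_values(tab$age_years)$median, 63)

  s <- summarize_values(c(2, 4, 6, 8))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, sd(c(2, 4, 6, 8)))
  expect_equal(s$median, 5)

  one <- summarize_values(7)
  expect_equal(one$mean, 7)
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)
  expect_error(summarize_values(numeric(0)), "no values")
})
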