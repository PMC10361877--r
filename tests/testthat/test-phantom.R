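test_that("phantom generator is deterministic and builds the device stack", {
  p <- small_phantom_params(seed = 11)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$sct$values, b$sct$values)
  expect_identical(a$mr$values, b$mr$values)

  expect_length(a$structures$markers, 4)
  expect_true(all(c("external", "brain", "skull", "true_mask", "holder_low",
                    "holder_high", "table_low", "table_high") %in%
                    names(a$structures)))

  # device-visibility contract: devices carry their nominal HU in the CT and
  # are absent (background air) from the synthetic CT
  lut <- p$lut
  nominal <- c(holder_high = 1.2, holder_low = 1.0, table_high = 1.7,
               table_low = 0.11)
  marker_mask <- Reduce(`|`, lapply(a$structures$markers, function(r) r$mask))
  for (nm in names(nominal)) {
    m <- a$structures[[nm]]$mask & !marker_mask   # markers sit in the holder
    expect_equal(mean(a$ct$values[m]), density_to_hu(lut, nominal[[nm]]),
                 tolerance = 1e-9)
    expect_equal(mean(a$sct$values[m]), -1000, tolerance = 1e-9)
  }
  m <- a$structures$true_mask$mask
  expect_equal(mean(a$ct$values[m]), density_to_hu(lut, 1.2),
               tolerance = 1e-9)
  expect_equal(mean(a$sct$values[m]), -1000, tolerance = 1e-9)

  # markers visible in the pseudo-MR, well above background
  mr_bg <- a$mr$values[!a$structures$external$mask &
                         !Reduce(`|`, lapply(a$structures$markers,
                                             function(r) r$mask))]
  for (r in a$structures$markers)
    expect_gt(mean(a$mr$values[r$mask]),
              mean(mr_bg) + 5 * sd(mr_bg))
})

test_that("synthetic-CT degradation applies class bias, noise and identity", {
  p <- small_phantom_params(seed = 12)
  case <- generate_phantom(p)
  classes <- list(soft = case$structures$external$mask &
                    !case$structures$skull$mask,
                  bone = case$structures$skull$mask,
                  air = !case$structures$external$mask)

  ident <- degrade_to_sct(case$ct_anatomy, no_perturbation(), classes)
  expect_identical(ident$values, case$ct_anatomy$values)

  pb <- sct_perturbation(0, -30, 0, 0, 0)
  out <- degrade_to_sct(case$ct_anatomy, pb, classes)
  expect_equal(mean(out$values[classes$bone]) -
                 mean(case$ct_anatomy$values[classes$bone]), -30,
               tolerance = 1e-9)
  expect_identical(out$values[classes$air],
                   case$ct_anatomy$values[classes$air])

  n1 <- degrade_to_sct(case$ct_anatomy,
                       sct_perturbation(0, 0, 0, 10, 0, seed = 1), classes)
  n2 <- degrade_to_sct(case$ct_anatomy,
                       sct_perturbation(0, 0, 0, 10, 0, seed = 2), classes)
  expect_gt(mean(n1$values[classes$soft] != n2$values[classes$soft]), 0.99)
  nsoft <- sum(classes$soft)
  se <- sqrt(2) * 10 / sqrt(nsoft)
  expect_lt(abs(mean(n1$values[classes$soft]) -
                  mean(n2$values[classes$soft])), 3 * se)

  expect_error(sct_perturbation(noise_sd_hu = -1), ">= 0")
})

test_that("sixteen artificial PTVs are placed on the opposing-beam axes", {
  case <- generate_phantom(small_phantom_params(seed = 13))
  ptvs <- place_artificial_ptvs(case)
  expect_length(ptvs$rois, 16)
  expect_equal(nrow(ptvs$table), 16)
  expect_setequal(unique(ptvs$table$pair), c("sf1", "sf2", "sf3", "sf4"))

  vol_nominal <- 4 / 3 * pi * 1^3  # cc, 2 cm diameter
  for (r in ptvs$rois) {
    expect_lt(abs(volume_cc(r) - vol_nominal) / vol_nominal, 0.10)
    expect_false(any(r$mask & !case$structures$brain$mask))
  }

  # lateral axis: distinct symmetric x, common y and z
  sf1 <- ptvs$table[ptvs$table$pair == "sf1", ]
  cen <- t(vapply(ptvs$rois[sf1$ptv], roi_centroid, numeric(3)))
  expect_lt(max(abs(cen[, 2] - case$isocenter[2])), 1.0)
  expect_lt(max(abs(cen[, 3] - case$isocenter[3])), 1.0)
  expect_equal(unname(sort(cen[, 1] + rev(cen[, 1]))),
               rep(2 * case$isocenter[1], 4), tolerance = 1.6)
  expect_equal(length(unique(round(cen[, 1]))), 4)

  expect_error(place_artificial_ptvs(case, fractions = c(0.99)),
               "inside the brain")
})

test_that("markers are recovered within one voxel across seeds", {
  for (seed in 1:8) {
    case <- generate_phantom(small_phantom_params(seed = 100 + seed))
    det <- detect_markers(case$mr, external = case$structures$external)
    err <- sqrt(rowSums((det - case$true_marker_centroids)^2))
    expect_lt(max(err), 1.5)
  }
})
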