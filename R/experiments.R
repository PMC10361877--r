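#' Experiment configuration
#'
#' Bundles the cohort definition, the mask sweep grid, the static-field plan
#' and the misplacement settings used by the three studies. All randomness
#' flows from `seed`: phantom `i` uses a derived child seed, so the full
#' pipeline is reproducible from one integer.
#'
#' The three studies each fix their synthetic-CT perturbation explicitly:
#' the mask sweep and the misplacement study run with unperturbed anatomy so
#' that they isolate device-modeling and placement error respectively, while
#' the static-field study uses the configured perturbation (the phantom
#' default, or a pure density rescaling via `anatomy_scale`).
#'
#' @param n_phantoms Cohort size (default 10).
#' @param seed Master seed.
#' @param base_params [phantom_params()] template for the cohort; head
#'   semi-axes are jittered per phantom.
#' @param semiaxis_jitter Relative half-range of the uniform semi-axis
#'   jitter (default 0.10).
#' @param lut HU LUT shared by both arms.
#' @param pdd [pdd_params()] of the dose engine.
#' @param mu Monitor units per field.
#' @param sweep_thicknesses,sweep_densities Mask sweep grid (mm, g/cm^3).
#' @param include_no_mask Include the no-mask configuration in the sweep.
#' @param sweep_angles Gantry angles of the pseudo-plan used in the sweep.
#' @param sweep_perturbation Perturbation for the sweep arm.
#' @param static_perturbation Perturbation for the static-field arm.
#' @param anatomy_scale Multiplier on the LUT-converted anatomy density of
#'   the evaluated arm (1 = none); used for systematic-density-bias studies.
#' @param placement Template placement mode: `"marker_fit"` (detect markers
#'   in the pseudo-MR and fit), `"truth"` (exact), or `"misplaced"`.
#' @param misplace_rot_deg,misplace_trans_mm Misplacement magnitude (rotation
#'   about the superior axis through the isocenter, translation along the
#'   lateral axis).
#' @param misplace_angles,misplace_n Beams and number of phantoms of the
#'   misplacement study.
#' @export
experiment_config <- function(n_phantoms = 10, seed = 1,
                              base_params = phantom_params(),
                              semiaxis_jitter = 0.10,
                              lut = default_hu_lut(),
                              pdd = pdd_params(),
                              mu = 1000,
                              sweep_thicknesses = c(2.5, 3),
                              sweep_densities = c(1.1, 1.15, 1.2),
                              include_no_mask = TRUE,
                              sweep_angles = c(0, 90, 180, 270),
                              sweep_perturbation = no_perturbation(),
                              static_perturbation = sct_perturbation(),
                              anatomy_scale = 1,
                              placement = "marker_fit",
                              misplace_rot_deg = 1.5,
                              misplace_trans_mm = 2,
                              misplace_angles = c(135, 225),
                              misplace_n = 4) {
  structure(as.list(environment()), class = "experiment_config")
}

#' Phantom parameter sets of the seeded cohort
#'
#' Head semi-axes are sampled uniformly within `+/- semiaxis_jitter` of the
#' base semi-axes, one draw per phantom from its derived child seed.
#'
#' @param cfg An [experiment_config()].
#' @return List of [phantom_params()].
#' @export
cohort_params <- function(cfg) {
  lapply(seq_len(cfg$n_phantoms), function(i) {
    p <- cfg$base_params
    set.seed(derive_seed(cfg$seed, 500L + i))
    jit <- runif(3, 1 - cfg$semiaxis_jitter, 1 + cfg$semiaxis_jitter)
    p$head_semiaxes <- p$head_semiaxes * jit
    p$seed <- derive_seed(cfg$seed, i)
    p
  })
}

# the 8-field static plan: 5x5 cm cardinal fields, 10x10 cm diagonal fields
static_plan <- function(cfg, isocenter = c(0, 0, 0)) {
  angles <- c(0, 90, 180, 270, 45, 135, 225, 315)
  lapply(angles, function(a) {
    fs <- if (a %% 90 == 0) c(5, 5) else c(10, 10)
    beam_spec(a, fs, cfg$mu, isocenter)
  })
}

pair_of_angle <- function(angle) {
  for (nm in names(opposing_pairs()))
    if (angle %in% opposing_pairs()[[nm]]) return(nm)
  NA_character_
}

# reference arm: the device-bearing CT through the LUT
reference_density <- function(case, lut) {
  compose_density_map(case$ct, lut)
}

# anatomy + true mask only, used to measure entrance distances on the skin
# or mask surface (devices excluded on purpose)
entrance_density <- function(case, lut) {
  v <- case$ct_anatomy$values
  v[case$structures$true_mask$mask] <-
    density_to_hu(lut, case$params$mask_density)
  compose_density_map(rt_volume(v, case$ct$spacing, case$ct$origin, "HU"),
                      lut)
}

# synthetic-CT arm for a given perturbation (regenerated from the anatomy so
# each study controls its own error model)
sct_for <- function(case, pert) {
  classes <- list(
    soft = case$structures$external$mask & !case$structures$skull$mask,
    bone = case$structures$skull$mask,
    air = !case$structures$external$mask)
  if (is.null(pert$seed))
    pert$seed <- derive_seed(case$params$seed, 78L)
  degrade_to_sct(case$ct_anatomy, pert, classes)
}

placement_transform <- function(case, mode, misplace = NULL) {
  if (mode == "truth") return(rt_identity())
  if (mode == "marker_fit") {
    det <- detect_markers(case$mr, external = case$structures$external)
    return(fit_rigid(case$template$marker_points, det))
  }
  if (mode == "misplaced") {
    stopifnot(!is.null(misplace))
    delta <- rigid_transform(rot_z(misplace$rot_deg),
                             c(misplace$trans_mm, 0, 0))
    return(delta)
  }
  stop("unknown placement mode: ", mode)
}

# evaluated arm: synthetic CT + placed template + swept mask shell
evaluated_density <- function(case, cfg, pert, mspec, transform) {
  sct <- sct_for(case, pert)
  external <- extract_external(sct)
  shell <- build_mask_shell(external, mspec)
  placed <- place_template(case$template, transform, vol_grid(sct))
  overrides <- unname(placed$overrides)
  if (mspec$enabled)
    overrides <- c(overrides,
                   list(density_override(shell, mspec$density,
                                         priority_of("mask"))))
  list(density = compose_density_map(sct, cfg$lut, overrides,
                                     anatomy_scale = cfg$anatomy_scale),
       placed = placed, external = external, shell = shell)
}

ptv_dose_vectors <- function(dose, ptvs) {
  lapply(ptvs, function(r) dose$values[r$mask])
}

#' Run the mask-parameter sweep
#'
#' For each phantom: the reference dose is computed on the device-bearing CT
#' arm; the evaluated dose on the synthetic-CT arm with the placed template
#' and a mask shell of each swept (thickness, density) configuration, plus
#' the no-mask configuration. The percent D50 deviation of the summed
#' pseudo-plan (cardinal fields by default) is recorded for every PTV on the
#' plan's beam axes, and summarized per configuration.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print per-phantom progress.
#' @return List with `records` (one row per phantom x config x PTV) and
#'   `summary` (per-config mean, SD and mean absolute deviation).
#' @export
run_mask_sweep <- function(cfg = experiment_config(), progress = FALSE) {
  configs <- sweep_configs(cfg)
  params <- cohort_params(cfg)
  records <- list()
  for (i in seq_along(params)) {
    case <- generate_phantom(params[[i]])
    ptvs <- place_artificial_ptvs(case)
    onplan <- ptvs$table$angle_lo %in% cfg$sweep_angles |
      ptvs$table$angle_hi %in% cfg$sweep_angles
    sel <- ptvs$table$ptv[onplan]
    beams <- lapply(cfg$sweep_angles, function(a)
      beam_spec(a, c(5, 5), cfg$mu, case$isocenter))

    dens_ref <- reference_density(case, cfg$lut)
    dose_ref <- compute_plan_dose(dens_ref, beams, cfg$pdd)
    ref_vec <- ptv_dose_vectors(dose_ref, ptvs$rois[sel])
    rm(dens_ref, dose_ref)

    # the synthetic-CT arm without the mask is shared by all configurations;
    # each config only rewrites the (device-disjoint) shell densities
    transform <- placement_transform(case, cfg$placement)
    sct <- sct_for(case, cfg$sweep_perturbation)
    external <- extract_external(sct)
    placed <- place_template(case$template, transform, vol_grid(sct))
    base <- compose_density_map(sct, cfg$lut, unname(placed$overrides),
                                anatomy_scale = cfg$anatomy_scale)
    shells <- lapply(unique(configs$d[configs$enabled]), function(d)
      build_mask_shell(external, mask_spec(d, 1)))
    names(shells) <- sprintf("%g", unique(configs$d[configs$enabled]))

    for (k in seq_len(nrow(configs))) {
      dens_ev <- base
      if (configs$enabled[k]) {
        shell <- shells[[sprintf("%g", configs$d[k])]]
        dens_ev$values[shell$mask] <- configs$rho[k]
      }
      dose_ev <- compute_plan_dose(dens_ev, beams, cfg$pdd)
      ev_vec <- ptv_dose_vectors(dose_ev, ptvs$rois[sel])
      for (nm in sel) {
        dr <- d50(ref_vec[[nm]])
        de <- d50(ev_vec[[nm]])
        records[[length(records) + 1]] <- data.frame(
          phantom = i, config = configs$label[k], d_mm = configs$d[k],
          rho = configs$rho[k], enabled = configs$enabled[k], ptv = nm,
          d50_ref = dr, d50_eval = de, delta_pct = delta_d50_pct(dr, de))
      }
      rm(dens_ev, dose_ev)
    }
    rm(sct, base, placed)
    gc(FALSE)
    if (progress)
      message(sprintf("mask sweep: phantom %d/%d done", i, length(params)))
  }
  records <- do.call(rbind, records)
  summary <- do.call(rbind, lapply(split(records, records$config), function(g)
    data.frame(config = g$config[1], d_mm = g$d_mm[1], rho = g$rho[1],
               enabled = g$enabled[1], n = nrow(g),
               mean_delta_pct = mean(g$delta_pct),
               sd_delta_pct = sd(g$delta_pct),
               mean_abs_delta_pct = mean(abs(g$delta_pct)))))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}

sweep_configs <- function(cfg) {
  grid <- expand.grid(d = cfg$sweep_thicknesses, rho = cfg$sweep_densities)
  out <- data.frame(label = sprintf("d%.1f_rho%.2f", grid$d, grid$rho),
                    d = grid$d, rho = grid$rho, enabled = TRUE)
  if (cfg$include_no_mask)
    out <- rbind(data.frame(label = "no_mask", d = 0, rho = 0,
                            enabled = FALSE), out)
  out
}

#' Run the static-field test
#'
#' Computes the eight static fields on the reference and evaluated arm of
#' each phantom, evaluates every PTV on each beam's axis (D50 of reference
#' and recalculated dose, percent deviation, centroid-to-entrance distance),
#' sums each opposing pair before evaluation, and fits the depth gradient of
#' the percent deviation per single beam and per opposing pair.
#'
#' @param cfg An [experiment_config()].
#' @param mask The mask specification modeled in the evaluated arm
#'   (default: the phantom's true mask, the chosen optimum).
#' @param progress Print per-phantom progress.
#' @return List with `records`, `pair_records`, `slopes_single`,
#'   `slopes_pair`.
#' @export
run_static_field_test <- function(cfg = experiment_config(),
                                  mask = NULL, progress = FALSE) {
  params <- cohort_params(cfg)
  records <- list()
  pair_records <- list()
  for (i in seq_along(params)) {
    case <- generate_phantom(params[[i]])
    if (is.null(mask))
      mspec <- mask_spec(case$params$mask_thickness_mm,
                         case$params$mask_density)
    else mspec <- mask
    ptvs <- place_artificial_ptvs(case)
    beams <- static_plan(cfg, case$isocenter)
    dens_ref <- reference_density(case, cfg$lut)
    dens_ent <- entrance_density(case, cfg$lut)
    transform <- placement_transform(
      case, cfg$placement,
      misplace = list(rot_deg = cfg$misplace_rot_deg,
                      trans_mm = cfg$misplace_trans_mm))
    ev <- evaluated_density(case, cfg, cfg$static_perturbation, mspec,
                            transform)

    vec_ref <- list(); vec_ev <- list(); dptv <- list()
    for (b in beams) {
      ang <- b$angle_deg
      pnm <- pair_of_angle(ang)
      sel <- ptvs$table$ptv[ptvs$table$pair == pnm]
      dr <- compute_dose(dens_ref, b, cfg$pdd)
      de <- compute_dose(ev$density, b, cfg$pdd)
      ent <- beam_entrance_point(dens_ent, b)
      key <- sprintf("%03d", ang)
      vec_ref[[key]] <- ptv_dose_vectors(dr, ptvs$rois[sel])
      vec_ev[[key]] <- ptv_dose_vectors(de, ptvs$rois[sel])
      dptv[[key]] <- vapply(sel, function(nm)
        sqrt(sum((roi_centroid(ptvs$rois[[nm]]) - ent)^2)), numeric(1))
      for (nm in sel) {
        r50 <- d50(vec_ref[[key]][[nm]])
        e50 <- d50(vec_ev[[key]][[nm]])
        records[[length(records) + 1]] <- data.frame(
          phantom = i, angle = ang, pair = pnm, ptv = nm,
          d50_ref = r50, d50_eval = e50,
          delta_pct = delta_d50_pct(r50, e50),
          d_ptv_mm = dptv[[key]][[nm]])
      }
      rm(dr, de)
    }
    for (pnm in names(opposing_pairs())) {
      ang <- sort(opposing_pairs()[[pnm]])
      ka <- sprintf("%03d", ang[1]); kb <- sprintf("%03d", ang[2])
      sel <- ptvs$table$ptv[ptvs$table$pair == pnm]
      for (nm in sel) {
        sr <- vec_ref[[ka]][[nm]] + vec_ref[[kb]][[nm]]
        se <- vec_ev[[ka]][[nm]] + vec_ev[[kb]][[nm]]
        r50 <- d50(sr); e50 <- d50(se)
        pair_records[[length(pair_records) + 1]] <- data.frame(
          phantom = i, pair = pnm, angle_lo = ang[1], angle_hi = ang[2],
          ptv = nm, d50_ref = r50, d50_eval = e50,
          delta_pct = delta_d50_pct(r50, e50),
          d_ptv_mm = dptv[[ka]][[nm]])
      }
    }
    rm(case, dens_ref, dens_ent, ev)
    gc(FALSE)
    if (progress)
      message(sprintf("static fields: phantom %d/%d done", i, length(params)))
  }
  records <- do.call(rbind, records)
  pair_records <- do.call(rbind, pair_records)
  slopes_single <- do.call(rbind, lapply(split(records, records$angle),
    function(g) {
      f <- fit_slope(g$d_ptv_mm, g$delta_pct)
      data.frame(angle = g$angle[1], m_pct_per_mm = f$m,
                 intercept_pct = f$intercept, n = f$n,
                 mean_delta_pct = mean(g$delta_pct))
    }))
  slopes_pair <- do.call(rbind, lapply(split(pair_records, pair_records$pair),
    function(g) {
      f <- fit_slope(g$d_ptv_mm, g$delta_pct)
      data.frame(pair = g$pair[1], m_pct_per_mm = f$m,
                 intercept_pct = f$intercept, n = f$n,
                 mean_delta_pct = mean(g$delta_pct))
    }))
  rownames(slopes_single) <- rownames(slopes_pair) <- NULL
  list(records = records, pair_records = pair_records,
       slopes_single = slopes_single, slopes_pair = slopes_pair)
}

#' Run the template-misplacement study
#'
#' Compares the percent D50 deviation of the holder-attenuated oblique beams
#' under exact template placement against a deliberately misplaced template
#' (default 1.5 degree rotation + 2 mm lateral shift, the order of the
#' rotational setup differences seen between imaging sessions), on otherwise
#' unperturbed anatomy so that placement is the only error source. The
#' improvement is the reduction of the mean absolute deviation obtained by
#' repositioning the template from the misplaced to the exact pose.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print per-phantom progress.
#' @return data.frame, one row per phantom, with mean absolute deviations
#'   under both placements and the improvement.
#' @export
run_misplacement_study <- function(cfg = experiment_config(),
                                   progress = FALSE) {
  params <- cohort_params(cfg)[seq_len(min(cfg$misplace_n, cfg$n_phantoms))]
  out <- list()
  for (i in seq_along(params)) {
    case <- generate_phantom(params[[i]])
    mspec <- mask_spec(case$params$mask_thickness_mm,
                       case$params$mask_density)
    ptvs <- place_artificial_ptvs(case)
    beams <- lapply(cfg$misplace_angles, function(a)
      beam_spec(a, c(10, 10), cfg$mu, case$isocenter))
    dens_ref <- reference_density(case, cfg$lut)
    ref50 <- list()
    for (b in beams) {
      pnm <- pair_of_angle(b$angle_deg)
      sel <- ptvs$table$ptv[ptvs$table$pair == pnm]
      dr <- compute_dose(dens_ref, b, cfg$pdd)
      ref50[[sprintf("%03d", b$angle_deg)]] <-
        vapply(sel, function(nm) d50(dr$values[ptvs$rois[[nm]]$mask]),
               numeric(1))
      rm(dr)
    }
    deltas <- list(truth = c(), misplaced = c())
    for (mode in c("truth", "misplaced")) {
      transform <- placement_transform(
        case, mode, misplace = list(rot_deg = cfg$misplace_rot_deg,
                                    trans_mm = cfg$misplace_trans_mm))
      ev <- evaluated_density(case, cfg, no_perturbation(), mspec, transform)
      for (b in beams) {
        pnm <- pair_of_angle(b$angle_deg)
        sel <- ptvs$table$ptv[ptvs$table$pair == pnm]
        key <- sprintf("%03d", b$angle_deg)
        de <- compute_dose(ev$density, b, cfg$pdd)
        for (nm in sel) {
          e50 <- d50(de$values[ptvs$rois[[nm]]$mask])
          deltas[[mode]] <- c(deltas[[mode]],
                              delta_d50_pct(ref50[[key]][[nm]], e50))
        }
        rm(de)
      }
    }
    out[[i]] <- data.frame(
      phantom = i,
      mean_abs_delta_truth_pct = mean(abs(deltas$truth)),
      mean_abs_delta_misplaced_pct = mean(abs(deltas$misplaced)),
      improvement_pct = mean(abs(deltas$misplaced)) -
        mean(abs(deltas$truth)))
    rm(case, dens_ref)
    gc(FALSE)
    if (progress)
      message(sprintf("misplacement: phantom %d/%d done", i, length(params)))
  }
  do.call(rbind, out)
}
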