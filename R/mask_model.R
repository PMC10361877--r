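#' Mask specification
#'
#' Thickness and density of the simplified thermoplastic-mask model: a
#' uniform shell of thickness `d` around the external contour with an
#' assigned relative mass density. `enabled = FALSE` represents the
#' no-mask case.
#'
#' @param thickness_mm Shell thickness d in mm (> 0 when enabled).
#' @param density Relative mass density rho in g/cm^3 (> 0 when enabled).
#' @param enabled Logical.
#' @export
mask_spec <- function(thickness_mm = 3, density = 1.2, enabled = TRUE) {
  if (enabled) {
    stopifnot(is.finite(thickness_mm), thickness_mm > 0,
              is.finite(density), density > 0)
  }
  structure(list(thickness_mm = thickness_mm, density = density,
                 enabled = enabled),
            class = "mask_spec")
}

#' Density override: force a density inside an ROI
#'
#' @param roi An `rt_roi`.
#' @param density Relative mass density (g/cm^3), `>= 0`.
#' @param priority Integer; on overlap the higher priority wins. Convention:
#'   markers (4) > mask (3) > holder (2) > table (1) > anatomy.
#' @export
density_override <- function(roi, density, priority = 1L) {
  stopifnot(is.finite(density), density >= 0)
  structure(list(roi = roi, density = density, priority = as.integer(priority)),
            class = "density_override")
}

#' Extract the external (outer body) contour from an HU volume
#'
#' Thresholds the volume, optionally removes device voxels, keeps the largest
#' 6-connected component and fills interior holes (air cavities). The result
#' must not touch the grid boundary - an external contour clipped by the
#' field of view is rejected as non-anatomical.
#'
#' @param vol An `rt_volume` of kind `"HU"`.
#' @param threshold_hu Threshold above which voxels are candidate body
#'   (default -400 HU).
#' @param exclude Optional list of `rt_roi`s (devices) removed before
#'   thresholding.
#' @return An `rt_roi` named `"external"`.
#' @export
extract_external <- function(vol, threshold_hu = -400, exclude = NULL) {
  stopifnot(vol$kind == "HU")
  m <- vol$values > threshold_hu
  if (!is.null(exclude)) {
    if (inherits(exclude, "rt_roi")) exclude <- list(exclude)
    for (r in exclude) {
      check_same_grid(vol, r)
      m <- m & !r$mask
    }
  }
  if (!any(m)) stop("external extraction failed: no voxels above threshold")
  lab <- cpp_label3d(m, dim(vol$values))
  counts <- tabulate(lab)
  main <- array(lab == which.max(counts), dim = dim(vol$values))
  main <- fill_holes(main)
  if (touches_boundary(main))
    stop("external contour touches the grid boundary; not a valid anatomy")
  rt_roi(main, vol$spacing, vol$origin, "external",
         meta = list(threshold_hu = threshold_hu))
}

touches_boundary <- function(m) {
  d <- dim(m)
  any(m[1, , ]) || any(m[d[1], , ]) || any(m[, 1, ]) || any(m[, d[2], ]) ||
    any(m[, , 1]) || any(m[, , d[3]])
}

# fill interior cavities: complement components not connected to the boundary
fill_holes <- function(m) {
  d <- dim(m)
  lab <- array(cpp_label3d(!m, d), d)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  hole <- array(lab > 0 & !(lab %in% border), dim = d)
  m | hole
}

#' Build the simplified mask shell around the external contour
#'
#' ROI algebra "(external + d) - external": the external contour is expanded
#' by the mask thickness and the original contour subtracted, leaving a shell
#' of thickness d that models the molded thermoplastic mask (without nose
#' mold, fixation toggles or mask extensions).
#'
#' @param external The external `rt_roi`.
#' @param spec A [mask_spec()].
#' @return An `rt_roi` named `"mask"`; empty (with `meta$enabled = FALSE`)
#'   for a disabled spec.
#' @export
build_mask_shell <- function(external, spec = mask_spec()) {
  if (!spec$enabled) {
    return(rt_roi(array(FALSE, dim(external$mask)), external$spacing,
                  external$origin, "mask",
                  meta = list(enabled = FALSE)))
  }
  shell <- roi_algebra(expand_roi(external, spec$thickness_mm), external,
                       "difference", name = "mask")
  shell$meta <- list(enabled = TRUE, thickness_mm = spec$thickness_mm,
                     density = spec$density)
  shell
}

#' Compose the density volume used for dose calculation
#'
#' Converts an HU volume to relative mass density through the LUT, optionally
#' rescales the anatomy densities (to emulate a systematic synthetic-CT
#' density error), then applies ROI density overrides in increasing priority
#' order so that higher-priority structures win on overlap. Overlapping
#' overrides of equal priority but different density are an error.
#'
#' @param vol An `rt_volume` of kind `"HU"`.
#' @param lut An `hu_lut`.
#' @param overrides List of [density_override()]s on the same grid.
#' @param anatomy_scale Multiplier applied to the LUT-converted densities
#'   before overrides (default 1).
#' @return An `rt_volume` of kind `"DENSITY"`.
#' @export
compose_density_map <- function(vol, lut = default_hu_lut(), overrides = list(),
                                anatomy_scale = 1) {
  stopifnot(vol$kind == "HU")
  dens <- hu_to_density(lut, vol$values) * anatomy_scale
  if (length(overrides)) {
    pr <- vapply(overrides, function(o) o$priority, integer(1))
    # equal-priority overlap with conflicting densities is ambiguous
    for (p in unique(pr)) {
      grp <- overrides[pr == p]
      if (length(grp) > 1) {
        for (i in seq_along(grp)) for (j in seq_len(i - 1)) {
          if (grp[[i]]$density != grp[[j]]$density &&
              any(grp[[i]]$roi$mask & grp[[j]]$roi$mask))
            stop("overlapping overrides with equal priority and different densities")
        }
      }
    }
    for (o in overrides[order(pr)]) {
      check_same_grid(vol, o$roi)
      dens[o$roi$mask] <- o$density
    }
  }
  rt_volume(dens, vol$spacing, vol$origin, "DENSITY")
}
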