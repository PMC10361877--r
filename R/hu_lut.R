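#' Hounsfield-unit to relative mass density lookup table
#'
#' Piecewise-linear conversion curve between HU and relative mass density
#' (g/cm^3), as used by treatment planning systems to turn a CT (or synthetic
#' CT) into the density volume the dose calculation consumes. Nodes must be
#' strictly increasing in HU, non-decreasing in density, and cover at least
#' \[-1000, 2000\] HU. The same LUT must be used for the reference-CT arm and
#' the synthetic-CT arm of any comparison, so that LUT choice cancels out of
#' the dosimetric contrasts.
#'
#' @param nodes Two-column matrix (or list of pairs) of (HU, density) nodes.
#' @return An object of class `hu_lut`.
#' @export
hu_lut <- function(nodes) {
  if (is.list(nodes)) nodes <- do.call(rbind, lapply(nodes, as.numeric))
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 2, nrow(nodes) >= 2)
  hu <- nodes[, 1]; rho <- nodes[, 2]
  if (any(diff(hu) <= 0)) stop("LUT HU nodes must be strictly increasing")
  if (any(rho < 0)) stop("LUT densities must be non-negative")
  if (any(diff(rho) < 0)) stop("LUT densities must be non-decreasing")
  if (hu[1] > -1000 || hu[length(hu)] < 2000)
    stop("LUT must cover at least [-1000, 2000] HU")
  structure(list(hu = hu, density = rho), class = "hu_lut")
}

#' Default HU-density curve
#'
#' A generic water--bone ramp: (-1000, 0), (0, 1.0), (1000, 1.58),
#' (2000, 2.2). Clinical curves are scanner calibrations and belong in
#' configuration; this default is used consistently on both arms of every
#' comparison in this package.
#' @export
default_hu_lut <- function() {
  hu_lut(rbind(c(-1000, 0), c(0, 1), c(1000, 1.58), c(2000, 2.2)))
}

#' Convert HU to relative mass density
#'
#' Piecewise-linear interpolation between LUT nodes, clamped at the end nodes.
#' @param lut An `hu_lut`.
#' @param hu Numeric vector (or array) of HU values.
#' @return Densities in g/cm^3, same shape as `hu`.
#' @export
hu_to_density <- function(lut, hu) {
  if (any(!is.finite(hu))) stop("non-finite HU input")
  out <- stats::approx(lut$hu, lut$density, xout = as.numeric(hu),
                       rule = 2)$y
  if (is.array(hu)) out <- array(out, dim = dim(hu))
  out
}

#' Convert relative mass density back to HU
#'
#' Inverse of [hu_to_density()] on strictly increasing LUT segments. Used to
#' express density overrides (devices, mask) as HU when assembling reference
#' CT volumes, so that HU -> density -> HU round trips exactly.
#'
#' @param lut An `hu_lut`.
#' @param density Numeric vector of densities within the LUT range.
#' @return HU values.
#' @export
density_to_hu <- function(lut, density) {
  density <- as.numeric(density)
  if (any(!is.finite(density))) stop("non-finite density input")
  rng <- range(lut$density)
  if (any(density < rng[1] - 1e-12 | density > rng[2] + 1e-12))
    stop("density outside LUT range")
  flat <- lut$density[which(diff(lut$density) == 0)]
  vapply(density, function(d) {
    if (any(abs(flat - d) < 1e-12))
      stop("non-invertible segment: LUT is flat at density ", d)
    # locate segment containing d
    i <- findInterval(d, lut$density, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(lut$density) - 1L)
    d0 <- lut$density[i]; d1 <- lut$density[i + 1]
    if (d1 == d0) {
      if (abs(d - d0) < 1e-12)
        stop("non-invertible segment: LUT is flat at density ", d0)
      stop("density not on an invertible LUT segment")
    }
    lut$hu[i] + (d - d0) / (d1 - d0) * (lut$hu[i + 1] - lut$hu[i])
  }, numeric(1))
}

#' Read / write an HU LUT as JSON
#'
#' The file is a JSON list of `[hu, density]` pairs.
#' @param path File path.
#' @export
read_hu_lut <- function(path) {
  nodes <- jsonlite::read_json(path, simplifyVector = TRUE)
  hu_lut(nodes)
}

#' @rdname read_hu_lut
#' @param lut An `hu_lut`.
#' @export
write_hu_lut <- function(lut, path) {
  jsonlite::write_json(unname(cbind(lut$hu, lut$density)), path, digits = NA)
  invisible(path)
}
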