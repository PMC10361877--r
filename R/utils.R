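# Separable Gaussian smoothing of a 3-D array, kernel specified by FWHM in mm.
# Zero FWHM returns the input unchanged. Borders are renormalized (kernel
# weights outside the grid are dropped), so constant regions stay constant.
gaussian_smooth3 <- function(a, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(a)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(a)
  for (ax in 1:3) {
    s_vox <- sigma / spacing[ax]
    r <- max(1L, ceiling(3 * s_vox))
    k <- dnorm(seq(-r, r), sd = s_vox)
    k <- k / sum(k)
    a <- convolve_axis(a, k, ax)
  }
  a
}

convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  n <- dp[1]
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (o in seq(-r, r)) {
    w <- k[o + r + 1L]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], ]
    wsum[ok] <- wsum[ok] + w
  }
  out <- out / wsum
  ap <- array(out, dp)
  aperm(ap, order(perm))
}

# deterministic child seeds (kept well below 2^31)
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(i)
}
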