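#' Harmonics available for an n-band cube
#'
#' The discrete Fourier transform of an n-band spectrum yields n harmonics;
#' k = 0 is the spectrum average (identically (1, 0) after normalization) and
#' is never exposed as a feature, leaving k = 1, ..., n - 1.
#'
#' @param n_bands Channel count, >= 2.
#' @return Integer vector `1:(n_bands - 1)`.
#' @examples
#' harmonics_available(12)  # 1..11
#' @export
harmonics_available <- function(n_bands) {
  if (!is.numeric(n_bands) || n_bands < 2)
    stop("need at least 2 bands")
  seq_len(as.integer(n_bands) - 1L)
}

phasor_phase <- function(bands, k, phase_axis = c("index", "wavelength")) {
  phase_axis <- match.arg(phase_axis)
  n <- bands$n
  if (phase_axis == "index") {
    m <- 0:(n - 1)
    list(phi = 2 * pi * k * m / n, w = rep(1, n))
  } else {
    lam <- bands$centers_nm
    list(phi = 2 * pi * k * (lam - lam[1]) / (lam[n] - lam[1]),
         w = bands$bandwidths_nm)
  }
}

#' Per-pixel spectral phasor transform
#'
#' Maps each pixel's spectrum I(m), m = 0..n-1 in ascending wavelength, to
#' phasor coordinates at harmonic k:
#' \deqn{g = \frac{\sum_m I(m)\cos(2\pi k m/n)}{\sum_m I(m)}, \quad
#'       s = \frac{\sum_m I(m)\sin(2\pi k m/n)}{\sum_m I(m)}}
#' The default phase axis is the band index (uniform phase per channel, the
#' standard spectral-phasor convention; with a single camera the constant
#' channel bandwidth cancels in the ratio). `phase_axis = "wavelength"` instead
#' uses phase proportional to wavelength offset and weights both sums by the
#' per-band bandwidths. For nonnegative spectra the phasor is a convex
#' combination of unit-circle points, so g^2 + s^2 <= 1; Z-scored spectra can
#' leave the unit disk and can have a near-zero denominator, in which case the
#' pixel is invalidated (|sum I| < eps) rather than producing an unbounded
#' phasor.
#'
#' @param cube [spectral_cube] with n >= 2 bands.
#' @param k Harmonic, in `harmonics_available(n)`.
#' @param eps Denominator guard; pixels with |sum of spectrum| < eps become
#'   invalid. Default 1e-6.
#' @param phase_axis `"index"` (default) or `"wavelength"`.
#' @param min_denom_quantile Optional adaptive guard in (0, 1): `eps` is
#'   raised to this quantile of |sum of spectrum| over the cube's valid
#'   pixels. This is the spectral analogue of the intensity thresholding
#'   routinely applied before lifetime phasor analysis: pixels whose spectrum
#'   sums to nearly zero (common after Z-scoring) have an ill-determined
#'   phase, and dividing by the near-zero sum turns them into heavy-tailed
#'   noise that dominates the scope average.
#' @return A `phasor_field`: list with H x W matrices `g` and `s`, the
#'   `harmonic`, and a `valid` mask (input validity AND denominator guard).
#' @export
phasor_transform <- function(cube, k, eps = 1e-6,
                             phase_axis = c("index", "wavelength"),
                             min_denom_quantile = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  n <- cube$bands$n
  if (n < 2L) stop("phasor transform needs at least 2 bands")
  k <- as.integer(k)
  if (length(k) != 1L || k < 1L || k > n - 1L)
    stop(sprintf("harmonic k must be in 1..%d", n - 1L))
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  ph <- phasor_phase(cube$bands, k, phase_axis)
  d <- dim(cube$pixels)
  flat <- matrix(cube$pixels, nrow = d[1] * d[2])  # pixels x bands
  denom <- as.vector(flat %*% ph$w)
  gnum <- as.vector(flat %*% (cos(ph$phi) * ph$w))
  snum <- as.vector(flat %*% (sin(ph$phi) * ph$w))
  if (!is.null(min_denom_quantile)) {
    if (min_denom_quantile <= 0 || min_denom_quantile >= 1)
      stop("min_denom_quantile must be in (0, 1)")
    eps <- max(eps, stats::quantile(abs(denom)[as.vector(cube$valid)],
                                    min_denom_quantile, names = FALSE))
  }
  ok <- abs(denom) >= eps
  denom[!ok] <- 1
  g <- matrix(gnum / denom, d[1], d[2])
  s <- matrix(snum / denom, d[1], d[2])
  g[!ok] <- NA_real_
  s[!ok] <- NA_real_
  structure(
    list(g = g, s = s, harmonic = k,
         valid = cube$valid & matrix(ok, d[1], d[2])),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("phasor_field: %dx%d, harmonic k=%d, %d/%d valid\n",
              nrow(x$g), ncol(x$g), x$harmonic, sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Summarize a phasor field over a pixel scope
#'
#' Averages the per-pixel phasor coordinates over the scope into a single
#' (g_avg, s_avg) point per case/ROI, and computes a scalar dispersion
#' STD = sqrt(var(g) + var(s)) with population variances over the same scope
#' (a rotation-invariant measure of the spread of the 2-D phasor cloud).
#'
#' @param field A `phasor_field` from [phasor_transform()].
#' @param scope [roi_mask] or H x W logical matrix; intersected with the
#'   field's validity mask. Must be nonempty; >= 2 pixels for the STD.
#' @return A `phasor_summary`: list with `g_avg`, `s_avg`, `std`, `harmonic`,
#'   `n_pixels`.
#' @export
summarize_phasor <- function(field, scope) {
  stopifnot(inherits(field, "phasor_field"))
  mask <- if (inherits(scope, "roi_mask")) scope$mask else as.matrix(scope)
  sel <- mask & field$valid
  np <- sum(sel)
  if (np < 1L) stop("empty scope for phasor summary")
  g <- field$g[sel]
  s <- field$s[sel]
  g_avg <- mean(g)
  s_avg <- mean(s)
  std <- if (np >= 2L)
    sqrt(mean((g - g_avg)^2) + mean((s - s_avg)^2))
  else NA_real_
  structure(list(g_avg = g_avg, s_avg = s_avg, std = std,
                 harmonic = field$harmonic, n_pixels = np),
            class = "phasor_summary")
}

#' @export
print.phasor_summary <- function(x, ...) {
  cat(sprintf("phasor_summary (k=%d, %d px): g_avg=%.4f s_avg=%.4f std=%.4f\n",
              x$harmonic, x$n_pixels, x$g_avg, x$s_avg, x$std))
  invisible(x)
}

#' Per-band average features
#'
#' The reflectance-averaging baseline: the mean of each band's values over
#' the scope, giving an n-dimensional feature vector (12-dim "Avg-MSI" for
#' the full cube, 3-dim "Avg-RGB" for the RGB-like sub-cube).
#'
#' @param cube A [spectral_cube].
#' @param scope [roi_mask] or H x W logical matrix; intersected with the
#'   cube's validity mask. Must be nonempty.
#' @return Numeric vector of length n, named by band center.
#' @export
band_average_features <- function(cube, scope) {
  stopifnot(inherits(cube, "spectral_cube"))
  mask <- if (inherits(scope, "roi_mask")) scope$mask else as.matrix(scope)
  sel <- mask & cube$valid
  if (!any(sel)) stop("empty scope for band averages")
  out <- vapply(seq_len(cube$bands$n),
                function(m) mean(cube$pixels[, , m][sel]), numeric(1))
  names(out) <- paste0("avg_", cube$bands$centers_nm)
  out
}
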