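#' Band-wise Z-score normalization
#'
#' Standardizes each band independently to zero mean and unit variance over
#' the pixels in `scope_mask` that are valid in the cube:
#' \deqn{Z = (X - \mu) / \sigma}
#' with \eqn{\mu} and \eqn{\sigma} the mean and population standard deviation
#' of that band's values over the scope. Normalizing band-wise means one
#' band's values never influence another's, and it emphasizes relative
#' spectral contrast over absolute reflectance. All pixels of the cube are
#' transformed (using the scope statistics), so downstream ROI restriction
#' still sees consistently scaled values.
#'
#' @param cube [spectral_cube] with stage `"reflectance"`.
#' @param scope_mask [roi_mask] defining the pixels over which the per-band
#'   statistics are computed (normally the entire retina); needs at least 2
#'   in-scope valid pixels.
#' @return A [spectral_cube] with stage `"zscored"`.
#' @export
zscore_bands <- function(cube, scope_mask) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(scope_mask, "roi_mask"))
  if (cube$stage != "reflectance")
    stop("zscore_bands expects a reflectance cube")
  sel <- scope_mask$mask & cube$valid
  if (sum(sel) < 2L) stop("Z-score scope must contain at least 2 valid pixels")
  out <- cube$pixels
  for (m in seq_len(cube$bands$n)) {
    v <- cube$pixels[, , m][sel]
    mu <- mean(v)
    sigma <- sqrt(mean((v - mu)^2))  # population sd
    if (sigma <= 0)
      stop(sprintf("zero variance in band %g nm over the Z-score scope",
                   cube$bands$centers_nm[m]))
    out[, , m] <- (cube$pixels[, , m] - mu) / sigma
  }
  spectral_cube(out, cube$bands, stage = "zscored", valid = cube$valid)
}

#' Percentile trimming policy
#'
#' @param lower_pct,upper_pct Percentiles in \[0, 50) removed from each tail,
#'   per band. Defaults 20 and 20.
#' @param enabled Logical; a disabled policy is a no-op in [trim_percentiles()].
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(lower_pct = 20, upper_pct = 20, enabled = TRUE) {
  if (lower_pct < 0 || lower_pct >= 50 || upper_pct < 0 || upper_pct >= 50)
    stop("trim percentiles must lie in [0, 50)")
  structure(list(lower_pct = lower_pct, upper_pct = upper_pct,
                 enabled = enabled),
            class = "trim_policy")
}

#' Trim per-band outlier pixels by percentile
#'
#' For each band, pixels whose value lies strictly below the `lower_pct`
#' percentile or strictly above the `100 - upper_pct` percentile of that
#' band's in-scope valid values are flagged. A pixel flagged in ANY band is
#' marked invalid overall (the per-pixel phasor needs the full spectrum, so a
#' partially trimmed spectrum is unusable). Surviving spectra are returned
#' bit-identical; only the validity mask changes. Percentiles use linear
#' interpolation between order statistics, and exclusion is by strict
#' inequality, so ties at the boundary survive.
#'
#' @param cube [spectral_cube], normally stage `"zscored"`.
#' @param policy A [trim_policy].
#' @param scope_mask [roi_mask] over which percentiles are computed and
#'   trimming applied.
#' @return The cube with an updated validity mask.
#' @export
trim_percentiles <- function(cube, policy = trim_policy(), scope_mask) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(policy, "trim_policy"),
            inherits(scope_mask, "roi_mask"))
  if (!policy$enabled || (policy$lower_pct == 0 && policy$upper_pct == 0))
    return(cube)
  sel <- scope_mask$mask & cube$valid
  keep <- cube$valid
  for (m in seq_len(cube$bands$n)) {
    band <- cube$pixels[, , m]
    v <- band[sel]
    qs <- stats::quantile(v, c(policy$lower_pct / 100,
                               1 - policy$upper_pct / 100),
                          names = FALSE, type = 7)
    drop <- sel & (band < qs[1] | band > qs[2])
    keep <- keep & !drop
  }
  if (sum(keep & scope_mask$mask) < 2L)
    stop("percentile trimming left fewer than 2 valid in-scope pixels")
  spectral_cube(cube$pixels, cube$bands, stage = cube$stage, valid = keep)
}

#' Extract the RGB-like 3-band sub-cube
#'
#' Simulates a conventional color fundus camera by keeping only the bands
#' centered at 471 (blue), 595 (green) and 732 nm (red), in ascending
#' wavelength order. The validity mask is carried over.
#'
#' @param cube A [spectral_cube] whose band set contains 471, 595 and 732 nm.
#' @param centers_nm The three band centers to extract.
#' @return A 3-band [spectral_cube] at the same stage.
#' @export
extract_rgb_like <- function(cube, centers_nm = c(471, 595, 732)) {
  stopifnot(inherits(cube, "spectral_cube"))
  centers_nm <- sort(centers_nm)
  idx <- match(centers_nm, cube$bands$centers_nm)
  if (anyNA(idx))
    stop("cube lacks required band(s): ",
         paste(centers_nm[is.na(idx)], collapse = ", "), " nm")
  bands <- band_set(cube$bands$centers_nm[idx], cube$bands$bandwidths_nm[idx])
  spectral_cube(cube$pixels[, , idx, drop = FALSE], bands,
                stage = cube$stage, valid = cube$valid)
}

#' Restrict a cube to an ROI as a pixel set
#'
#' Returns the spectra and coordinates of exactly those pixels that are both
#' inside the ROI and valid in the cube.
#'
#' @param cube A [spectral_cube].
#' @param roi An [roi_mask] of matching shape.
#' @return A list with `spectra` (n_pixels x n matrix), `rows`, `cols`
#'   (0-based pixel coordinates) and `n_pixels`.
#' @export
apply_roi <- function(cube, roi) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(roi, "roi_mask"))
  d <- dim(cube$pixels)
  if (!all(dim(roi$mask) == d[1:2]))
    stop("ROI mask shape does not match the cube")
  sel <- roi$mask & cube$valid
  if (!any(sel))
    stop(sprintf("no valid pixels inside ROI '%s'", roi$region))
  idx <- which(sel)
  npix <- prod(d[1:2])
  spectra <- matrix(cube$pixels, nrow = npix)[idx, , drop = FALSE]
  list(spectra = spectra,
       rows = (idx - 1L) %% d[1],
       cols = (idx - 1L) %/% d[1],
       n_pixels = length(idx))
}
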