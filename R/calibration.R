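#' Reference image set for reflectance calibration
#'
#' Bundles the white-reference cube, the dark-current cube and the calibrated
#' reflectance of the white target (per band, as provided by the target's
#' manufacturer). Both cubes must share the band set and image size of the
#' cubes they will calibrate.
#'
#' @param white [spectral_cube] of the reference white target, stage
#'   `"raw_dl"`.
#' @param dark [spectral_cube] of the dark current (no illumination), stage
#'   `"raw_dl"`.
#' @param refl_ref Per-band calibrated white reflectance, each in (0, 1];
#'   a single value is recycled across bands.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(white, dark, refl_ref = 0.95) {
  stopifnot(inherits(white, "spectral_cube"), inherits(dark, "spectral_cube"))
  if (!band_sets_equal(white$bands, dark$bands))
    stop("white and dark references have different band sets")
  if (!all(dim(white$pixels) == dim(dark$pixels)))
    stop("white and dark references have different shapes")
  n <- white$bands$n
  if (length(refl_ref) == 1L) refl_ref <- rep(refl_ref, n)
  if (length(refl_ref) != n)
    stop("refl_ref must have one value per band")
  if (any(refl_ref <= 0 | refl_ref > 1))
    stop("refl_ref values must lie in (0, 1]")
  structure(list(white = white, dark = dark, refl_ref = refl_ref),
            class = "reference_set")
}

#' Convert raw digital levels to spectral reflectance
#'
#' Per pixel (i, j) and band, reflectance is
#' \deqn{R = \frac{DL - DL^{dark}}{DL^{white} - DL^{dark}} \cdot R^{ref}}
#' using the white-reference and dark-current images and the calibrated
#' white reflectance. Values are deliberately not clipped to \[0, 1\]:
#' noise can push them slightly outside and downstream Z-scoring makes
#' clipping both unnecessary and distorting. Pixels where any band's
#' white-minus-dark difference falls below `eps` digital levels are marked
#' invalid in the output mask.
#'
#' @param raw [spectral_cube] with stage `"raw_dl"`.
#' @param refs A [reference_set] matching `raw` in bands and shape.
#' @param eps Denominator guard in digital levels; default 1 DL (below the
#'   sensor noise floor the ratio is meaningless). Must be positive.
#' @return A [spectral_cube] with stage `"reflectance"`.
#' @export
compute_reflectance <- function(raw, refs, eps = 1.0) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(refs, "reference_set"))
  if (raw$stage != "raw_dl") stop("input cube must be at stage raw_dl")
  if (!band_sets_equal(raw$bands, refs$white$bands))
    stop("cube and reference band sets differ")
  if (!all(dim(raw$pixels) == dim(refs$white$pixels)))
    stop("cube and reference shapes differ")
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  denom <- refs$white$pixels - refs$dark$pixels
  num <- raw$pixels - refs$dark$pixels
  bad <- denom < eps
  denom[bad] <- 1  # placeholder; flagged invalid below
  refl <- num / denom
  n <- raw$bands$n
  for (m in seq_len(n)) refl[, , m] <- refl[, , m] * refs$refl_ref[m]
  valid <- raw$valid & !apply(bad, c(1, 2), any)
  spectral_cube(refl, raw$bands, stage = "reflectance", valid = valid)
}
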