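#' Multispectral image cube
#'
#' A `spectral_cube` holds an H x W x n array of per-pixel band values
#' together with its [band_set], a processing `stage` marker and an H x W
#' logical validity mask. Pixels flagged invalid (e.g. by percentile
#' trimming or a degenerate calibration denominator) are excluded from all
#' downstream statistics; their stored spectra are never altered.
#'
#' @param pixels Numeric H x W x n array. Digital levels (`stage = "raw_dl"`)
#'   must be nonnegative; reflectance and Z-scored values may be any real.
#' @param bands A [band_set] whose channel count matches `dim(pixels)[3]`.
#' @param stage One of `"raw_dl"`, `"reflectance"`, `"zscored"`.
#' @param valid Optional H x W logical validity mask; defaults to all `TRUE`.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(pixels, bands,
                          stage = c("raw_dl", "reflectance", "zscored"),
                          valid = NULL) {
  stage <- match.arg(stage)
  if (!inherits(bands, "band_set")) stop("bands must be a band_set")
  pixels <- as.array(pixels)
  d <- dim(pixels)
  if (length(d) != 3L)
    stop("pixels must be a 3-d array (H x W x n)")
  if (d[3] != bands$n)
    stop(sprintf("cube has %d pages but band_set has %d channels",
                 d[3], bands$n))
  if (stage == "raw_dl" && any(pixels < 0, na.rm = TRUE))
    stop("raw digital levels must be nonnegative")
  if (is.null(valid)) {
    valid <- matrix(TRUE, d[1], d[2])
  } else {
    valid <- as.matrix(valid)
    if (!is.logical(valid)) storage.mode(valid) <- "logical"
    if (!all(dim(valid) == d[1:2]))
      stop("valid mask must be H x W")
  }
  structure(
    list(pixels = pixels, bands = bands, stage = stage, valid = valid),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("spectral_cube: %dx%d pixels, %s, stage=%s, %d/%d valid\n",
              d[1], d[2], format(x$bands), x$stage,
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$pixels)

#' Region-of-interest mask
#'
#' Wraps an H x W logical mask with its anatomical region label. The regions
#' follow the fundus anatomy used throughout the pipeline: the entire retina,
#' the vessels, the optic disk, the macula, and the remaining background.
#'
#' @param mask H x W logical (or coercible) matrix; `TRUE`/nonzero = inside.
#' @param region One of `"entire_retina"`, `"vessels"`, `"optic_disk"`,
#'   `"macula"`, `"background"`.
#' @return An object of class `roi_mask` with an `empty` flag set when the
#'   mask contains no pixels.
#' @export
roi_mask <- function(mask, region = c("entire_retina", "vessels",
                                      "optic_disk", "macula", "background")) {
  region <- match.arg(region)
  mask <- as.matrix(mask)
  if (!is.logical(mask)) mask <- mask != 0
  empty <- !any(mask)
  if (empty)
    warning(sprintf("ROI mask for region '%s' is empty", region))
  structure(list(region = region, mask = mask, empty = empty),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %s, %d pixels%s\n", x$region, sum(x$mask),
              if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

roi_regions <- function() {
  c("entire_retina", "vessels", "optic_disk", "macula", "background")
}
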