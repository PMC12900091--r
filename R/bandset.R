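#' Spectral band metadata
#'
#' A `band_set` records the peak wavelength and bandwidth of each channel of a
#' multispectral cube, in ascending wavelength order.
#'
#' @param centers_nm Numeric vector of peak wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param bandwidths_nm Numeric vector of per-channel bandwidths in nm, all
#'   positive; recycled if a single value is given.
#' @return An object of class `band_set` with fields `centers_nm`,
#'   `bandwidths_nm` and `n` (channel count).
#' @examples
#' bs <- band_set(c(471, 595, 732))
#' bs$n
#' @export
band_set <- function(centers_nm, bandwidths_nm = 10) {
  centers_nm <- as.numeric(centers_nm)
  if (length(centers_nm) < 2L)
    stop("a band_set needs at least 2 channels")
  if (any(diff(centers_nm) <= 0))
    stop("band centers must be strictly increasing in wavelength")
  if (length(bandwidths_nm) == 1L)
    bandwidths_nm <- rep(as.numeric(bandwidths_nm), length(centers_nm))
  bandwidths_nm <- as.numeric(bandwidths_nm)
  if (length(bandwidths_nm) != length(centers_nm))
    stop("bandwidths_nm must match centers_nm in length")
  if (any(bandwidths_nm <= 0))
    stop("all bandwidths must be positive")
  structure(
    list(centers_nm = centers_nm, bandwidths_nm = bandwidths_nm,
         n = length(centers_nm)),
    class = "band_set"
  )
}

#' Default 12-band fundus camera band set
#'
#' The 12 visible/NIR LED peak wavelengths of the area-scanning multispectral
#' fundus camera the pipeline was designed around: 416, 450, 471, 494, 524,
#' 595, 598, 624, 660, 732, 865 and 955 nm.
#'
#' @return A [band_set] with 12 channels.
#' @export
default_band_set <- function() {
  band_set(c(416, 450, 471, 494, 524, 595, 598, 624, 660, 732, 865, 955))
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("band_set: %d channels, %g-%g nm\n",
              x$n, min(x$centers_nm), max(x$centers_nm)))
  invisible(x)
}

#' @export
format.band_set <- function(x, ...) {
  paste0(x$n, " bands [", paste(x$centers_nm, collapse = ", "), "] nm")
}

band_sets_equal <- function(a, b) {
  isTRUE(all.equal(a$centers_nm, b$centers_nm)) &&
    isTRUE(all.equal(a$bandwidths_nm, b$bandwidths_nm))
}
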