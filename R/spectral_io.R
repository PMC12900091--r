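# On-disk formats: cubes are multi-page TIFF (one page per band, ascending
# wavelength) plus a JSON sidecar carrying the band_set, the stage, and the
# scale/offset used to map values into the TIFF's [0,1] sample range.
# raw_dl cubes use 16-bit pages (bit-exact for a 16-bit camera); float stages
# use 32-bit pages (quantization <= value range * 2^-32). Masks are 8-bit
# single-channel PNG, 0 = outside.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a spectral cube to disk
#'
#' Writes a multi-page TIFF (one page per band) and a JSON metadata sidecar
#' at `<path>.json` holding the band centers, bandwidths, stage and the
#' scale/offset encoding of the pixel values.
#'
#' @param cube A [spectral_cube].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  n <- cube$bands$n
  if (cube$stage == "raw_dl") {
    bits <- 16L
    offset <- 0
    scale <- 65535
    if (any(cube$pixels > 65535))
      stop("raw digital levels exceed the 16-bit range")
  } else {
    bits <- 32L
    lo <- min(cube$pixels)
    hi <- max(cube$pixels)
    offset <- lo
    scale <- if (hi > lo) hi - lo else 1
  }
  pages <- lapply(seq_len(n), function(m) {
    (cube$pixels[, , m] - offset) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  meta <- list(
    centers_nm = cube$bands$centers_nm,
    bandwidths_nm = cube$bands$bandwidths_nm,
    stage = cube$stage,
    offset = offset,
    scale = scale,
    bits = bits
  )
  jsonlite::write_json(meta, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral cube from disk
#'
#' Reads a multi-page TIFF written by [write_cube()] (or any band-per-page
#' stack) together with its JSON metadata sidecar. Pages must be in ascending
#' wavelength order and their count must equal the sidecar's channel count.
#'
#' @param path TIFF path.
#' @param metadata_path JSON sidecar path; defaults to `<path>.json`.
#' @return A [spectral_cube] with an all-`TRUE` validity mask.
#' @export
read_cube <- function(path, metadata_path = sidecar_path(path)) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  if (!file.exists(metadata_path))
    stop("cube metadata sidecar not found: ", metadata_path)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  if (is.null(meta$centers_nm))
    stop("metadata error: sidecar lacks centers_nm")
  if (any(diff(meta$centers_nm) <= 0))
    stop("metadata error: band centers are not strictly increasing")
  bands <- band_set(meta$centers_nm,
                    if (is.null(meta$bandwidths_nm)) 10 else meta$bandwidths_nm)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != bands$n)
    stop(sprintf("format error: %d TIFF pages but %d band centers",
                 length(pages), bands$n))
  offset <- if (is.null(meta$offset)) 0 else meta$offset
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  stage <- if (is.null(meta$stage)) "raw_dl" else meta$stage
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  px <- array(0, dim = c(h, w, bands$n))
  for (m in seq_len(bands$n)) px[, , m] <- pages[[m]] * scale + offset
  if (stage == "raw_dl") px <- round(px)
  spectral_cube(px, bands, stage = stage)
}

#' Write an ROI mask as a single-channel PNG
#'
#' @param roi An [roi_mask].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  png::writePNG(ifelse(roi$mask, 1, 0), path)
  invisible(path)
}

#' Read an ROI mask from a single-channel image
#'
#' Any nonzero pixel is inside the region. An all-zero image yields a usable
#' but empty mask (with a warning and the `empty` flag set).
#'
#' @param path PNG path.
#' @param region Anatomical region label, see [roi_mask()].
#' @return An [roi_mask].
#' @export
read_mask <- function(path, region = "entire_retina") {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  roi_mask(img > 0, region = region)
}

#' Write a per-case feature table as CSV
#'
#' @param table Data frame with columns `case_id`, `label` and one numeric
#'   column per feature. Case ids must be unique; features must be finite.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- as.data.frame(table)
  if (nrow(table) < 1L) stop("feature table must contain at least one case")
  if (!all(c("case_id", "label") %in% names(table)))
    stop("feature table needs case_id and label columns")
  if (anyDuplicated(table$case_id))
    stop("duplicate case_id in feature table")
  feat <- setdiff(names(table), c("case_id", "label"))
  if (length(feat) && !all(vapply(table[feat],
                                  function(x) all(is.finite(x)), logical(1))))
    stop("feature table contains non-finite feature values")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Data frame with `case_id`, `label` and numeric feature columns.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$case_id <- as.character(tab$case_id)
  tab
}

#' Write a dataset manifest as JSON
#'
#' The manifest lists every case with its label, cube path, per-region mask
#' paths, shared reference image paths, and (for synthetic diseased cases)
#' the spatial extent of the disease effect.
#'
#' @param manifest A list as produced by [generate_dataset()] with
#'   `out_dir` set.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  ids <- vapply(manifest$cases, `[[`, character(1), "case_id")
  if (anyDuplicated(ids)) stop("duplicate case_id in manifest")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset manifest, checking that referenced files exist
#'
#' @param path JSON manifest path.
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  for (cs in man$cases) {
    for (p in c(cs$cube, unlist(cs$masks))) {
      fp <- file.path(base, p)
      if (!file.exists(fp)) stop("manifest references missing file: ", fp)
    }
  }
  man
}
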