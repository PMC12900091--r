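#' Per-case feature extraction pipeline
#'
#' Runs one case through the full preprocessing chain and returns its feature
#' vector. The fixed pipeline order is: reflectance calibration, optional
#' RGB-like band extraction, optional band-wise Z-score over the entire
#' retina, percentile trimming over the entire retina, then restriction to
#' the requested ROI. Z-score statistics and trim thresholds are always
#' computed over the entire-retina scope so that small ROIs neither erase
#' inter-region contrast nor destabilize the per-band standard deviation.
#'
#' @param cube Raw-digital-level [spectral_cube] of the case.
#' @param refs The dataset's [reference_set].
#' @param masks Named list of [roi_mask] including `entire_retina`.
#' @param representation One of `"phasor_msi"`, `"phasor_rgb"`, `"avg_msi"`,
#'   `"avg_rgb"`.
#' @param harmonic Phasor harmonic k (ignored for the averaging baselines).
#' @param normalize `"zscore"` or `"none"`.
#' @param trim A [trim_policy]; trimming is applied only when Z-scoring is
#'   (outlier trimming is part of the normalization step).
#' @param roi ROI name (a key of `masks`); default `"entire_retina"`.
#' @param include_std Append the scalar phasor dispersion STD as a third
#'   feature (phasor representations only).
#' @param denom_quantile Adaptive denominator guard for [phasor_transform()]
#'   on Z-scored input: only pixels whose |band sum| exceeds this quantile of
#'   the valid pixels' |band sums| contribute to the phasor average (default
#'   0.5, i.e. the upper half). Z-scored spectra sum to near zero for
#'   unremarkable pixels, whose phasor phase is therefore pure noise.
#'   Ignored for unnormalized input, where band sums are bounded away from
#'   zero.
#' @return Named numeric feature vector.
#' @export
case_features <- function(cube, refs, masks,
                          representation = c("phasor_msi", "phasor_rgb",
                                             "avg_msi", "avg_rgb"),
                          harmonic = 1L,
                          normalize = c("zscore", "none"),
                          trim = trim_policy(),
                          roi = "entire_retina",
                          include_std = FALSE,
                          denom_quantile = 0.5) {
  representation <- match.arg(representation)
  normalize <- match.arg(normalize)
  if (!roi %in% names(masks)) stop("unknown ROI: ", roi)
  retina <- masks$entire_retina
  refl <- compute_reflectance(cube, refs)
  if (representation %in% c("phasor_rgb", "avg_rgb"))
    refl <- extract_rgb_like(refl)
  work <- refl
  scope <- masks[[roi]]
  if (normalize == "zscore") {
    # Z-score statistics are always global (entire retina), preserving
    # inter-region contrast; outlier trimming is local to the analysis ROI
    # (global trimming would excise small distinctive regions wholesale).
    work <- zscore_bands(work, retina)
    work <- trim_percentiles(work, trim, scope)
  }
  # the retina is the analysis domain; pixels outside it never contribute
  work$valid <- work$valid & retina$mask
  if (representation %in% c("avg_msi", "avg_rgb"))
    return(band_average_features(work, scope))
  # phasor path: the ROI is the analysis domain, so the adaptive denominator
  # guard is computed over the ROI's own pixels
  work$valid <- work$valid & scope$mask
  field <- phasor_transform(
    work, k = harmonic,
    min_denom_quantile = if (normalize == "zscore") denom_quantile else NULL)
  sm <- summarize_phasor(field, scope)
  out <- c(g_avg = sm$g_avg, s_avg = sm$s_avg)
  if (include_std) out <- c(out, std = sm$std)
  out
}

#' Build a per-case feature table from a dataset
#'
#' Applies [case_features()] to every case of an in-memory dataset (from
#' [generate_dataset()]) or a loaded manifest directory, producing the
#' feature table consumed by [evaluate()] and [manova_wilks()].
#'
#' @param dataset In-memory dataset list (`cases`, `refs`) or a manifest as
#'   returned by [read_manifest()] plus `dir`.
#' @param ... Passed to [case_features()].
#' @param cases Optional subset of case ids to include.
#' @return Data frame with `case_id`, `label` and one column per feature.
#' @export
build_feature_table <- function(dataset, ..., cases = NULL) {
  rows <- lapply(dataset$cases, function(cs) {
    if (!is.null(cases) && !cs$case_id %in% cases) return(NULL)
    f <- case_features(cs$cube, dataset$refs, cs$masks, ...)
    cbind(data.frame(case_id = cs$case_id, label = cs$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load a written synthetic dataset back into memory
#'
#' @param dir Directory containing `manifest.json` and the files it lists.
#' @return Dataset list in the same shape as [generate_dataset()] returns
#'   in-memory.
#' @export
load_dataset <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.json"))
  refl_ref <- unlist(man$refl_ref)
  white <- read_cube(file.path(dir, man$cases[[1]]$references$white))
  dark <- read_cube(file.path(dir, man$cases[[1]]$references$dark))
  refs <- reference_set(white, dark, refl_ref)
  cases <- lapply(man$cases, function(cs) {
    masks <- lapply(stats::setNames(names(cs$masks), names(cs$masks)),
                    function(rg) read_mask(file.path(dir, cs$masks[[rg]]), rg))
    list(case_id = cs$case_id, label = cs$label,
         extent = if (is.null(cs$extent)) NA_character_ else cs$extent,
         cube = read_cube(file.path(dir, cs$cube)), masks = masks)
  })
  list(cases = cases, refs = refs)
}
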