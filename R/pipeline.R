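#' Retain the cases relevant to a region
#'
#' For region-based analysis, diseased cases whose disease extent does not
#' intersect the region are excluded (a macula-confined disease says nothing
#' about the optic disk), while all healthy cases are always retained. A
#' whole-retina extent intersects every region, and the entire-retina region
#' intersects every extent.
#'
#' @param dataset Dataset list whose cases carry `extent` metadata.
#' @param region One of the ROI names, see [roi_mask()].
#' @return Character vector of retained case ids.
#' @export
roi_case_filter <- function(dataset, region) {
  if (!region %in% roi_regions()) stop("unknown region: ", region)
  extent_region <- c(macula_only = "macula", disk_only = "optic_disk",
                     vessels_only = "vessels", whole_retina = "whole_retina")
  keep <- vapply(dataset$cases, function(cs) {
    if (cs$label == "healthy") return(TRUE)
    ext <- cs$extent
    if (is.null(ext) || is.na(ext))
      stop("diseased case ", cs$case_id, " lacks extent metadata")
    ext == "whole_retina" || region == "entire_retina" ||
      extent_region[[ext]] == region
  }, logical(1))
  vapply(dataset$cases[keep], `[[`, character(1), "case_id")
}

report_row <- function(analysis, report) {
  cbind(data.frame(analysis = analysis, stringsAsFactors = FALSE),
        as.data.frame(as.list(report$mean)))
}

drop_std <- function(tab) tab[setdiff(names(tab), "std")]

#' Run the full experiment suite on one dataset
#'
#' Computes, on a synthetic or loaded dataset, the six comparison tables the
#' pipeline is built around: (1) the four classifiers on unnormalized
#' first-harmonic phasor features; (2) harmonic comparison with the nu-SVC;
#' (3) MANOVA per harmonic on (g_avg, s_avg); (4) the normalization/STD
#' ablation (reflectance vs Z-score, with and without the phasor STD);
#' (5) the representation comparison Avg-RGB / Avg-MSI / Phasor-RGB /
#' Phasor-MSI on Z-scored data; (6) its MANOVA counterpart; and (7) the ROI
#' comparison on Z-scored Phasor-MSI features with region-relevant case
#' subsets. One seeded split list is shared by every classification
#' experiment on the full case set; reduced ROI case sets reuse the same
#' protocol seed.
#'
#' @param config A [synthetic_config]; used when `dataset` is not supplied.
#' @param dataset Optional pre-generated dataset (see [generate_dataset()]).
#' @param protocol A [split_protocol].
#' @param harmonics Harmonics for the harmonic comparison; default 1:4.
#' @param trim A [trim_policy] applied with Z-score normalization.
#' @param out_dir Optional directory; when set, every table is written as CSV
#'   together with a small JSON run manifest (seed, case counts, package
#'   version).
#' @return Named list of data frames: `classifier_comparison`,
#'   `harmonic_comparison`, `harmonic_manova`, `normalization_ablation`,
#'   `representation_comparison`, `representation_manova`, `roi_comparison`.
#' @export
run_experiment <- function(config = synthetic_config(), dataset = NULL,
                           protocol = split_protocol(), harmonics = 1:4,
                           trim = trim_policy(), out_dir = NULL) {
  if (is.null(dataset)) dataset <- generate_dataset(config)
  n_cases <- length(dataset$cases)
  splits <- make_splits(n_cases, protocol)

  ft <- function(...) build_feature_table(dataset, ...)
  # feature tables reused across experiments
  phasor_r <- lapply(harmonics, function(k)
    ft("phasor_msi", harmonic = k, normalize = "none", include_std = TRUE))
  names(phasor_r) <- paste0("h", harmonics)
  phasor_z <- ft("phasor_msi", harmonic = 1, normalize = "zscore",
                 trim = trim, include_std = TRUE)
  phasor_z_rgb <- ft("phasor_rgb", harmonic = 1, normalize = "zscore",
                     trim = trim)
  avg_msi <- ft("avg_msi", normalize = "zscore", trim = trim)
  avg_rgb <- ft("avg_rgb", normalize = "zscore", trim = trim)

  classifier_comparison <- do.call(rbind, lapply(
    c("nc", "gnb", "svm", "nusvc"), function(cl)
      report_row(toupper(cl), evaluate(drop_std(phasor_r$h1), splits, cl))))

  harmonic_comparison <- do.call(rbind, lapply(seq_along(harmonics),
    function(i) report_row(paste0("k=", harmonics[i]),
                           evaluate(drop_std(phasor_r[[i]]), splits, "nusvc"))))

  harmonic_manova <- manova_suite(
    stats::setNames(lapply(phasor_r, drop_std), paste0("k=", harmonics)))

  normalization_ablation <- rbind(
    report_row("R-AVG", evaluate(drop_std(phasor_r$h1), splits, "nusvc")),
    report_row("Z-AVG", evaluate(drop_std(phasor_z), splits, "nusvc")),
    report_row("R-AVG+STD", evaluate(phasor_r$h1, splits, "nusvc")),
    report_row("Z-AVG+STD", evaluate(phasor_z, splits, "nusvc")))

  rep_tables <- list("Avg-RGB" = avg_rgb, "Avg-MSI" = avg_msi,
                     "Phasor-RGB" = phasor_z_rgb,
                     "Phasor-MSI" = drop_std(phasor_z))
  representation_comparison <- do.call(rbind, lapply(names(rep_tables),
    function(nm) report_row(nm, evaluate(rep_tables[[nm]], splits, "nusvc"))))

  representation_manova <- manova_suite(rep_tables)

  roi_comparison <- do.call(rbind, lapply(
    c("entire_retina", "macula", "vessels", "optic_disk", "background"),
    function(rg) {
      ids <- roi_case_filter(dataset, rg)
      tab <- ft("phasor_msi", harmonic = 1, normalize = "zscore",
                trim = trim, roi = rg, cases = ids)
      sp <- if (nrow(tab) == n_cases) splits else make_splits(nrow(tab), protocol)
      row <- report_row(rg, evaluate(tab, sp, "nusvc"))
      cbind(row[1], n_diseased = sum(tab$label == "diseased"), row[-1])
    }))

  tables <- list(classifier_comparison = classifier_comparison,
                 harmonic_comparison = harmonic_comparison,
                 harmonic_manova = harmonic_manova,
                 normalization_ablation = normalization_ablation,
                 representation_comparison = representation_comparison,
                 representation_manova = representation_manova,
                 roi_comparison = roi_comparison)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = protocol$seed, n_cases = n_cases,
           n_reps = protocol$n_reps, harmonics = harmonics,
           package_version = as.character(utils::packageVersion("retphasor"))),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  }
  tables
}
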