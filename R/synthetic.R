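# Synthetic multispectral fundus data: circular retina field with an optic
# disk (bright ellipse), macula (darker disk), branching vessel network, and
# background; smooth tissue reflectance spectra; disease modeled as focal
# drusen-like lesions (random bright blobs with a band-limited spectral
# profile peaked in the 494-624 nm range) inside a configurable extent; a
# per-pixel multiplicative lognormal illumination field plus additive
# Gaussian sensor noise; and the exact digital-level forward model that
# reflectance calibration inverts.

#' Configuration for the synthetic fundus dataset generator
#'
#' Defaults emulate the study conditions the pipeline was designed for:
#' 73 healthy and 60 diseased retinas imaged in the 12 standard bands, with
#' a whole-retina disease extent. Image size defaults to 64 x 64 pixels, a
#' computationally convenient downscale that preserves the anatomy/lesion
#' geometry the analysis exercises.
#'
#' @param n_healthy,n_diseased Case counts; defaults 73 and 60.
#' @param image_size `c(H, W)` in pixels.
#' @param bands A [band_set]; default [default_band_set()].
#' @param base_spectrum_params Named list of per-tissue spectral curve
#'   parameters; see [tissue_spectrum()].
#' @param disease_effect List with `magnitude` (peak added reflectance of a
#'   lesion, >= 0; 0 means healthy and diseased are identically distributed),
#'   `extent` (one of `"whole_retina"`, `"macula_only"`, `"disk_only"`,
#'   `"vessels_only"`), `profile_center_nm`/`profile_width_nm` (Gaussian
#'   spectral profile of the lesion contrast) or an explicit per-band
#'   `delta_spectrum`, plus lesion geometry (`n_lesions_mean`,
#'   `lesion_radius_px` range) and `diffuse_fraction` (relative amplitude of
#'   the smooth, widespread disease component that accompanies the focal
#'   lesions, as in advanced disease affecting the whole fundus).
#' @param noise List with `multiplicative_sd` (lognormal sd of the per-pixel
#'   illumination field, shared across bands), `additive_sd` (Gaussian sd on
#'   digital levels, per pixel per band), and `band_illum_sd` (amplitude of
#'   the smooth per-band illumination nonuniformity field; each band is lit
#'   by its own LED, so each acquisition carries band-independent smooth
#'   illumination structure that flat-reference calibration cannot remove).
#' @param subject_variability List with `pigmentation_sd` (lognormal sd of
#'   per-case tissue brightness/melanin-slope factors) and `dip_sd` (Gaussian
#'   sd of per-case absorption dip depths); models inter-subject anatomical
#'   and pigmentation differences and applies identically to both classes.
#' @param white_level,dark_level Per-band reference digital levels (recycled
#'   from scalars); white must exceed dark in every band.
#' @param refl_ref Per-band calibrated white reflectance in (0, 1].
#' @param seed Integer master seed; each case derives its own stream.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_healthy = 73,
                             n_diseased = 60,
                             image_size = c(64, 64),
                             bands = default_band_set(),
                             base_spectrum_params = default_spectrum_params(),
                             disease_effect = list(),
                             noise = list(multiplicative_sd = 0.05,
                                          additive_sd = 30,
                                          band_illum_sd = 0.10),
                             subject_variability = list(pigmentation_sd = 0.08,
                                                        dip_sd = 0.05),
                             white_level = 48000,
                             dark_level = 400,
                             refl_ref = 0.95,
                             seed = 1L) {
  eff <- utils::modifyList(
    list(magnitude = 0.3,
         extent = "whole_retina",
         profile_center_nm = 560,
         profile_width_nm = 60,
         delta_spectrum = NULL,
         n_lesions_mean = 20,
         lesion_radius_px = c(2, 5),
         diffuse_fraction = 0.5),
    disease_effect)
  if (eff$magnitude < 0) stop("disease magnitude must be >= 0")
  if (!eff$extent %in% c("whole_retina", "macula_only", "disk_only",
                         "vessels_only"))
    stop("unknown disease extent: ", eff$extent)
  noise <- utils::modifyList(list(multiplicative_sd = 0.05, additive_sd = 30,
                                  band_illum_sd = 0.10),
                             noise)
  if (noise$multiplicative_sd < 0 || noise$additive_sd < 0 ||
      noise$band_illum_sd < 0)
    stop("noise sds must be >= 0")
  subject_variability <- utils::modifyList(
    list(pigmentation_sd = 0.08, dip_sd = 0.05), subject_variability)
  n <- bands$n
  if (length(white_level) == 1L) white_level <- rep(white_level, n)
  if (length(dark_level) == 1L) dark_level <- rep(dark_level, n)
  if (length(refl_ref) == 1L) refl_ref <- rep(refl_ref, n)
  if (any(white_level <= dark_level))
    stop("white_level must exceed dark_level in every band")
  structure(list(
    n_healthy = n_healthy, n_diseased = n_diseased,
    image_size = image_size, bands = bands,
    base_spectrum_params = base_spectrum_params,
    disease_effect = eff, noise = noise,
    subject_variability = subject_variability,
    white_level = white_level, dark_level = dark_level,
    refl_ref = refl_ref, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default tissue spectral curve parameters
#'
#' Each tissue reflectance is a smooth curve on (0, 1]: a monotone
#' melanin-like sigmoid rise toward the red/NIR, times Gaussian absorption
#' dips (hemoglobin near 555 nm for vessels, macular pigment near 460 nm),
#' plus an overall brightness factor. The optic disk is the brightest tissue
#' at every band; vessels are darker than background in the 500-600 nm
#' region.
#'
#' @return Named list of per-class parameter lists.
#' @export
default_spectrum_params <- function() {
  list(
    background = list(base = 0.06, amp = 0.50, knee_nm = 600, slope_nm = 80,
                      dip_depth = 0, dip_center_nm = 555, dip_width_nm = 45,
                      brightness = 1.0),
    vessel     = list(base = 0.06, amp = 0.50, knee_nm = 600, slope_nm = 80,
                      dip_depth = 0.55, dip_center_nm = 555, dip_width_nm = 45,
                      brightness = 0.85),
    optic_disk = list(base = 0.35, amp = 0.55, knee_nm = 500, slope_nm = 120,
                      dip_depth = 0, dip_center_nm = 555, dip_width_nm = 45,
                      brightness = 1.0),
    macula     = list(base = 0.06, amp = 0.50, knee_nm = 600, slope_nm = 80,
                      dip_depth = 0.50, dip_center_nm = 460, dip_width_nm = 50,
                      brightness = 0.80)
  )
}

#' Smooth tissue reflectance spectrum
#'
#' Evaluates the parametric reflectance curve of one tissue class at the band
#' centers: `brightness * (base + amp * sigmoid((lambda - knee)/slope)) *
#' (1 - dip_depth * exp(-((lambda - dip_center)/dip_width)^2))`.
#'
#' @param tissue_class One of `"background"`, `"vessel"`, `"optic_disk"`,
#'   `"macula"`.
#' @param bands A [band_set].
#' @param params Parameter list as in [default_spectrum_params()].
#' @return Per-band reflectance vector, all values in (0, 1].
#' @export
tissue_spectrum <- function(tissue_class, bands = default_band_set(),
                            params = default_spectrum_params()) {
  p <- params[[tissue_class]]
  if (is.null(p)) stop("unknown tissue class: ", tissue_class)
  lam <- bands$centers_nm
  rise <- p$base + p$amp / (1 + exp(-(lam - p$knee_nm) / p$slope_nm))
  dip <- 1 - p$dip_depth * exp(-((lam - p$dip_center_nm) / p$dip_width_nm)^2)
  r <- p$brightness * rise * dip
  if (any(r <= 0) || any(r > 1))
    stop("spectrum parameters yield reflectance outside (0, 1] for ",
         tissue_class)
  r
}

disease_profile <- function(config) {
  eff <- config$disease_effect
  if (!is.null(eff$delta_spectrum)) {
    prof <- eff$delta_spectrum
    if (length(prof) != config$bands$n)
      stop("delta_spectrum length must equal the number of bands")
    return(prof)
  }
  lam <- config$bands$centers_nm
  exp(-((lam - eff$profile_center_nm) / eff$profile_width_nm)^2)
}

# --- geometry helpers -------------------------------------------------------

disk_mask <- function(h, w, cy, cx, ry, rx = ry) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

# Branching random-walk vessel network rooted at the optic disk center.
vessel_mask <- function(h, w, retina, cy0, cx0) {
  mask <- matrix(FALSE, h, w)
  stamp <- function(y, x, r) {
    ys <- max(1, floor(y - r)):min(h, ceiling(y + r))
    xs <- max(1, floor(x - r)):min(w, ceiling(x + r))
    for (yi in ys) for (xi in xs)
      if ((yi - y)^2 + (xi - x)^2 <= r^2) mask[yi, xi] <<- TRUE
  }
  n_roots <- sample(5:7, 1)  # vascular density varies between subjects
  wscale <- min(h, w) / 64   # keep vessel coverage proportionate to the field
  queue <- lapply(seq_len(n_roots), function(i) {
    list(y = cy0, x = cx0, ang = stats::runif(1, 0, 2 * pi),
         len = stats::runif(1, 0.9, 1.4) * min(h, w) / 2,
         width = max(0.6, stats::runif(1, 0.8, 1.8) * wscale), depth = 0L)
  })
  while (length(queue)) {
    b <- queue[[1]]; queue <- queue[-1]
    y <- b$y; x <- b$x; ang <- b$ang
    steps <- max(3L, round(b$len))
    for (st in seq_len(steps)) {
      y <- y + sin(ang); x <- x + cos(ang)
      ang <- ang + stats::rnorm(1, 0, 0.18)
      yi <- round(y); xi <- round(x)
      if (yi < 1 || yi > h || xi < 1 || xi > w || !retina[yi, xi]) break
      stamp(y, x, b$width)
      if (b$depth < 2L && stats::runif(1) < 0.03) {
        queue[[length(queue) + 1L]] <- list(
          y = y, x = x, ang = ang + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.9),
          len = b$len * 0.6, width = max(0.8, b$width * 0.8),
          depth = b$depth + 1L)
      }
    }
  }
  mask
}

blob_sum <- function(h, w, idx, n_blobs, radius_range, amp_range) {
  field <- matrix(0, h, w)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (b in seq_len(n_blobs)) {
    ctr <- idx[sample.int(length(idx), 1)]
    cy <- (ctr - 1L) %% h + 1L
    cx <- (ctr - 1L) %/% h + 1L
    r <- stats::runif(1, radius_range[1], radius_range[2])
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    field <- field + amp * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * r^2))
  }
  field
}

# Disease contrast field in [0, 1+diffuse]: focal drusen-like blobs plus a
# smooth low-amplitude widespread component.
lesion_field <- function(h, w, allowed, eff) {
  idx <- which(allowed)
  if (!length(idx)) return(matrix(0, h, w))
  n_blobs <- stats::rpois(1, eff$n_lesions_mean) + 3L
  focal <- pmin(blob_sum(h, w, idx, n_blobs, eff$lesion_radius_px,
                         c(0.7, 1)), 1)
  field <- focal
  if (eff$diffuse_fraction > 0) {
    broad <- pmin(blob_sum(h, w, idx, 6L,
                           c(0.12, 0.28) * min(h, w), c(0.5, 1)), 1)
    field <- pmin(focal + eff$diffuse_fraction * broad,
                  1 + eff$diffuse_fraction)
  }
  field * allowed
}

# Per-case inter-subject variation of the tissue spectral curves.
jitter_spectrum_params <- function(params, sv) {
  for (cl in names(params)) {
    p <- params[[cl]]
    p$brightness <- p$brightness * exp(stats::rnorm(1, 0, sv$pigmentation_sd))
    p$amp <- p$amp * exp(stats::rnorm(1, 0, sv$pigmentation_sd))
    # keep peak reflectance inside (0, 1]
    p$brightness <- min(p$brightness, 0.99 / (p$base + p$amp))
    if (p$dip_depth > 0)
      p$dip_depth <- min(0.9, max(0.05,
                                  p$dip_depth + stats::rnorm(1, 0, sv$dip_sd)))
    params[[cl]] <- p
  }
  params
}

case_geometry <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  r_ret <- 0.47 * min(h, w)
  cy <- h / 2; cx <- w / 2
  if (r_ret < 8) stop("image too small to place the optic disk and macula")
  retina <- disk_mask(h, w, cy, cx, r_ret)
  # optic disk: bright ellipse offset toward one side, mild jitter
  dy <- cy + stats::rnorm(1, 0, 1)
  dx <- cx + 0.55 * r_ret + stats::rnorm(1, 0, 1)
  dr <- 0.24 * r_ret * stats::runif(1, 0.9, 1.1)
  disk <- disk_mask(h, w, dy, dx, 1.15 * dr, dr) & retina
  # macula: darker disk on the opposite side
  my <- cy + stats::rnorm(1, 0, 1)
  mx <- cx - 0.35 * r_ret + stats::rnorm(1, 0, 1)
  mr <- 0.22 * r_ret * stats::runif(1, 0.9, 1.1)
  macula <- disk_mask(h, w, my, mx, mr) & retina & !disk
  vessels <- vessel_mask(h, w, retina, dy, dx) & retina
  if (!any(disk) || !any(macula))
    stop("image too small to place the optic disk and macula")
  # tissue assignment priority: vessels > disk > macula > background
  disk_roi <- disk & !vessels
  macula_roi <- macula & !vessels
  background <- retina & !vessels & !disk_roi & !macula_roi
  list(retina = retina, vessels = vessels, optic_disk = disk_roi,
       macula = macula_roi, background = background)
}

case_seed <- function(config, case_index) {
  (config$seed %% 65536L) * 32749L + 7919L * as.integer(case_index)
}

#' Generate one synthetic fundus case
#'
#' Builds the tissue geometry, composes the per-pixel reflectance field
#' (tissue spectrum, plus focal lesion contrast for diseased cases, times the
#' multiplicative illumination field), and maps it through the exact
#' digital-level forward model
#' `DL = dark + (white - dark) * R / refl_ref + sensor noise`,
#' which [compute_reflectance()] inverts. The random stream is fully
#' determined by `config$seed` and `case_index`.
#'
#' @param config A [synthetic_config].
#' @param label `"healthy"` or `"diseased"`.
#' @param case_index Integer index used to derive the case's random stream.
#' @return List with `cube` (raw_dl [spectral_cube]), `masks` (named list of
#'   [roi_mask]: entire_retina, vessels, optic_disk, macula, background),
#'   `label`, `extent` (diseased only, else `NA`), and `reflectance_field`
#'   (the injected noisy reflectance, for calibration round-trip checks).
#' @export
generate_case <- function(config, label = c("healthy", "diseased"),
                          case_index = 1L) {
  label <- match.arg(label)
  set.seed(case_seed(config, case_index))
  h <- config$image_size[1]; w <- config$image_size[2]
  n <- config$bands$n
  geo <- case_geometry(config)
  params <- jitter_spectrum_params(config$base_spectrum_params,
                                   config$subject_variability)
  spectra <- list(
    background = tissue_spectrum("background", config$bands, params),
    vessel = tissue_spectrum("vessel", config$bands, params),
    optic_disk = tissue_spectrum("optic_disk", config$bands, params),
    macula = tissue_spectrum("macula", config$bands, params)
  )
  refl <- array(0.02, dim = c(h, w, n))  # faint stray light outside the field
  for (m in seq_len(n)) {
    page <- refl[, , m]
    page[geo$background] <- spectra$background[m]
    page[geo$macula] <- spectra$macula[m]
    page[geo$optic_disk] <- spectra$optic_disk[m]
    page[geo$vessels] <- spectra$vessel[m]
    refl[, , m] <- page
  }
  extent <- NA_character_
  if (label == "diseased" && config$disease_effect$magnitude > 0) {
    eff <- config$disease_effect
    extent <- eff$extent
    allowed <- switch(eff$extent,
                      whole_retina = geo$retina,
                      macula_only = geo$macula,
                      disk_only = geo$optic_disk,
                      vessels_only = geo$vessels)
    lesions <- lesion_field(h, w, allowed, eff)
    prof <- disease_profile(config) * eff$magnitude
    for (m in seq_len(n)) refl[, , m] <- refl[, , m] + lesions * prof[m]
  } else if (label == "diseased") {
    extent <- config$disease_effect$extent
  }
  bsd <- config$noise$band_illum_sd
  if (bsd > 0) {
    yy <- matrix(seq_len(h) * 2 / h - 1, h, w)
    xx <- matrix(seq_len(w) * 2 / w - 1, h, w, byrow = TRUE)
    for (m in seq_len(n)) {
      gr <- stats::rnorm(2, 0, 0.7)
      by <- stats::runif(1, -1, 1); bx <- stats::runif(1, -1, 1)
      br <- stats::runif(1, 0.4, 0.9)
      field <- gr[1] * yy + gr[2] * xx +
        stats::rnorm(1, 0, 1) * exp(-((yy - by)^2 + (xx - bx)^2) / (2 * br^2))
      field <- field - mean(field)
      refl[, , m] <- refl[, , m] * pmax(1 + bsd * field, 0.2)
    }
  }
  msd <- config$noise$multiplicative_sd
  if (msd > 0) {
    illum <- exp(stats::rnorm(h * w, -msd^2 / 2, msd))  # mean-1 lognormal
    for (m in seq_len(n)) refl[, , m] <- refl[, , m] * illum
  }
  dl <- array(0, dim = c(h, w, n))
  asd <- config$noise$additive_sd
  for (m in seq_len(n)) {
    dl[, , m] <- config$dark_level[m] +
      (config$white_level[m] - config$dark_level[m]) *
      refl[, , m] / config$refl_ref[m]
    if (asd > 0) dl[, , m] <- dl[, , m] + stats::rnorm(h * w, 0, asd)
  }
  dl <- pmin(pmax(dl, 0), 65535)  # 16-bit sensor clips at both ends
  masks <- list(
    entire_retina = roi_mask(geo$retina, "entire_retina"),
    vessels = roi_mask(geo$vessels, "vessels"),
    optic_disk = roi_mask(geo$optic_disk, "optic_disk"),
    macula = roi_mask(geo$macula, "macula"),
    background = roi_mask(geo$background, "background")
  )
  list(cube = spectral_cube(dl, config$bands, stage = "raw_dl"),
       masks = masks, label = label, extent = extent,
       reflectance_field = refl)
}

#' Reference white/dark cube pair for a synthetic dataset
#'
#' One shared pair per dataset (the calibration procedure uses a single
#' reference target): spatially flat white at `white_level` and dark at
#' `dark_level` per band, noise-free.
#'
#' @param config A [synthetic_config].
#' @return A [reference_set].
#' @export
generate_references <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  n <- config$bands$n
  mk <- function(levels) {
    a <- array(0, dim = c(h, w, n))
    for (m in seq_len(n)) a[, , m] <- levels[m]
    spectral_cube(a, config$bands, stage = "raw_dl")
  }
  reference_set(mk(config$white_level), mk(config$dark_level),
                config$refl_ref)
}

#' Generate a full synthetic dataset
#'
#' Generates `n_healthy + n_diseased` cases (healthy first) and the shared
#' reference pair. With `out_dir` set, writes every cube (TIFF + sidecar),
#' mask (PNG), the references, and a JSON manifest, and returns the manifest;
#' otherwise returns the dataset in memory.
#'
#' @param config A [synthetic_config] with `n_healthy + n_diseased >= 2`.
#' @param out_dir Optional output directory.
#' @return List with `cases`, `refs`, `config`; each case carries `case_id`,
#'   `label`, `extent` and either in-memory `cube`/`masks` or relative file
#'   paths.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  if (config$n_healthy + config$n_diseased < 2L)
    stop("need at least 2 cases")
  labels <- c(rep("healthy", config$n_healthy),
              rep("diseased", config$n_diseased))
  ids <- sprintf("%s%03d", ifelse(labels == "healthy", "H", "D"),
                 c(seq_len(config$n_healthy), seq_len(config$n_diseased)))
  refs <- generate_references(config)
  if (is.null(out_dir)) {
    cases <- lapply(seq_along(labels), function(i) {
      cs <- generate_case(config, labels[i], case_index = i)
      cs$case_id <- ids[i]
      cs
    })
    return(list(cases = cases, refs = refs, config = config))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cube(refs$white, file.path(out_dir, "white.tif"))
  write_cube(refs$dark, file.path(out_dir, "dark.tif"))
  man_cases <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cs <- generate_case(config, labels[i], case_index = i)
    cube_rel <- paste0(ids[i], ".tif")
    write_cube(cs$cube, file.path(out_dir, cube_rel))
    mask_rel <- list()
    for (rg in names(cs$masks)) {
      mask_rel[[rg]] <- paste0(ids[i], "_", rg, ".png")
      write_mask(cs$masks[[rg]], file.path(out_dir, mask_rel[[rg]]))
    }
    man_cases[[i]] <- list(case_id = ids[i], label = labels[i],
                           extent = cs$extent, cube = cube_rel,
                           masks = mask_rel,
                           references = list(white = "white.tif",
                                             dark = "dark.tif"))
  }
  manifest <- list(cases = man_cases,
                   refl_ref = config$refl_ref,
                   seed = config$seed)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}
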