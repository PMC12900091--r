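test_that("tissue spectra honor the anatomy contracts", {
  bands <- default_band_set()
  bg <- tissue_spectrum("background", bands)
  vs <- tissue_spectrum("vessel", bands)
  od <- tissue_spectrum("optic_disk", bands)
  mc <- tissue_spectrum("macula", bands)
  for (r in list(bg, vs, od, mc)) {
    expect_length(r, 12L)
    expect_true(all(r > 0 & r <= 1))
  }
  # vessels darker than background where hemoglobin absorbs
  i524 <- match(524, bands$centers_nm); i595 <- match(595, bands$centers_nm)
  expect_lt(vs[i524], bg[i524])
  expect_lt(vs[i595], bg[i595])
  # optic disk brightest overall
  expect_gt(min(od - bg), 0)
  expect_gt(mean(od), max(mean(bg), mean(vs), mean(mc)))
  # nonpositive-reflectance parameters are rejected
  bad <- default_spectrum_params()
  bad$vessel$dip_depth <- 3
  expect_error(tissue_spectrum("vessel", bands, bad), "outside")
  expect_error(tissue_spectrum("sclera", bands), "unknown tissue")
})

test_that("generation is bit-reproducible given config seed and case index", {
  cfg <- synthetic_config(n_healthy = 2, n_diseased = 2,
                          image_size = c(32, 32), seed = 99)
  a <- generate_case(cfg, "diseased", case_index = 3L)
  b <- generate_case(cfg, "diseased", case_index = 3L)
  expect_identical(a$cube$pixels, b$cube$pixels)
  expect_identical(lapply(a$masks, `[[`, "mask"),
                   lapply(b$masks, `[[`, "mask"))
  # a different case index gives a different realization
  c3 <- generate_case(cfg, "diseased", case_index = 4L)
  expect_false(identical(a$cube$pixels, c3$cube$pixels))
})

test_that("masks partition the retina and are geometrically consistent", {
  cfg <- synthetic_config(n_healthy = 2, n_diseased = 2, seed = 5)
  cs <- generate_case(cfg, "healthy", 1L)
  m <- cs$masks
  expect_true(all(vapply(m, function(x) !x$empty, logical(1))))
  parts <- m$vessels$mask + m$optic_disk$mask + m$macula$mask +
    m$background$mask
  expect_true(all(parts[m$entire_retina$mask] == 1L))  # exact partition
  expect_true(all(parts[!m$entire_retina$mask] == 0L))
  expect_false(any(m$optic_disk$mask & m$macula$mask))
})

test_that("the disease effect is confined to its configured extent", {
  no_noise <- list(multiplicative_sd = 0, additive_sd = 0, band_illum_sd = 0)
  cfg <- synthetic_config(
    n_healthy = 1, n_diseased = 1, image_size = c(48, 48), seed = 21,
    disease_effect = list(extent = "macula_only", magnitude = 0.3),
    noise = no_noise)
  cfg0 <- synthetic_config(
    n_healthy = 1, n_diseased = 1, image_size = c(48, 48), seed = 21,
    disease_effect = list(extent = "macula_only", magnitude = 0),
    noise = no_noise)
  cs <- generate_case(cfg, "diseased", 1L)
  cs0 <- generate_case(cfg0, "diseased", 1L)
  # identical stream up to the disease step: same geometry
  expect_identical(cs$masks$macula$mask, cs0$masks$macula$mask)
  diff <- abs(cs$reflectance_field - cs0$reflectance_field)
  per_pixel <- apply(diff, c(1, 2), max)
  expect_equal(max(per_pixel[!cs$masks$macula$mask]), 0)  # untouched outside
  expect_gt(max(per_pixel[cs$masks$macula$mask]), 0.05)   # lesions inside
  expect_equal(cs$extent, "macula_only")
})

test_that("magnitude zero yields identically generated classes", {
  cfg <- synthetic_config(n_healthy = 1, n_diseased = 1,
                          image_size = c(32, 32), seed = 13,
                          disease_effect = list(magnitude = 0))
  h <- generate_case(cfg, "healthy", 1L)
  d <- generate_case(cfg, "diseased", 1L)
  expect_identical(h$cube$pixels, d$cube$pixels)
})

test_that("the forward model is exactly inverted by calibration (noise off)", {
  cfg <- synthetic_config(n_healthy = 1, n_diseased = 1,
                          image_size = c(32, 32), seed = 8,
                          noise = list(multiplicative_sd = 0, additive_sd = 0,
                                       band_illum_sd = 0))
  cs <- generate_case(cfg, "diseased", 2L)
  refl <- compute_reflectance(cs$cube, generate_references(cfg))
  expect_lt(max(abs(refl$pixels - cs$reflectance_field)), 1e-10)
})

test_that("generated datasets have the configured composition", {
  cfg <- synthetic_config()
  expect_equal(cfg$n_healthy, 73)
  expect_equal(cfg$n_diseased, 60)
  ds <- local_test_dataset()
  labs <- vapply(ds$cases, `[[`, character(1), "label")
  expect_equal(sum(labs == "healthy"), 12L)
  expect_equal(sum(labs == "diseased"), 10L)
  expect_false(anyDuplicated(vapply(ds$cases, `[[`, character(1),
                                    "case_id")) > 0)
  expect_error(generate_dataset(synthetic_config(n_healthy = 1,
                                                 n_diseased = 0)),
               "at least 2")
})

test_that("a written dataset loads back equal to the in-memory original", {
  cfg <- synthetic_config(n_healthy = 2, n_diseased = 2,
                          image_size = c(32, 32), seed = 31)
  dir <- withr::local_tempdir()
  generate_dataset(cfg, out_dir = dir)
  mem <- generate_dataset(cfg)
  disk <- load_dataset(dir)
  for (i in seq_along(mem$cases)) {
    expect_equal(disk$cases[[i]]$case_id, mem$cases[[i]]$case_id)
    expect_equal(disk$cases[[i]]$label, mem$cases[[i]]$label)
    # raw DLs are real-valued; the 16-bit container quantizes them to
    # integer digital levels (<= 1 DL; integer DLs round-trip bit-exactly,
    # covered in the I/O tests)
    expect_lte(max(abs(disk$cases[[i]]$cube$pixels -
                       mem$cases[[i]]$cube$pixels)), 1 + 1e-9)
    expect_identical(disk$cases[[i]]$masks$entire_retina$mask,
                     mem$cases[[i]]$masks$entire_retina$mask)
  }
})

test_that("image too small to place the anatomy is rejected", {
  expect_error(generate_case(synthetic_config(image_size = c(12, 12),
                                              seed = 1), "healthy", 1L),
               "too small")
})

test_that("classification power rises with effect size and is chance at null", {
  # grid probes the rising part of the power curve at this problem size;
  # 0.08 is well below, 0.3 at, the default lesion contrast
  seeds <- 1:16
  ba_at <- function(mag, sd) {
    cfg <- synthetic_config(n_healthy = 16, n_diseased = 16,
                            image_size = c(40, 40), seed = sd,
                            disease_effect = list(magnitude = mag))
    ds <- generate_dataset(cfg)
    tab <- build_feature_table(ds, "phasor_msi", harmonic = 1,
                               normalize = "zscore")
    # chance-level classifiers routinely hit the warned 0/0 conventions
    suppressWarnings(
      evaluate(tab, split_protocol(seed = 42), "nusvc")$mean[["BA"]])
  }
  ba0 <- vapply(seeds, function(s) ba_at(0, s), numeric(1))
  ba_small <- vapply(seeds, function(s) ba_at(0.08, s), numeric(1))
  ba_large <- vapply(seeds, function(s) ba_at(0.3, s), numeric(1))
  # monotone in expectation over the seed ensemble
  expect_lte(mean(ba0), mean(ba_small))
  expect_lte(mean(ba_small), mean(ba_large))
  # null soundness: the seed-level BA sd is ~10 points, so the mean over 16
  # seeds has a 95% band of roughly 50 +/- 5; allow 6 for band estimation
  expect_gt(mean(ba0), 44)
  expect_lt(mean(ba0), 56)
})
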