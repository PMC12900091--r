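test_that("harmonic enumeration follows the n-1 rule", {
  expect_equal(harmonics_available(12), 1:11)
  expect_equal(harmonics_available(3), 1:2)
  expect_equal(harmonics_available(2), 1L)
  expect_error(harmonics_available(1), "at least 2")
})

test_that("phasor transform matches the direct-sum oracle", {
  set.seed(9)
  spectra <- matrix(runif(200 * 12), ncol = 12)
  cube <- make_cube(spectra, bands = default_band_set())
  for (k in c(1, 2, 5, 11)) {
    f <- phasor_transform(cube, k)
    want <- t(apply(spectra, 1, phasor_oracle, k = k))
    expect_lt(max(abs(cbind(f$g, f$s) - want)), 1e-12)
  }
})

test_that("closed forms: flat spectrum at the origin, delta on the circle", {
  n <- 12
  flat <- make_cube(matrix(3.7, 1, n), bands = default_band_set())
  for (k in 1:11) {
    f <- phasor_transform(flat, k)
    expect_lt(abs(f$g[1, 1]), 1e-12)
    expect_lt(abs(f$s[1, 1]), 1e-12)
  }
  for (m in c(0, 1, 5, 11)) {
    sp <- rep(0, n); sp[m + 1] <- 2.5
    cube <- make_cube(matrix(sp, 1), bands = default_band_set())
    for (k in c(1, 3)) {
      f <- phasor_transform(cube, k)
      expect_equal(f$g[1, 1], cos(2 * pi * k * m / n), tolerance = 1e-12)
      expect_equal(f$s[1, 1], sin(2 * pi * k * m / n), tolerance = 1e-12)
    }
  }
})

test_that("nonnegative spectra stay inside the unit disk", {
  set.seed(10)
  spectra <- matrix(rexp(2000 * 8), ncol = 8)
  cube <- make_cube(spectra, bands = band_set(seq(400, 750, by = 50)))
  for (k in c(1, 3, 7)) {
    f <- phasor_transform(cube, k)
    expect_true(all(f$g^2 + f$s^2 <= 1 + 1e-12))
  }
})

test_that("phasor mixing is the intensity-weighted linear combination", {
  set.seed(11)
  for (i in 1:50) {
    a <- runif(12); b <- runif(12)
    al <- runif(1, 0.1, 3); be <- runif(1, 0.1, 3)
    k <- sample(1:11, 1)
    pa <- phasor_oracle(a, k); pb <- phasor_oracle(b, k)
    mix <- phasor_transform(make_cube(matrix(al * a + be * b, 1),
                                      bands = default_band_set()), k)
    wa <- al * sum(a); wb <- be * sum(b)
    want <- (wa * pa + wb * pb) / (wa + wb)
    expect_equal(c(mix$g[1, 1], mix$s[1, 1]), unname(want),
                 tolerance = 1e-12)
  }
})

test_that("phasor is scale-invariant and conjugate-symmetric", {
  set.seed(12)
  sp <- runif(12)
  bands <- default_band_set()
  for (k in c(1, 4)) {
    f1 <- phasor_transform(make_cube(matrix(sp, 1), bands = bands), k)
    f2 <- phasor_transform(make_cube(matrix(sp * 137.2, 1), bands = bands), k)
    expect_equal(c(f1$g, f1$s), c(f2$g, f2$s), tolerance = 1e-12)
    fc <- phasor_transform(make_cube(matrix(sp, 1), bands = bands), 12 - k)
    expect_equal(fc$g[1, 1], f1$g[1, 1], tolerance = 1e-12)
    expect_equal(fc$s[1, 1], -f1$s[1, 1], tolerance = 1e-12)
  }
})

test_that("harmonic bounds and denominator guards are enforced", {
  cube <- make_cube(matrix(runif(24), ncol = 12), bands = default_band_set())
  expect_error(phasor_transform(cube, 0), "1\\.\\.11")
  expect_error(phasor_transform(cube, 12), "1\\.\\.11")
  expect_error(phasor_transform(cube, 1, eps = -1), "positive")
  # zero-sum spectrum is invalidated, not unbounded
  z <- make_cube(matrix(c(1, -1, 0.5, -0.5, rep(0, 8)), 1),
                 stage = "zscored", bands = default_band_set())
  z$pixels[1, 1, ] <- c(1, -1, 0.5, -0.5, rep(0, 8))
  f <- phasor_transform(z, 1, eps = 1e-6)
  expect_false(f$valid[1, 1])
  expect_true(is.na(f$g[1, 1]))
  # the adaptive guard keeps the strongest half
  set.seed(13)
  zz <- make_cube(matrix(rnorm(500 * 12), ncol = 12), stage = "zscored",
                  bands = default_band_set())
  fq <- phasor_transform(zz, 1, min_denom_quantile = 0.5)
  expect_equal(sum(fq$valid), 250L)
  expect_error(phasor_transform(zz, 1, min_denom_quantile = 1.2), "in \\(0, 1\\)")
})

test_that("wavelength phase axis weights by bandwidth and spans 0..2*pi*k", {
  bands <- band_set(c(400, 500, 700), bandwidths_nm = c(10, 20, 10))
  sp <- c(2, 0, 0)  # all intensity at lambda0 -> phase 0 -> (1, 0)
  f <- phasor_transform(make_cube(matrix(sp, 1), bands = bands), 1,
                        phase_axis = "wavelength")
  expect_equal(c(f$g[1, 1], f$s[1, 1]), c(1, 0), tolerance = 1e-12)
  # intensity at the last band -> phase 2*pi*k -> also (1, 0)
  f2 <- phasor_transform(make_cube(matrix(c(0, 0, 2), 1), bands = bands), 1,
                         phase_axis = "wavelength")
  expect_equal(c(f2$g[1, 1], f2$s[1, 1]), c(1, 0), tolerance = 1e-12)
  # mid band at 500 nm -> phase 2*pi*(100/300)
  f3 <- phasor_transform(make_cube(matrix(c(0, 2, 0), 1), bands = bands), 1,
                         phase_axis = "wavelength")
  expect_equal(f3$g[1, 1], cos(2 * pi / 3), tolerance = 1e-12)
})

test_that("phasor summaries average correctly and report dispersion", {
  # identical pixels -> zero dispersion
  cube <- make_cube(matrix(rep(c(1, 2, 3), each = 5), ncol = 3),
                    bands = band_set(c(450, 550, 650)))
  f <- phasor_transform(cube, 1)
  sm <- summarize_phasor(f, all_mask(cube))
  expect_equal(sm$std, 0)
  expect_equal(sm$n_pixels, 5L)
  # two pixels at (0,0) and (1,0): mean (0.5, 0), std 0.5
  f2 <- structure(list(g = matrix(c(0, 1), 2, 1), s = matrix(0, 2, 1),
                       harmonic = 1L, valid = matrix(TRUE, 2, 1)),
                  class = "phasor_field")
  sm2 <- summarize_phasor(f2, matrix(TRUE, 2, 1))
  expect_equal(c(sm2$g_avg, sm2$s_avg, sm2$std), c(0.5, 0, 0.5))
  # mixture scope average equals the pixel-count-weighted sub-scope average
  set.seed(14)
  g <- matrix(rnorm(40), 8, 5); s <- matrix(rnorm(40), 8, 5)
  fld <- structure(list(g = g, s = s, harmonic = 1L,
                        valid = matrix(TRUE, 8, 5)), class = "phasor_field")
  part <- matrix(runif(40) < 0.5, 8, 5)
  a <- summarize_phasor(fld, part)
  b <- summarize_phasor(fld, !part)
  tot <- summarize_phasor(fld, matrix(TRUE, 8, 5))
  expect_equal(tot$g_avg,
               (a$n_pixels * a$g_avg + b$n_pixels * b$g_avg) / 40,
               tolerance = 1e-12)
  expect_equal(tot$s_avg,
               (a$n_pixels * a$s_avg + b$n_pixels * b$s_avg) / 40,
               tolerance = 1e-12)
  expect_error(summarize_phasor(fld, matrix(FALSE, 8, 5)), "empty scope")
})

test_that("band averages have the right length and values", {
  cube <- make_cube(matrix(0.42, 7, 12), bands = default_band_set())
  expect_equal(unname(band_average_features(cube, all_mask(cube))),
               rep(0.42, 12))
  rgb <- extract_rgb_like(cube)
  expect_length(band_average_features(rgb, all_mask(rgb)), 3L)
  two <- make_cube(matrix(c(0.2, 0.4), 2, 2), bands = band_set(c(450, 550)))
  expect_equal(unname(band_average_features(two, all_mask(two))),
               c(0.3, 0.3))
})
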